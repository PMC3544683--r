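#' @rdname rishScores
#' @export
setGeneric("rishScores", function(x) standardGeneric("rishScores"))

#' @rdname classLabels
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname tissueLabels
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' @rdname panelGenes
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname analyticAUC
#' @export
setGeneric("analyticAUC", function(effect) standardGeneric("analyticAUC"))

#' @rdname bestSubset
#' @export
setGeneric("bestSubset", function(trace) standardGeneric("bestSubset"))

#' Access the score matrix of a RishScoreSet
#'
#' @param x a [RishScoreSet-class].
#' @return `rishScores`: the integer score matrix (genes x samples).
#' @rdname rishScores
#' @export
setMethod("rishScores", "RishScoreSet", function(x)
  SummarizedExperiment::assay(x, "scores"))

#' Adjacent-tissue class labels
#'
#' @param x a [RishScoreSet-class].
#' @return factor with levels `NTAB`, `NTAC`, one per sample.
#' @rdname classLabels
#' @export
setMethod("classLabels", "RishScoreSet", function(x)
  SummarizedExperiment::colData(x)$class)

#' Tissue of origin per sample
#'
#' @param x a [RishScoreSet-class].
#' @return character vector, one tissue name per sample.
#' @rdname tissueLabels
#' @export
setMethod("tissueLabels", "RishScoreSet", function(x)
  SummarizedExperiment::colData(x)$tissue)

#' Gene panel of an object
#'
#' @param x a [RishScoreSet-class].
#' @return character vector of gene names in panel order.
#' @rdname panelGenes
#' @export
setMethod("panelGenes", "RishScoreSet", function(x) rownames(x))

#' @exportMethod show
setMethod("show", "RishScoreSet", function(object) {
  cl <- classLabels(object)
  cat("RishScoreSet:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  NTAC:", sum(cl == "NTAC"), " NTAB:", sum(cl == "NTAB"),
      " tissues:", length(unique(tissueLabels(object))), "\n")
  cat("  genes:", paste(utils::head(rownames(object), 5), collapse = ", "),
      if (nrow(object) > 5) "..." else "", "\n")
})

setMethod("show", "CohortDesign", function(object) {
  g <- object@groups
  cat("CohortDesign:", nrow(g), "tissue groups,", sum(g$n_cases),
      "cases (NTAC", sum(g$n_cases[g$tumor_class == "malignant"]),
      "/ NTAB", sum(g$n_cases[g$tumor_class == "benign"]), ")\n")
  print(g, row.names = FALSE)
})

setMethod("show", "GeneEffect", function(object) {
  cat("GeneEffect for", object@gene,
      sprintf("(analytic AUC %.3f)\n", analyticAUC(object)))
  m <- rbind(NTAC = object@pNTAC, NTAB = object@pNTAB)
  colnames(m) <- as.character(0:6)
  print(round(m, 3))
})

setMethod("show", "SelectionTrace", function(object) {
  cat("SelectionTrace (criterion:", object@criterion, ")\n")
  print(as.data.frame(object), row.names = FALSE)
})

#' @describeIn SelectionTrace-class number of subset sizes in the trace.
#' @param x a `SelectionTrace`.
#' @export
setMethod("length", "SelectionTrace", function(x) length(x@genes))

#' Tabular view of a selection trace
#'
#' @param x a [SelectionTrace-class].
#' @param row.names,optional,... ignored, present for generic consistency.
#' @return data.frame with columns `size`, `gene_added`, `mean_auc`,
#'   `sd_auc`.
#' @export
as.data.frame.SelectionTrace <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  k <- length(x@genes)
  added <- vapply(seq_len(k), function(i) {
    if (i == 1L) x@genes[[1L]] else setdiff(x@genes[[i]], x@genes[[i - 1L]])
  }, character(1))
  data.frame(size = seq_len(k), gene_added = added,
             mean_auc = x@meanAUC, sd_auc = x@sdAUC)
}

#' @exportMethod as.data.frame
setMethod("as.data.frame", "SelectionTrace", as.data.frame.SelectionTrace)
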