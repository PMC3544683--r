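#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats pnorm sd var p.adjust runif quantile predict
#' @importFrom utils combn write.table read.delim
NULL

#' RishScoreSet: ordinal RISH score matrices with cohort annotation
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding
#' semi-quantitative RNA in situ hybridization (RISH) scores. Genes are rows,
#' samples are columns; the single assay `"scores"` contains integers in
#' 0--6 (positive-cell-ratio category 0--3 plus staining-density category
#' 0--3). Column data carries the tissue of origin and the adjacent-tissue
#' class: `NTAC` (normal tissue adjacent to a malignant tumor) or `NTAB`
#' (normal tissue adjacent to a benign tumor).
#'
#' @seealso [RishScoreSet()] (constructor), [rishScores()], [classLabels()],
#'   [tissueLabels()], [panelGenes()]
#' @export
setClass("RishScoreSet", contains = "SummarizedExperiment")

.validScoreValues <- function(s) {
  is.numeric(s) && all(!is.na(s)) && all(s == round(s)) &&
    all(s >= 0) && all(s <= 6)
}

setValidity("RishScoreSet", function(object) {
  msg <- character()
  if (!"scores" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'scores' is required")
  else if (!.validScoreValues(SummarizedExperiment::assay(object, "scores")))
    msg <- c(msg, "all scores must be integers in {0,...,6}")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("tissue", "class") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'tissue' and 'class'")
  else {
    cl <- cd$class
    if (!is.factor(cl) || !identical(levels(cl), c("NTAB", "NTAC")))
      msg <- c(msg, "'class' must be a factor with levels NTAB, NTAC")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene names (rownames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a RishScoreSet
#'
#' @param scores integer matrix of RISH composite scores in 0--6, genes in
#'   rows, samples in columns. Must carry rownames (genes); colnames are
#'   taken from `sampleIDs` when given.
#' @param tissue character vector, tissue of origin per sample.
#' @param classLabel character or factor per sample, each `"NTAC"` or
#'   `"NTAB"`.
#' @param sampleIDs unique sample identifiers; defaults to
#'   `colnames(scores)`.
#'
#' @return A [RishScoreSet-class] object.
#' @examples
#' m <- matrix(c(0L, 6L, 3L, 2L), nrow = 2,
#'             dimnames = list(c("TP53", "MYC"), c("s1", "s2")))
#' RishScoreSet(m, tissue = c("breast", "breast"),
#'              classLabel = c("NTAC", "NTAB"))
#' @export
RishScoreSet <- function(scores, tissue, classLabel,
                         sampleIDs = colnames(scores)) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (is.null(sampleIDs))
    sampleIDs <- paste0("sample_", seq_len(ncol(scores)))
  if (!all(as.character(classLabel) %in% c("NTAB", "NTAC")))
    stop("class labels must be 'NTAC' or 'NTAB'")
  colnames(scores) <- sampleIDs
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(scores = scores),
    colData = S4Vectors::DataFrame(
      tissue = as.character(tissue),
      class = factor(as.character(classLabel), levels = c("NTAB", "NTAC")),
      row.names = sampleIDs))
  new("RishScoreSet", se)
}

#' CohortDesign: tissue-group composition of a cohort
#'
#' Describes a cohort as an ordered list of tissue groups, each with a tissue
#' name, a tumor class (`malignant` or `benign`) and a case count. The tumor
#' class determines the adjacent-tissue label of every case in the group:
#' malignant tumors contribute NTAC samples, benign tumors NTAB samples.
#'
#' @slot groups data.frame with columns `tissue` (unique names),
#'   `tumor_class` (`"malignant"` or `"benign"`) and `n_cases`
#'   (positive integers).
#'
#' @seealso [CohortDesign()], [defaultDesign()], [simulateCohort()]
#' @export
setClass("CohortDesign", representation(groups = "data.frame"))

setValidity("CohortDesign", function(object) {
  g <- object@groups
  msg <- character()
  if (!all(c("tissue", "tumor_class", "n_cases") %in% colnames(g)))
    msg <- c(msg, "groups needs columns tissue, tumor_class, n_cases")
  else {
    if (anyDuplicated(g$tissue))
      msg <- c(msg, "tissue group names must be unique")
    if (!all(g$tumor_class %in% c("malignant", "benign")))
      msg <- c(msg, "tumor_class must be 'malignant' or 'benign'")
    if (!all(g$n_cases == round(g$n_cases)) || any(g$n_cases < 1))
      msg <- c(msg, "n_cases must be positive integers")
  }
  if (length(msg)) msg else TRUE
})

#' @param groups data.frame with columns `tissue`, `tumor_class`, `n_cases`.
#' @return A [CohortDesign-class].
#' @examples
#' CohortDesign(data.frame(tissue = "breast_carcinoma",
#'                         tumor_class = "malignant", n_cases = 5))
#' @rdname CohortDesign-class
#' @export
CohortDesign <- function(groups) {
  groups$tissue <- as.character(groups$tissue)
  groups$tumor_class <- as.character(groups$tumor_class)
  groups$n_cases <- as.integer(groups$n_cases)
  new("CohortDesign", groups = groups)
}

#' GeneEffect: class-conditional score distributions for one gene
#'
#' A pair of discrete probability distributions over the composite score
#' alphabet \{0,...,6\}: one conditional on the NTAC class, one on NTAB.
#' This is the generative unit of the synthetic-cohort simulator; its class
#' separability is summarized exactly by [analyticAUC()].
#'
#' @slot gene gene name.
#' @slot pNTAC numeric(7), probabilities of scores 0..6 in NTAC samples.
#' @slot pNTAB numeric(7), probabilities of scores 0..6 in NTAB samples.
#'
#' @seealso [GeneEffect()], [nullEffect()], [effectFromAUC()],
#'   [analyticAUC()]
#' @export
setClass("GeneEffect",
         representation(gene = "character", pNTAC = "numeric",
                        pNTAB = "numeric"))

.validProbVector <- function(p) {
  length(p) == 7L && all(!is.na(p)) && all(p >= 0) &&
    abs(sum(p) - 1) <= 1e-9
}

setValidity("GeneEffect", function(object) {
  msg <- character()
  if (length(object@gene) != 1L || !nzchar(object@gene))
    msg <- c(msg, "gene must be a single non-empty name")
  if (!.validProbVector(object@pNTAC))
    msg <- c(msg, "pNTAC must be 7 non-negative probabilities summing to 1 (tol 1e-9)")
  if (!.validProbVector(object@pNTAB))
    msg <- c(msg, "pNTAB must be 7 non-negative probabilities summing to 1 (tol 1e-9)")
  if (length(msg)) msg else TRUE
})

#' @param gene gene name.
#' @param pNTAC,pNTAB numeric(7) probability vectors over scores 0..6.
#' @return A [GeneEffect-class].
#' @examples
#' GeneEffect("TP53", pNTAC = c(0, 0, 0, 0, 0, 0, 1),
#'            pNTAB = c(1, 0, 0, 0, 0, 0, 0))
#' @rdname GeneEffect-class
#' @export
GeneEffect <- function(gene, pNTAC, pNTAB) {
  new("GeneEffect", gene = as.character(gene), pNTAC = as.numeric(pNTAC),
      pNTAB = as.numeric(pNTAB))
}

#' SelectionTrace: nested gene subsets with cross-validated AUC
#'
#' The record of one incremental (forward, filter-ranked) selection run:
#' for every subset size k = 1..panel size, the nested gene subset and the
#' mean and standard deviation of its repeated cross-validated AUC.
#'
#' @slot criterion the filter criterion that ordered the genes.
#' @slot genes list of character vectors; element k is the size-k subset and
#'   extends element k-1 by exactly one gene.
#' @slot meanAUC,sdAUC numeric, one value per subset size.
#'
#' @seealso [incrementalSelection()], [bestSubset()]
#' @export
setClass("SelectionTrace",
         representation(criterion = "character", genes = "list",
                        meanAUC = "numeric", sdAUC = "numeric"))

setValidity("SelectionTrace", function(object) {
  msg <- character()
  k <- length(object@genes)
  if (length(object@meanAUC) != k || length(object@sdAUC) != k)
    msg <- c(msg, "genes, meanAUC and sdAUC must have equal length")
  if (k > 0 && length(object@genes[[1L]]) != 1L)
    msg <- c(msg, "trace must start from a single gene")
  if (k > 1) {
    for (i in 2:k) {
      prev <- object@genes[[i - 1L]]
      cur <- object@genes[[i]]
      if (length(cur) != length(prev) + 1L || !all(prev %in% cur)) {
        msg <- c(msg, "subsets must be nested and grow by one gene")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})
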