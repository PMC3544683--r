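# Pipeline I/O and report surfaces: TSV score matrices, JSON configs,
# heat-map export, and the end-to-end run that writes the differential
# table, single-gene AUC table, per-criterion selection traces and best
# subsets.

#' Write a RishScoreSet as TSV
#'
#' One row per sample: `sample_id`, `tissue`, `class`, then one integer
#' column per gene. UTF-8, LF line endings, tab separated.
#'
#' @param x a [RishScoreSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeScoreMatrix <- function(x, path) {
  stopifnot(is(x, "RishScoreSet"))
  df <- data.frame(sample_id = colnames(x),
                   tissue = tissueLabels(x),
                   class = as.character(classLabels(x)),
                   t(rishScores(x)), check.names = FALSE)
  con <- file(path, open = "wb")  # binary mode forces LF on all platforms
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a RishScoreSet from TSV
#'
#' Parses the dialect written by [writeScoreMatrix()] and validates it:
#' scores must be integers in 0--6 (a violation names the offending sample
#' and gene), class labels must be `NTAC` or `NTAB`, and sample ids must be
#' unique.
#'
#' @param path TSV file path.
#' @return A [RishScoreSet-class].
#' @export
readScoreMatrix <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("sample_id", "tissue", "class")
  if (!all(need %in% colnames(df)[1:3]))
    stop("format error: header must start with sample_id, tissue, class")
  if (anyDuplicated(df$sample_id))
    stop("format error: duplicated sample_id '",
         df$sample_id[duplicated(df$sample_id)][1L], "'")
  bad <- !df$class %in% c("NTAC", "NTAB")
  if (any(bad))
    stop("format error: unknown class label '", df$class[bad][1L],
         "' for sample '", df$sample_id[bad][1L], "'")
  genes <- setdiff(colnames(df), need)
  if (!length(genes)) stop("format error: no gene columns")
  m <- as.matrix(df[, genes, drop = FALSE])
  if (!is.numeric(m))
    stop("format error: non-numeric score column")
  off <- which(is.na(m) | m != round(m) | m < 0 | m > 6, arr.ind = TRUE)
  if (nrow(off))
    stop("format error: score out of {0..6} at sample '",
         df$sample_id[off[1L, 1L]], "', gene '", genes[off[1L, 2L]], "'")
  RishScoreSet(t(m), tissue = df$tissue, classLabel = df$class,
               sampleIDs = df$sample_id)
}

#' Write / read a cohort design as JSON
#'
#' @param design a [CohortDesign-class].
#' @param path JSON file path.
#' @return `writeCohortDesign`: `path` invisibly; `readCohortDesign`: a
#'   [CohortDesign-class].
#' @export
writeCohortDesign <- function(design, path) {
  stopifnot(is(design, "CohortDesign"))
  jsonlite::write_json(design@groups, path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeCohortDesign
#' @export
readCohortDesign <- function(path) {
  CohortDesign(jsonlite::fromJSON(path))
}

#' Write / read a gene-effect panel as JSON
#'
#' @param effects list of [GeneEffect-class].
#' @param path JSON file path.
#' @return `writeEffectPanel`: `path` invisibly; `readEffectPanel`: a named
#'   list of [GeneEffect-class].
#' @export
writeEffectPanel <- function(effects, path) {
  stopifnot(all(vapply(effects, is, logical(1), "GeneEffect")))
  out <- lapply(effects, function(e)
    list(gene = e@gene, p_ntac = e@pNTAC, p_ntab = e@pNTAB))
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeEffectPanel
#' @export
readEffectPanel <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  effs <- lapply(raw, function(e)
    GeneEffect(e$gene, unlist(e$p_ntac), unlist(e$p_ntab)))
  names(effs) <- vapply(effs, function(e) e@gene, character(1))
  effs
}

#' Per-gene z-scaled matrix for heat-map display
#'
#' Standardizes each gene across samples (mean 0, SD 1, sample-SD
#' convention with an SD floor so constant genes map to zero) and clips the
#' result to \[-3, 3\], the display scale of the expression heat map.
#'
#' @param x a [RishScoreSet-class].
#' @return Numeric matrix (genes x samples) with all entries in \[-3, 3\].
#' @export
zscaleForHeatmap <- function(x) {
  stopifnot(is(x, "RishScoreSet"))
  m <- rishScores(x)
  mu <- rowMeans(m)
  sg <- pmax(apply(m, 1L, sd), .sdFloor)
  z <- (m - mu) / sg
  pmin(pmax(z, -3), 3)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline. Exactly one input
#' source must be given: a score-matrix TSV (`matrixPath`) or a simulation
#' (`design` + `effects` + `seed`).
#'
#' @param outDir output directory (created if absent).
#' @param matrixPath optional TSV of an existing score matrix.
#' @param design,effects simulation inputs ([CohortDesign-class], list of
#'   [GeneEffect-class]); defaults are the study design with a null panel.
#' @param seed integer seed for simulation and cross-validation.
#' @param alpha significance level for direction calls (default 0.05).
#' @param criteria filter criteria to trace (default: all four).
#' @param classifier a [classifierSpec()].
#' @param cv a [cvSpec()]; its seed is overridden by `seed`.
#' @return List of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(outDir, matrixPath = NULL,
                           design = defaultDesign(),
                           effects = effectPanel(), seed = 1L,
                           alpha = 0.05, criteria = .criteria,
                           classifier = classifierSpec(),
                           cv = cvSpec()) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  criteria <- match.arg(criteria, .criteria, several.ok = TRUE)
  if (!is.null(matrixPath) && !file.exists(matrixPath))
    stop("matrixPath does not exist: ", matrixPath)
  cv$seed <- as.integer(seed)
  structure(list(outDir = outDir, matrixPath = matrixPath, design = design,
                 effects = effects, seed = as.integer(seed), alpha = alpha,
                 criteria = criteria, classifier = classifier, cv = cv),
            class = "pipelineConfig")
}

.fmtAUC <- function(x) sprintf("%.4f", x)
.fmtP <- function(x) sprintf("%.6e", x)

.writeTSV <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Run the full marker-discovery pipeline
#'
#' Executes the three analysis steps on the configured input cohort —
#' per-gene rank-sum testing, single-gene cross-validated AUC, and
#' filter-ranked incremental subset selection per criterion — and writes
#' the report bundle to `config$outDir`:
#' \describe{
#'   \item{scores.tsv}{the analyzed score matrix ([writeScoreMatrix()]).}
#'   \item{differential.tsv}{gene, W, z, p, p_bh, direction table.}
#'   \item{single_gene_auc.tsv}{per-gene cross-validated AUC.}
#'   \item{trace_<criterion>.tsv}{one selection trace per criterion.}
#'   \item{best_subsets.tsv}{best subset per criterion.}
#'   \item{heatmap_z.tsv}{per-gene z-scaled matrix clipped to \[-3, 3\].}
#'   \item{run_log.json}{seed, config hash, per-stage timings.}
#' }
#' P values are written in scientific notation and AUCs with 4 decimals,
#' so repeated runs with the same config are byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with the in-memory results (`scores`,
#'   `differential`, `singleGene`, `traces`, `bestSubsets`) and the output
#'   `paths`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  x <- stage("input", {
    if (!is.null(config$matrixPath)) readScoreMatrix(config$matrixPath)
    else simulateCohort(config$design, config$effects, config$seed)
  })
  paths <- list(scores = file.path(config$outDir, "scores.tsv"))
  writeScoreMatrix(x, paths$scores)

  diffTab <- stage("test", differentialPanel(x, alpha = config$alpha))
  dOut <- diffTab
  dOut$z <- .fmtAUC(dOut$z)
  dOut$p <- .fmtP(dOut$p)
  dOut$p_bh <- .fmtP(dOut$p_bh)
  dOut$mean_ntac <- .fmtAUC(dOut$mean_ntac)
  dOut$mean_ntab <- .fmtAUC(dOut$mean_ntab)
  dOut$mean_difference <- .fmtAUC(dOut$mean_difference)
  paths$differential <- file.path(config$outDir, "differential.tsv")
  .writeTSV(dOut, paths$differential)

  singles <- stage("single_gene_auc",
                   singleGeneAUCs(x, config$classifier, config$cv))
  sOut <- data.frame(gene = singles$gene,
                     mean_auc = .fmtAUC(singles$mean_auc),
                     sd_auc = .fmtAUC(singles$sd_auc))
  paths$singleGene <- file.path(config$outDir, "single_gene_auc.tsv")
  .writeTSV(sOut, paths$singleGene)

  traces <- list()
  bests <- list()
  for (cr in config$criteria) {
    tr <- stage(paste0("select_", cr),
                incrementalSelection(x, cr, config$classifier, config$cv))
    traces[[cr]] <- tr
    bests[[cr]] <- bestSubset(tr)
    td <- as.data.frame(tr)
    td$mean_auc <- .fmtAUC(td$mean_auc)
    td$sd_auc <- .fmtAUC(td$sd_auc)
    paths[[paste0("trace_", cr)]] <-
      file.path(config$outDir, paste0("trace_", cr, ".tsv"))
    .writeTSV(td, paths[[paste0("trace_", cr)]])
  }
  bOut <- do.call(rbind, lapply(bests, function(b)
    data.frame(criterion = b$criterion, size = b$size,
               mean_auc = .fmtAUC(b$meanAUC),
               genes = paste(b$genes, collapse = ","))))
  paths$bestSubsets <- file.path(config$outDir, "best_subsets.tsv")
  .writeTSV(bOut, paths$bestSubsets)

  z <- stage("heatmap", zscaleForHeatmap(x))
  zOut <- data.frame(gene = rownames(z),
                     apply(z, 2L, .fmtAUC), check.names = FALSE)
  paths$heatmap <- file.path(config$outDir, "heatmap_z.tsv")
  .writeTSV(zOut, paths$heatmap)

  cfgEcho <- list(seed = config$seed, alpha = config$alpha,
                  criteria = config$criteria,
                  classifier = unclass(config$classifier),
                  cv = unclass(config$cv),
                  input = if (is.null(config$matrixPath)) "simulated"
                          else config$matrixPath,
                  n_samples = ncol(x), n_genes = nrow(x))
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfgEcho, tmp, auto_unbox = TRUE, digits = NA)
  log <- list(seed = config$seed,
              config_hash = unname(tools::md5sum(tmp)),
              config = cfgEcho, stage_seconds = as.list(timings))
  unlink(tmp)
  paths$log <- file.path(config$outDir, "run_log.json")
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(scores = x, differential = diffTab, singleGene = singles,
                 traces = traces, bestSubsets = bests, paths = paths))
}
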