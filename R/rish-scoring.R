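# Semi-quantitative scoring of TMA cores: positive-cell-ratio category
# (0-3) plus staining-density category (0-3) -> composite score 0-6.

#' Positive-cell ratio category of a TMA core
#'
#' Categorizes the fraction of positively stained cells: 0 for under 25%,
#' 1 for 25% up to 50%, 2 for over 50% up to 75%, 3 for over 75%. The
#' published bins leave the boundaries between them unstated; here every
#' fraction in \[0, 1\] maps to exactly one category, with 0.25 falling in
#' category 1, 0.50 in category 1 and 0.75 in category 2.
#'
#' @param positiveFraction numeric vector of fractions in \[0, 1\].
#' @return Integer vector of categories in \{0, 1, 2, 3\}.
#' @examples
#' ratioScore(c(0.10, 0.40, 0.60, 0.80))  # 0 1 2 3
#' @export
ratioScore <- function(positiveFraction) {
  f <- as.numeric(positiveFraction)
  if (any(is.na(f)) || any(f < 0) || any(f > 1))
    stop("positiveFraction must lie in [0, 1]")
  as.integer(ifelse(f < 0.25, 0L,
             ifelse(f <= 0.50, 1L,
             ifelse(f <= 0.75, 2L, 3L))))
}

.checkDensity <- function(densityCategory) {
  d <- densityCategory
  if (any(is.na(d)) || !is.numeric(d) || any(d != round(d)) ||
      any(d < 0) || any(d > 3))
    stop("densityCategory must be an integer in {0, 1, 2, 3} ",
         "(no/light/deep/black staining)")
  as.integer(d)
}

#' Composite RISH expression score of a TMA core
#'
#' The sum of the positive-cell ratio category ([ratioScore()]) and the
#' staining-density category (0 no staining, 1 light, 2 deep, 3 black),
#' giving an ordinal expression score from 0 to 6.
#'
#' @param positiveFraction numeric vector of positive-cell fractions in
#'   \[0, 1\].
#' @param densityCategory integer vector of staining-density categories in
#'   \{0, 1, 2, 3\}; recycled against `positiveFraction`.
#' @return Integer vector of composite scores in \{0, ..., 6\}.
#' @examples
#' compositeScore(0.80, 3)  # 6: >75% positive cells with black staining
#' compositeScore(0.10, 0)  # 0
#' @export
compositeScore <- function(positiveFraction, densityCategory) {
  ratioScore(positiveFraction) + .checkDensity(densityCategory)
}

#' Score a table of core measurements into a RishScoreSet
#'
#' Applies [compositeScore()] to every (sample, gene) core measurement and
#' assembles the results, with the sample annotation, into a
#' [RishScoreSet-class]. The measurement table must cover the full
#' sample x gene grid exactly once.
#'
#' @param measurements data.frame with columns `sample_id`, `gene`,
#'   `positive_fraction`, `density_category` (long format, one row per
#'   core).
#' @param labels data.frame with columns `sample_id`, `tissue`, `class`
#'   (`"NTAC"` or `"NTAB"`), one row per sample.
#' @return A [RishScoreSet-class] with genes in order of first appearance
#'   in `measurements` and samples in `labels` order.
#' @examples
#' meas <- expand.grid(sample_id = c("s1", "s2"), gene = c("TP53", "MYC"),
#'                     stringsAsFactors = FALSE)
#' meas$positive_fraction <- c(0.8, 0.1, 0.3, 0.6)
#' meas$density_category <- c(3, 0, 2, 1)
#' labs <- data.frame(sample_id = c("s1", "s2"),
#'                    tissue = "breast", class = c("NTAC", "NTAB"))
#' scoreCores(meas, labs)
#' @export
scoreCores <- function(measurements, labels) {
  need <- c("sample_id", "gene", "positive_fraction", "density_category")
  if (!all(need %in% colnames(measurements)))
    stop("measurements needs columns ", paste(need, collapse = ", "))
  if (!all(c("sample_id", "tissue", "class") %in% colnames(labels)))
    stop("labels needs columns sample_id, tissue, class")
  samples <- as.character(labels$sample_id)
  genes <- unique(as.character(measurements$gene))
  if (anyDuplicated(samples)) stop("duplicated sample_id in labels")

  key <- paste(measurements$sample_id, measurements$gene, sep = "\r")
  if (anyDuplicated(key))
    stop("incomplete-table error: duplicated core measurement for ",
         sub("\r", " x ", key[duplicated(key)][1L]))
  grid <- expand.grid(sample_id = samples, gene = genes,
                      stringsAsFactors = FALSE)
  wantKey <- paste(grid$sample_id, grid$gene, sep = "\r")
  missing <- setdiff(wantKey, key)
  if (length(missing))
    stop("incomplete-table error: no measurement for ",
         sub("\r", " x ", missing[1L]))
  extra <- setdiff(key, wantKey)
  if (length(extra))
    stop("incomplete-table error: measurement for unlabelled sample in ",
         sub("\r", " x ", extra[1L]))

  sc <- compositeScore(measurements$positive_fraction,
                       measurements$density_category)
  m <- matrix(NA_integer_, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(measurements$gene, genes),
          match(as.character(measurements$sample_id), samples))] <- sc
  RishScoreSet(m, tissue = as.character(labels$tissue),
               classLabel = as.character(labels$class),
               sampleIDs = samples)
}
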