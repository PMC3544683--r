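# Filter criteria: per-gene class-separability scores computed without a
# classifier. The Gaussian-fit criteria (t, symmetric KL, Bhattacharyya)
# treat the ordinal scores as continuous, as classical filter toolboxes do;
# class variances are floored so constant-within-class columns stay finite.

.varFloor <- 1e-9

.twoGroupMoments <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups need at least 2 observations")
  list(m1 = mean(x), m2 = mean(y),
       v1 = max(var(x), .varFloor), v2 = max(var(y), .varFloor),
       n1 = length(x), n2 = length(y))
}

#' Absolute two-sample t filter score
#'
#' @param x,y numeric score vectors (each length >= 2).
#' @param welch use Welch's unequal-variance form instead of the pooled
#'   variance (default `FALSE`, the classical filter form).
#' @return Non-negative |t|.
#' @examples
#' tScore(c(1, 2, 3), c(3, 4, 5))  # 2.449
#' @export
tScore <- function(x, y, welch = FALSE) {
  s <- .twoGroupMoments(x, y)
  se2 <- if (welch) s$v1 / s$n1 + s$v2 / s$n2
  else {
    sp2 <- ((s$n1 - 1) * s$v1 + (s$n2 - 1) * s$v2) / (s$n1 + s$n2 - 2)
    sp2 * (1 / s$n1 + 1 / s$n2)
  }
  abs(s$m1 - s$m2) / sqrt(max(se2, .varFloor))
}

#' Symmetric Kullback-Leibler (entropy) filter score
#'
#' Symmetric KL divergence between the Gaussian fits to the two classes:
#' J = (s1^2 + d^2) / (2 s2^2) + (s2^2 + d^2) / (2 s1^2) - 1, with
#' d the mean difference and s1^2, s2^2 the (floored) class variances.
#'
#' @param x,y numeric score vectors (each length >= 2).
#' @return Non-negative divergence; 0 for identical fits.
#' @examples
#' entropyScore(c(-1, 0, 1), c(1, 2, 3))  # 4: unit variances, d = 2
#' @export
entropyScore <- function(x, y) {
  s <- .twoGroupMoments(x, y)
  d2 <- (s$m1 - s$m2)^2
  (s$v1 + d2) / (2 * s$v2) + (s$v2 + d2) / (2 * s$v1) - 1
}

#' Bhattacharyya filter score
#'
#' Bhattacharyya distance between the Gaussian fits to the two classes:
#' (1/4) d^2 / (s1^2 + s2^2) + (1/2) ln\((s1^2 + s2^2) / (2 s1 s2)\).
#'
#' @param x,y numeric score vectors (each length >= 2).
#' @return Non-negative distance; 0 for identical fits.
#' @examples
#' bhattacharyyaScore(c(-1, 0, 1), c(1, 2, 3))  # 0.5
#' @export
bhattacharyyaScore <- function(x, y) {
  s <- .twoGroupMoments(x, y)
  0.25 * (s$m1 - s$m2)^2 / (s$v1 + s$v2) +
    0.5 * log((s$v1 + s$v2) / (2 * sqrt(s$v1 * s$v2)))
}

#' Wilcoxon filter score
#'
#' The absolute tie-corrected standardized rank-sum statistic |z| from
#' [wilcoxonRankSum()].
#'
#' @param x,y numeric score vectors, each non-empty.
#' @return Non-negative |z|.
#' @export
wilcoxonScore <- function(x, y) {
  abs(wilcoxonRankSum(x, y, method = "normal")$z)
}

.criteria <- c("ttest", "entropy", "bhattacharyya", "wilcoxon")

.criterionFun <- function(criterion) {
  switch(criterion,
         ttest = tScore,
         entropy = entropyScore,
         bhattacharyya = bhattacharyyaScore,
         wilcoxon = wilcoxonScore,
         stop("unknown criterion '", criterion, "'; use one of ",
              paste(.criteria, collapse = ", ")))
}

#' Rank the gene panel by a filter criterion
#'
#' Scores every gene's NTAC-vs-NTAB separability by the chosen criterion
#' and orders the panel best-first. Ties in the score are broken by
#' original panel order, so the ranking is deterministic.
#'
#' @param x a [RishScoreSet-class] containing both classes.
#' @param criterion one of `"ttest"`, `"entropy"`, `"bhattacharyya"`,
#'   `"wilcoxon"`.
#' @return data.frame with columns `rank`, `gene`, `score`, ordered by
#'   decreasing score; the criterion is attached as attribute
#'   `"criterion"`.
#' @examples
#' x <- simulateCohort(defaultDesign(), effectPanel(auc = c(TP53 = 0.9)),
#'                     seed = 1)
#' head(rankGenes(x, "bhattacharyya"), 3)
#' @export
rankGenes <- function(x, criterion = .criteria) {
  stopifnot(is(x, "RishScoreSet"))
  criterion <- match.arg(criterion, .criteria)
  fun <- .criterionFun(criterion)
  cl <- classLabels(x)
  if (length(unique(cl)) < 2L)
    stop("both NTAC and NTAB samples are required")
  m <- rishScores(x)
  sc <- apply(m, 1L, function(row) fun(row[cl == "NTAC"], row[cl == "NTAB"]))
  ord <- order(-sc)  # stable: ties keep panel order
  out <- data.frame(rank = seq_along(sc), gene = rownames(m)[ord],
                    score = as.numeric(sc[ord]))
  attr(out, "criterion") <- criterion
  out
}
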