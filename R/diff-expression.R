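# Wilcoxon rank-sum testing for heavily tied ordinal scores. Scores 0-6
# guarantee massive ties, so midranks are used throughout, the asymptotic
# variance carries the tie correction, and an exact permutation path is
# provided for small samples where the normal approximation is rough.

# midrank sum of x within the pooled sample, its null mean, and the
# tie-corrected null variance n1*n2/12 * [(N+1) - sum(t^3 - t)/(N(N-1))]
.rankSumStats <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  E <- n1 * (N + 1) / 2
  t <- table(c(x, y))
  V <- n1 * n2 / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
  list(W = W, E = E, V = V, r = r, N = N, n1 = n1)
}

# tie-corrected z with 0.5 continuity correction shrinking toward the mean
.rankSumZ <- function(W, E, V) {
  if (V <= 0) return(0)
  dev <- W - E
  if (abs(dev) <= 0.5) return(0)
  (dev - sign(dev) * 0.5) / sqrt(V)
}

# exact two-sided P by full enumeration of the C(N, n1) assignments of the
# pooled midranks: the probability of a rank sum at least as far from its
# null mean as observed
.exactRankSumP <- function(r, n1, W, E) {
  idx <- combn(length(r), n1)
  Ws <- colSums(matrix(r[idx], nrow = n1))
  mean(abs(Ws - E) >= abs(W - E) - 1e-9)
}

.exactFeasibleN <- 20L

#' Wilcoxon rank-sum test for tied ordinal scores
#'
#' Compares two groups of ordinal scores by the rank-sum statistic
#' W = sum of midranks of `x` in the pooled midrank assignment. The
#' `"exact"` method enumerates all assignments of the pooled values to the
#' two groups (feasible for `length(x) + length(y) <= 20`) and returns the
#' exact two-sided permutation P; the `"normal"` method standardizes W with
#' the tie-corrected variance and a 0.5 continuity correction. `"auto"`
#' (default) picks exact when the pooled size is at most 20, normal
#' otherwise. The standardized `z` is reported for both methods.
#'
#' @param x,y numeric score vectors, each non-empty.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return List with elements `W` (rank sum of `x`), `z` (tie-corrected
#'   standardized statistic), `p` (two-sided P) and `method` (the method
#'   actually used).
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6), method = "exact")$p  # 0.1
#' wilcoxonRankSum(c(2, 4), c(2, 4))$p                          # 1
#' @export
wilcoxonRankSum <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (any(is.na(c(x, y)))) stop("scores must not contain NA")
  s <- .rankSumStats(x, y)
  if (method == "auto")
    method <- if (s$N <= .exactFeasibleN) "exact" else "normal"
  z <- .rankSumZ(s$W, s$E, s$V)
  p <- if (method == "exact") {
    if (s$N > .exactFeasibleN)
      stop("capacity error: exact enumeration requires pooled n <= ",
           .exactFeasibleN, " (got ", s$N, ")")
    .exactRankSumP(s$r, s$n1, s$W, s$E)
  } else {
    min(1, 2 * pnorm(-abs(z)))
  }
  list(W = s$W, z = z, p = p, method = method)
}

#' Per-gene differential expression between NTAC and NTAB
#'
#' Runs [wilcoxonRankSum()] for every gene, NTAC scores against NTAB
#' scores, and calls a direction of change: `over` if the NTAC mean score
#' exceeds the NTAB mean and P is below `alpha`, `under` for the reverse,
#' `none` otherwise. Raw P values drive the direction calls; a
#' Benjamini-Hochberg adjusted column (`p_bh`) is reported alongside for
#' reference only.
#'
#' @param x a [RishScoreSet-class] containing both classes.
#' @param alpha significance level for direction calls (default 0.05).
#' @param method test method passed to [wilcoxonRankSum()]; the default
#'   `"auto"` uses the tie-corrected normal approximation for cohorts of
#'   more than 20 samples.
#' @return data.frame with one row per gene: `gene`, `W` (NTAC rank sum),
#'   `z`, `p`, `p_bh`, `mean_ntac`, `mean_ntab`, `mean_difference`
#'   (NTAC minus NTAB) and `direction` (`over`/`under`/`none`).
#' @examples
#' x <- simulateCohort(defaultDesign(), effectPanel(auc = c(TP53 = 0.9)),
#'                     seed = 1)
#' head(differentialPanel(x))
#' @export
differentialPanel <- function(x, alpha = 0.05,
                              method = c("auto", "exact", "normal")) {
  stopifnot(is(x, "RishScoreSet"))
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  cl <- classLabels(x)
  if (length(unique(cl)) < 2L)
    stop("both NTAC and NTAB samples are required")
  m <- rishScores(x)
  res <- lapply(rownames(m), function(g) {
    sc <- m[g, ]
    ntac <- sc[cl == "NTAC"]; ntab <- sc[cl == "NTAB"]
    w <- wilcoxonRankSum(ntac, ntab, method = method)
    md <- mean(ntac) - mean(ntab)
    data.frame(gene = g, W = w$W, z = w$z, p = w$p,
               mean_ntac = mean(ntac), mean_ntab = mean(ntab),
               mean_difference = md,
               direction = if (w$p < alpha && md > 0) "over"
                           else if (w$p < alpha && md < 0) "under"
                           else "none")
  })
  out <- do.call(rbind, res)
  out$p_bh <- p.adjust(out$p, method = "BH")
  out[, c("gene", "W", "z", "p", "p_bh", "mean_ntac", "mean_ntab",
          "mean_difference", "direction")]
}
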