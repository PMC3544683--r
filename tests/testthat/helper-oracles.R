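# Independent oracles and small-fixture builders, kept free of the
# package's own code paths.

# exact two-sided rank-sum P by explicit loop over all group assignments
bruteExactWilcoxonP <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  E <- n1 * (length(pooled) + 1) / 2
  sets <- combn(length(pooled), n1)
  hits <- 0L
  for (j in seq_len(ncol(sets)))
    if (abs(sum(r[sets[, j]]) - E) >= abs(W - E) - 1e-9) hits <- hits + 1L
  hits / ncol(sets)
}

# AUC by explicit pair counting
brutePairAUC <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

# small RishScoreSet from per-gene NTAC/NTAB score vectors
makeScoreSet <- function(ntac, ntab) {
  stopifnot(identical(names(ntac), names(ntab)))
  nC <- length(ntac[[1]])
  nB <- length(ntab[[1]])
  m <- do.call(rbind, lapply(names(ntac), function(g) c(ntac[[g]], ntab[[g]])))
  rownames(m) <- names(ntac)
  RishScoreSet(m,
               tissue = rep(c("carcinoma", "adenoma"), c(nC, nB)),
               classLabel = rep(c("NTAC", "NTAB"), c(nC, nB)),
               sampleIDs = sprintf("s%02d", seq_len(nC + nB)))
}

# random ordinal two-group dataset with heavy ties
randomTiedGroups <- function(minN = 3, maxN = 9, maxTotal = 12) {
  repeat {
    n1 <- sample(minN:maxN, 1)
    n2 <- sample(minN:maxN, 1)
    if (n1 + n2 <= maxTotal) break
  }
  x <- sample(0:6, n1, replace = TRUE)
  y <- sample(0:6, n2, replace = TRUE)
  # degenerate pooled samples (all one value) have no rank information
  if (length(unique(c(x, y))) == 1L) return(randomTiedGroups(minN, maxN, maxTotal))
  list(x = x, y = y)
}
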