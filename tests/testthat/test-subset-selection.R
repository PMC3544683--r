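test_that("aucFromScores counts pairs with half-credit for ties", {
  expect_equal(aucFromScores(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(aucFromScores(1, 1), 0.5)
  expect_equal(aucFromScores(c(3, 1), c(2, 0)), 0.75)
  expect_error(aucFromScores(numeric(0), 1), "non-empty")
  set.seed(31)
  for (i in 1:25) {
    pos <- sample(0:4, sample(1:6, 1), TRUE)
    neg <- sample(0:4, sample(1:6, 1), TRUE)
    expect_equal(aucFromScores(pos, neg), brutePairAUC(pos, neg))
    expect_equal(aucFromScores(pos, neg), 1 - aucFromScores(neg, pos))
  }
})

test_that("cvAUC is deterministic, order-invariant and needs full folds", {
  x <- simulateCohort(defaultDesign(), effectPanel(auc = c(TP53 = 0.87)),
                      seed = 2)
  cv <- cvSpec(nFolds = 10, nRepeats = 3, seed = 9)
  a <- cvAUC(x, "TP53", cv = cv)
  b <- cvAUC(x, "TP53", cv = cv)
  expect_identical(a, b)

  # permuting sample order leaves the seed-derived fold map, hence the AUC,
  # unchanged: folds depend on sample IDs, labels and seed only
  set.seed(1)
  perm <- sample(ncol(x))
  xp <- RishScoreSet(rishScores(x)[, perm], tissue = tissueLabels(x)[perm],
                     classLabel = as.character(classLabels(x))[perm],
                     sampleIDs = colnames(x)[perm])
  expect_equal(cvAUC(xp, "TP53", cv = cv), a)

  small <- makeScoreSet(ntac = list(g = rep(5L, 12)),
                        ntab = list(g = rep(1L, 4)))
  expect_error(cvAUC(small, "g", cv = cvSpec(nFolds = 10)), "nFolds")
  expect_error(cvAUC(x, "NOPE", cv = cv), "unknown genes")
})

test_that("cvAUC separates the separable and stays null for shuffled labels", {
  d <- defaultDesign()
  sep <- list(GeneEffect("g", pNTAC = c(0, 0, 0, 0, 0, 0, 1),
                         pNTAB = c(1, 0, 0, 0, 0, 0, 0)))
  xs <- simulateCohort(d, sep, seed = 3)
  expect_gte(cvAUC(xs, "g", cv = cvSpec(nRepeats = 3, seed = 1))$meanAUC,
             0.99)

  # a fully null cohort is equivalent to permuted class labels
  xn <- simulateCohort(d, effectPanel(), seed = 8)
  null <- cvAUC(xn, cv = cvSpec(nRepeats = 3, seed = 1))$meanAUC
  expect_gte(null, 0.40)
  expect_lte(null, 0.60)
})

test_that("single-gene AUCs recover simulated separability ordering", {
  # levels chosen inside the regime where the margin classifier's decision
  # values remain informative for a lone ordinal feature (see vignette)
  d <- defaultDesign()
  effs <- list(effectFromAUC("weak", 0.75), effectFromAUC("mid", 0.85),
               effectFromAUC("strong", 0.95))
  correct <- 0L
  nrep <- 10L
  for (r in seq_len(nrep)) {
    x <- simulateCohort(d, effs, seed = 100 + r)
    s <- singleGeneAUCs(x, cv = cvSpec(nRepeats = 3, seed = r))
    expect_identical(s$gene, c("weak", "mid", "strong"))
    if (!is.unsorted(s$mean_auc)) correct <- correct + 1L
  }
  expect_gte(correct, 9L)
})

test_that("weakly separating genes yield near-null or collapsed CV AUC", {
  # a soft-margin SVM nearly zeroes its weight on a single weakly
  # informative ordinal feature under the 244/70 imbalance, so the
  # decision-value AUC sits at or below the pairwise score AUC and can
  # fall toward (or under) 0.5 — weak markers are not inflated
  d <- defaultDesign()
  x <- simulateCohort(d, list(effectFromAUC("weak", 0.6)), seed = 77)
  a <- cvAUC(x, "weak", cv = cvSpec(nRepeats = 3, seed = 1))$meanAUC
  sc <- rishScores(x)["weak", ]
  emp <- aucFromScores(sc[classLabels(x) == "NTAC"],
                       sc[classLabels(x) == "NTAB"])
  expect_lte(a, emp + 0.02)
})

test_that("incrementalSelection builds the nested filter-ranked trace", {
  x <- simulateCohort(defaultDesign(), effectPanel(auc = c(TP53 = 0.9)),
                      seed = 6)
  cv <- cvSpec(nRepeats = 2, seed = 1)
  tr <- incrementalSelection(x, "wilcoxon", cv = cv)
  expect_identical(length(tr), 15L)
  ranked <- rankGenes(x, "wilcoxon")$gene
  for (k in seq_len(15)) {
    expect_identical(tr@genes[[k]], ranked[seq_len(k)])
  }
  # the size-1 entry is the top gene evaluated alone
  expect_equal(tr@meanAUC[1],
               cvAUC(x, ranked[1], cv = cv)$meanAUC)
  best <- bestSubset(tr)
  expect_true("TP53" %in% best$genes)
  expect_equal(best$meanAUC, max(tr@meanAUC))
})

test_that("bestSubset prefers the highest AUC, then the smaller subset", {
  mk <- function(auc) new("SelectionTrace", criterion = "ttest",
                          genes = lapply(seq_along(auc),
                                         function(k) letters[seq_len(k)]),
                          meanAUC = auc, sdAUC = rep(0, length(auc)))
  peak1 <- bestSubset(mk(c(0.9, 0.8, 0.7)))
  expect_identical(peak1$genes, "a")
  tied <- bestSubset(mk(c(0.7, 0.9, 0.9)))
  expect_identical(tied$size, 2L)
  rising <- bestSubset(mk(c(0.6, 0.7, 0.8)))
  expect_identical(rising$size, 3L)
  expect_error(bestSubset(new("SelectionTrace", criterion = "ttest",
                              genes = list(), meanAUC = numeric(),
                              sdAUC = numeric())), "empty")
})
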