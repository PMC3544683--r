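test_that("default design reproduces the study cohort composition", {
  d <- defaultDesign()
  g <- cohortGroups(d)
  expect_identical(nrow(g), 8L)
  expect_identical(sum(g$n_cases), 314L)
  counts <- cohortClassCounts(d)
  expect_identical(counts[["NTAC"]], 244L)
  expect_identical(counts[["NTAB"]], 70L)
  expect_identical(sum(g$tumor_class == "malignant"), 6L)
  expect_identical(sum(g$tumor_class == "benign"), 2L)
})

test_that("default panel is the 15 unique marker names", {
  p <- defaultPanel()
  expect_length(p, 15L)
  expect_true("TP53" %in% p)
  expect_false(anyDuplicated(p) > 0)
})

test_that("analyticAUC is exact on hand-enumerable effects", {
  expect_equal(analyticAUC(nullEffect("g")), 0.5)
  sep <- GeneEffect("g", pNTAC = c(0, 0, 0, 0, 0, 0, 1),
                    pNTAB = c(1, 0, 0, 0, 0, 0, 0))
  expect_equal(analyticAUC(sep), 1.0)
  # NTAC uniform over 0..6 vs NTAB point mass at 3: 3/7 wins + half of 1/7
  unifVsPoint <- GeneEffect("g", pNTAC = rep(1 / 7, 7),
                            pNTAB = c(0, 0, 0, 1, 0, 0, 0))
  expect_equal(analyticAUC(unifVsPoint), 3 / 7 + 0.5 / 7)
})

test_that("analyticAUC increases strictly with the latent shift", {
  shifts <- seq(0, 4, by = 0.25)
  aucs <- vapply(shifts, function(s) analyticAUC(latentEffect("g", s)),
                 numeric(1))
  expect_true(all(diff(aucs) > 0))
  expect_equal(aucs[1], 0.5)
})

test_that("effectFromAUC calibrates within tolerance and flags failures", {
  e0 <- effectFromAUC("g", 0.5, 0.005)
  expect_equal(e0@pNTAC, e0@pNTAB)
  for (target in c(0.70, 0.87)) {
    e <- effectFromAUC("g", target, 0.005)
    expect_lte(abs(analyticAUC(e) - target), 0.005)
  }
  expect_error(effectFromAUC("g", 0.999, 0.0001), "calibration failure")
  expect_error(effectFromAUC("g", 1.0), "\\[0.5, 1\\)")
  expect_error(effectFromAUC("g", 0.3), "\\[0.5, 1\\)")
})

test_that("simulateCohort honors design, panel and seed contracts", {
  effs <- effectPanel(auc = c(TP53 = 0.87))
  x <- simulateCohort(defaultDesign(), effs, seed = 1)
  expect_identical(dim(rishScores(x)), c(15L, 314L))
  expect_true(all(rishScores(x) %in% 0:6))
  expect_identical(panelGenes(x), defaultPanel())
  # class counts are conserved exactly, never sampled
  expect_identical(as.integer(table(classLabels(x))[c("NTAB", "NTAC")]),
                   c(70L, 244L))
  x2 <- simulateCohort(defaultDesign(), effs, seed = 1)
  expect_identical(rishScores(x2), rishScores(x))
  x3 <- simulateCohort(defaultDesign(), effs, seed = 2)
  expect_false(identical(rishScores(x3), rishScores(x)))

  tiny <- CohortDesign(data.frame(tissue = "breast_carcinoma",
                                  tumor_class = "malignant", n_cases = 5))
  y <- simulateCohort(tiny, list(nullEffect("g1")), seed = 7)
  expect_identical(dim(rishScores(y)), c(1L, 5L))

  expect_error(simulateCohort(tiny, list(nullEffect("g1"), nullEffect("g1")),
                              seed = 1), "panel mismatch")
  expect_error(simulateCohort(tiny, list(nullEffect("g1"))), "seed")
  expect_error(simulateCohort(tiny, list(GeneEffect("g1", rep(0.2, 7),
                                                    rep(1 / 7, 7))),
                              seed = 1), "summing to 1")
})

test_that("per-gene substreams keep other genes' draws fixed", {
  d <- CohortDesign(data.frame(
    tissue = c("carcinoma", "adenoma"),
    tumor_class = c("malignant", "benign"), n_cases = c(30, 30)))
  base <- list(nullEffect("g1"), nullEffect("g2"), nullEffect("g3"))
  changed <- base
  changed[[2]] <- effectFromAUC("g2", 0.9)
  a <- simulateCohort(d, base, seed = 5)
  b <- simulateCohort(d, changed, seed = 5)
  expect_identical(rishScores(a)["g1", ], rishScores(b)["g1", ])
  expect_identical(rishScores(a)["g3", ], rishScores(b)["g3", ])
  expect_false(identical(rishScores(a)["g2", ], rishScores(b)["g2", ]))
})

test_that("empirical pairwise AUC converges to the analytic value", {
  big <- CohortDesign(data.frame(
    tissue = c("carcinoma", "adenoma"),
    tumor_class = c("malignant", "benign"), n_cases = c(5000, 5000)))
  eff <- effectFromAUC("g", 0.75)
  x <- simulateCohort(big, list(eff), seed = 99)
  sc <- rishScores(x)["g", ]
  emp <- aucFromScores(sc[classLabels(x) == "NTAC"],
                       sc[classLabels(x) == "NTAB"])
  expect_lte(abs(emp - analyticAUC(eff)), 0.01)
})

test_that("the tissueEffect hook perturbs only the targeted tissue", {
  d <- CohortDesign(data.frame(
    tissue = c("liver", "stomach"),
    tumor_class = c("malignant", "malignant"), n_cases = c(400, 400)))
  hook <- function(effect, tissue) {
    if (tissue == "liver") latentEffect(effect@gene, 3) else effect
  }
  plain <- simulateCohort(d, list(nullEffect("g")), seed = 3)
  shifted <- simulateCohort(d, list(nullEffect("g")), seed = 3,
                            tissueEffect = hook)
  liver <- tissueLabels(plain) == "liver"
  expect_identical(rishScores(plain)["g", !liver],
                   rishScores(shifted)["g", !liver])
  expect_gt(mean(rishScores(shifted)["g", liver]),
            mean(rishScores(plain)["g", liver]))
})
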