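# Synthetic RISH cohort generator with analytic calibration.
#
# Scores are drawn from class-conditional discrete distributions over
# {0..6} (GeneEffect). The calibrated family discretizes a latent
# Normal(shift * class, 1) through fixed cut points, so a single monotone
# shift parameter controls separability and bisection against the exact
# pairwise AUC is well-posed.

# 8 fixed cut points (6 interior) defining the 7 score bins of the latent
# Gaussian family. At shift 0 the score distribution is symmetric around 3.
.latentCuts <- c(-Inf, -2.5, -1.5, -0.5, 0.5, 1.5, 2.5, Inf)

# evaluate RNG-consuming code under a seed, leaving the caller's RNG intact
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# substream seed for gene g under master seed: a fixed affine map mod the
# Mersenne prime 2^31 - 1, so each gene owns an independent stream and
# appending genes never perturbs earlier genes' draws
.geneStreamSeed <- function(seed, g) {
  as.integer((as.numeric(seed) %% 2147483647) * 69069 + g * 104729) %% 2147483647L
}

#' The study cohort composition
#'
#' The default eight-group cohort: six malignant tumor groups whose adjacent
#' tissues are NTAC (hepatocellular carcinoma 26, rectal adenocarcinoma 48,
#' esophageal squamous cell carcinoma 34, gastric adenocarcinoma 66, thyroid
#' carcinoma 32, breast carcinoma 38) and two benign groups whose adjacent
#' tissues are NTAB (thyroid adenoma 32, breast fibroadenoma 38), totalling
#' 314 cases (244 NTAC / 70 NTAB).
#'
#' @return A [CohortDesign-class] with the eight groups above.
#' @examples
#' d <- defaultDesign()
#' sum(cohortClassCounts(d))  # 314
#' @export
defaultDesign <- function() {
  CohortDesign(data.frame(
    tissue = c("hepatocellular_carcinoma", "rectal_adenocarcinoma",
               "esophageal_squamous_cell_carcinoma", "gastric_adenocarcinoma",
               "thyroid_carcinoma", "breast_carcinoma",
               "thyroid_adenoma", "breast_fibroadenoma"),
    tumor_class = c(rep("malignant", 6), rep("benign", 2)),
    n_cases = c(26L, 48L, 34L, 66L, 32L, 38L, 32L, 38L)))
}

#' The 15-gene tumor-related screening panel
#'
#' @return Character vector of the 15 marker names, in panel order.
#' @examples
#' defaultPanel()
#' @export
defaultPanel <- function() {
  c("MYC", "CCND1", "TP53", "UVRAG", "RB1", "PTEN", "PTCH1", "BRCA1",
    "BRCA2", "FHIT", "BECN1", "BCL10", "APC", "CD82", "NME1-NME2")
}

#' Case counts of a cohort design by adjacent-tissue class
#'
#' @param design a [CohortDesign-class].
#' @return Named integer vector `c(NTAB = ..., NTAC = ...)`.
#' @export
cohortClassCounts <- function(design) {
  stopifnot(is(design, "CohortDesign"))
  g <- design@groups
  c(NTAB = sum(g$n_cases[g$tumor_class == "benign"]),
    NTAC = sum(g$n_cases[g$tumor_class == "malignant"]))
}

#' Tissue groups of a cohort design
#'
#' @param design a [CohortDesign-class].
#' @return The design's data.frame of groups.
#' @export
cohortGroups <- function(design) {
  stopifnot(is(design, "CohortDesign"))
  design@groups
}

#' Latent-Gaussian gene effect at a given shift
#'
#' Class-conditional score distributions obtained by discretizing a latent
#' Normal through the family's fixed cut points: NTAB scores come from
#' Normal(0, 1), NTAC scores from Normal(`shift`, 1). `shift = 0` gives the
#' null effect (identical distributions); increasing shift monotonically
#' increases [analyticAUC()].
#'
#' @param gene gene name.
#' @param shift latent mean shift of the NTAC class, in latent SD units.
#' @return A [GeneEffect-class].
#' @examples
#' analyticAUC(latentEffect("TP53", 0))    # 0.5
#' analyticAUC(latentEffect("TP53", 1.5))  # > 0.8
#' @export
latentEffect <- function(gene, shift) {
  stopifnot(is.numeric(shift), length(shift) == 1L, is.finite(shift))
  GeneEffect(gene,
             pNTAC = diff(pnorm(.latentCuts, mean = shift)),
             pNTAB = diff(pnorm(.latentCuts)))
}

#' Null gene effect (no class separation)
#'
#' @param gene gene name.
#' @return A [GeneEffect-class] with identical NTAC and NTAB distributions.
#' @export
nullEffect <- function(gene) latentEffect(gene, 0)

#' Exact pairwise AUC of a gene effect
#'
#' The probability that a random NTAC score exceeds a random NTAB score,
#' plus one half the probability of a tie (the Mann-Whitney form of the
#' ROC AUC), computed exactly by summing over the 7 x 7 score pairs.
#'
#' @param effect a [GeneEffect-class].
#' @return Probability in \[0.0, 1.0\].
#' @examples
#' analyticAUC(nullEffect("g"))  # 0.5
#' @rdname analyticAUC
#' @export
setMethod("analyticAUC", "GeneEffect", function(effect) {
  validObject(effect)
  pc <- effect@pNTAC
  pb <- effect@pNTAB
  joint <- outer(pc, pb)           # rows: NTAC score, cols: NTAB score
  sum(joint[lower.tri(joint)]) + 0.5 * sum(diag(joint))
})

#' Calibrate a gene effect to a target AUC
#'
#' Finds, by bisection on the latent shift of [latentEffect()]'s
#' one-parameter family, a [GeneEffect-class] whose exact pairwise AUC
#' ([analyticAUC()]) is within `tolerance` of `targetAUC`.
#'
#' @param gene gene name.
#' @param targetAUC target separability, in \[0.5, 1.0).
#' @param tolerance admissible absolute deviation of the achieved analytic
#'   AUC from the target (default 0.005).
#' @return A calibrated [GeneEffect-class].
#' @examples
#' e <- effectFromAUC("TP53", 0.87)
#' analyticAUC(e)  # within 0.005 of 0.87
#' @export
effectFromAUC <- function(gene, targetAUC, tolerance = 0.005) {
  stopifnot(is.numeric(targetAUC), length(targetAUC) == 1L,
            is.numeric(tolerance), tolerance > 0)
  if (targetAUC < 0.5 || targetAUC >= 1)
    stop("targetAUC must lie in [0.5, 1)")
  if (targetAUC == 0.5) return(latentEffect(gene, 0))
  aucAt <- function(s) analyticAUC(latentEffect(gene, s))
  lo <- 0; hi <- 12
  if (aucAt(hi) < targetAUC - tolerance)
    stop("calibration failure: target AUC ", targetAUC,
         " unreachable within the latent-shift family")
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    a <- aucAt(mid)
    if (abs(a - targetAUC) <= tolerance * 0.5) break
    if (a < targetAUC) lo <- mid else hi <- mid
  }
  eff <- latentEffect(gene, mid)
  if (abs(analyticAUC(eff) - targetAUC) > tolerance)
    stop("calibration failure: bisection did not reach target AUC ",
         targetAUC, " within tolerance ", tolerance)
  eff
}

#' A default effect panel
#'
#' One [GeneEffect-class] per panel gene: null effects everywhere except the
#' genes named in `auc`, which are calibrated to the given analytic AUCs.
#'
#' @param genes panel gene names (default [defaultPanel()]).
#' @param auc named numeric vector of target analytic AUCs for a subset of
#'   `genes`; unnamed genes get the null effect.
#' @param tolerance calibration tolerance passed to [effectFromAUC()].
#' @return List of [GeneEffect-class], one per gene, in panel order.
#' @examples
#' effs <- effectPanel(auc = c(TP53 = 0.87))
#' analyticAUC(effs[["TP53"]])
#' @export
effectPanel <- function(genes = defaultPanel(), auc = numeric(),
                        tolerance = 0.005) {
  if (length(auc) && (is.null(names(auc)) || !all(names(auc) %in% genes)))
    stop("names of 'auc' must be panel genes")
  effs <- lapply(genes, function(g) {
    if (g %in% names(auc)) effectFromAUC(g, auc[[g]], tolerance)
    else nullEffect(g)
  })
  names(effs) <- genes
  effs
}

#' Simulate a RISH score cohort
#'
#' Draws an integer score in 0--6 for every (sample, gene) pair,
#' independently, from the gene's NTAC- or NTAB-conditional distribution
#' according to the sample's adjacent-tissue class (derived from its tissue
#' group's tumor class). Class counts equal the design counts exactly; only
#' the scores are random. Each gene consumes its own RNG substream derived
#' from `seed`, so extending the effect panel leaves earlier genes' draws
#' untouched, and the caller's RNG state is never disturbed.
#'
#' @param design a [CohortDesign-class].
#' @param effects list of [GeneEffect-class], one per panel gene, no
#'   duplicates; gene order defines the row order of the result.
#' @param seed integer master seed; identical seeds give identical cohorts.
#' @param tissueEffect optional hook for per-tissue perturbations: a
#'   `function(effect, tissue)` returning the [GeneEffect-class] to use for
#'   samples of that tissue (default `NULL`: class alone determines the
#'   distribution).
#' @return A [RishScoreSet-class] with `sum(n_cases)` samples.
#' @examples
#' x <- simulateCohort(defaultDesign(), effectPanel(auc = c(TP53 = 0.87)),
#'                     seed = 1)
#' x
#' @export
simulateCohort <- function(design, effects, seed, tissueEffect = NULL) {
  stopifnot(is(design, "CohortDesign"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an integer 'seed' is required")
  if (!is.list(effects) || !all(vapply(effects, is, logical(1), "GeneEffect")))
    stop("'effects' must be a list of GeneEffect objects")
  lapply(effects, validObject)
  genes <- vapply(effects, function(e) e@gene, character(1))
  if (anyDuplicated(genes))
    stop("panel mismatch: duplicated gene effects for ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))

  g <- design@groups
  n <- sum(g$n_cases)
  tissue <- rep(g$tissue, g$n_cases)
  classLabel <- rep(ifelse(g$tumor_class == "malignant", "NTAC", "NTAB"),
                    g$n_cases)
  sampleIDs <- sprintf("sample_%03d", seq_len(n))

  scores <- matrix(0L, nrow = length(genes), ncol = n,
                   dimnames = list(genes, sampleIDs))
  isNTAC <- classLabel == "NTAC"
  for (j in seq_along(effects)) {
    eff <- effects[[j]]
    # one uniform per sample, in fixed sample order, inverted through the
    # class-conditional CDF; the uniform stream is identical across effect
    # panels, so changing one gene's effect never perturbs another's draws
    u <- .withSeed(.geneStreamSeed(seed, j), runif(n))
    if (is.null(tissueEffect)) {
      scores[j, isNTAC] <- findInterval(u[isNTAC], cumsum(eff@pNTAC))
      scores[j, !isNTAC] <- findInterval(u[!isNTAC], cumsum(eff@pNTAB))
    } else {
      for (i in seq_len(n)) {
        e <- tissueEffect(eff, tissue[i])
        stopifnot(is(e, "GeneEffect"))
        p <- if (isNTAC[i]) e@pNTAC else e@pNTAB
        scores[j, i] <- findInterval(u[i], cumsum(p))
      }
    }
  }
  RishScoreSet(scores, tissue = tissue, classLabel = classLabel,
               sampleIDs = sampleIDs)
}
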