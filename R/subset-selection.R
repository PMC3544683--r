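# Wrapper feature selection: grow gene subsets in filter-rank order from a
# single gene, scoring each subset by repeated stratified k-fold
# cross-validated AUC of a linear support vector machine (e1071/libsvm).
# Decision values (signed distance to the separating boundary), not hard
# labels, feed the AUC, so the measure keeps its ROC interpretation under
# the 244/70 class imbalance.

#' Mann-Whitney AUC from classifier scores
#'
#' The fraction of (positive, negative) score pairs where the positive
#' score is larger, counting ties one half — i.e., the area under the ROC
#' curve of a score-ordered classifier.
#'
#' @param posScores scores of the positive-class (NTAC) samples.
#' @param negScores scores of the negative-class (NTAB) samples.
#' @return Probability in \[0, 1\].
#' @examples
#' aucFromScores(c(0.9, 0.8), c(0.1, 0.2))  # 1
#' aucFromScores(c(3, 1), c(2, 0))          # 0.75
#' @export
aucFromScores <- function(posScores, negScores) {
  if (!length(posScores) || !length(negScores))
    stop("both score lists must be non-empty")
  np <- length(posScores)
  r <- rank(c(posScores, negScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(negScores))
}

#' Linear classifier configuration
#'
#' @param cost regularization strength C of the soft-margin linear SVM
#'   (default 1).
#' @param standardize center and scale each feature on the training fold
#'   before fitting (default `TRUE`).
#' @return List of class `"classifierSpec"`.
#' @export
classifierSpec <- function(cost = 1, standardize = TRUE) {
  stopifnot(is.numeric(cost), length(cost) == 1L, cost > 0)
  structure(list(kernel = "linear", cost = cost,
                 standardize = isTRUE(standardize)),
            class = "classifierSpec")
}

#' Cross-validation configuration
#'
#' @param nFolds number of folds (default 10).
#' @param nRepeats number of independent fold assignments (default 10).
#' @param stratified stratify folds by class label (default `TRUE`), so
#'   every fold contains both classes.
#' @param seed integer seed; repeat r derives its fold assignment from
#'   `seed + r`.
#' @return List of class `"cvSpec"`.
#' @export
cvSpec <- function(nFolds = 10L, nRepeats = 10L, stratified = TRUE,
                   seed = 1L) {
  stopifnot(nFolds >= 2L, nRepeats >= 1L, is.numeric(seed))
  structure(list(nFolds = as.integer(nFolds),
                 nRepeats = as.integer(nRepeats),
                 stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "cvSpec")
}

# Stratified fold assignment. Within each class, samples are taken in
# sample-ID order and folds permuted by the seeded RNG, so the assignment
# is a function of (sample IDs, labels, seed) only — permuting the row
# order of the input leaves each sample's fold unchanged.
.strataFolds <- function(classLabel, sampleIDs, nFolds, stratified = TRUE) {
  fold <- integer(length(classLabel))
  strata <- if (stratified) split(seq_along(classLabel), classLabel)
            else list(seq_along(classLabel))
  for (idx in strata) {
    idx <- idx[order(sampleIDs[idx])]
    fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  }
  fold
}

.sdFloor <- 1e-8

# train on the training rows, return decision values for the test rows,
# oriented so larger means more NTAC-like
.svmDecisionValues <- function(train, test, yTrain, classifier) {
  if (classifier$standardize) {
    mu <- colMeans(train)
    sg <- pmax(apply(train, 2L, sd), .sdFloor)
    train <- sweep(sweep(train, 2L, mu), 2L, sg, "/")
    test <- sweep(sweep(test, 2L, mu), 2L, sg, "/")
  }
  fit <- e1071::svm(train, yTrain, kernel = "linear",
                    cost = classifier$cost, scale = FALSE)
  dv <- attr(predict(fit, test, decision.values = TRUE), "decision.values")
  # libsvm orients decision values toward the class named first in the
  # "A/B" column label; flip when that class is NTAB
  if (startsWith(colnames(dv)[1L], "NTAB")) dv <- -dv
  as.numeric(dv)
}

#' Repeated cross-validated AUC of a gene subset
#'
#' Scores the discriminative ability of a gene subset: for each of
#' `cv$nRepeats` repeats, samples are assigned to `cv$nFolds` stratified
#' folds (repeat r seeded with `cv$seed + r`); each fold is held out once,
#' the classifier is trained on the remaining folds (standardizing features
#' on the training rows), and the held-out decision values are scored with
#' [aucFromScores()] (NTAC positive). A repeat's AUC is the mean over its
#' folds; the function returns the mean and SD over repeats. Deterministic
#' given `cv$seed`, and invariant to the order of samples in `x`.
#'
#' @param x a [RishScoreSet-class].
#' @param genes gene subset to evaluate (default: the full panel).
#' @param classifier a [classifierSpec()].
#' @param cv a [cvSpec()].
#' @return List with `meanAUC`, `sdAUC`, and `repeatAUC` (per-repeat
#'   values).
#' @examples
#' x <- simulateCohort(defaultDesign(), effectPanel(auc = c(TP53 = 0.9)),
#'                     seed = 1)
#' cvAUC(x, "TP53", cv = cvSpec(nRepeats = 2, seed = 1))$meanAUC
#' @export
cvAUC <- function(x, genes = panelGenes(x), classifier = classifierSpec(),
                  cv = cvSpec()) {
  stopifnot(is(x, "RishScoreSet"), inherits(classifier, "classifierSpec"),
            inherits(cv, "cvSpec"))
  if (!all(genes %in% panelGenes(x)))
    stop("unknown genes: ", paste(setdiff(genes, panelGenes(x)),
                                  collapse = ", "))
  y <- classLabels(x)
  ids <- colnames(x)
  counts <- table(y)
  if (any(counts < cv$nFolds))
    stop("each class needs at least nFolds = ", cv$nFolds,
         " samples (have NTAB ", counts[["NTAB"]],
         ", NTAC ", counts[["NTAC"]], ")")
  M <- t(rishScores(x)[genes, , drop = FALSE])
  storage.mode(M) <- "double"

  repeatAUC <- vapply(seq_len(cv$nRepeats), function(r) {
    fold <- .withSeed(cv$seed + r,
                      .strataFolds(y, ids, cv$nFolds, cv$stratified))
    foldAUC <- vapply(seq_len(cv$nFolds), function(k) {
      test <- fold == k
      dv <- .svmDecisionValues(M[!test, , drop = FALSE],
                               M[test, , drop = FALSE],
                               droplevels(y[!test]), classifier)
      aucFromScores(dv[y[test] == "NTAC"], dv[y[test] == "NTAB"])
    }, numeric(1))
    mean(foldAUC)
  }, numeric(1))
  list(meanAUC = mean(repeatAUC),
       sdAUC = if (length(repeatAUC) > 1L) sd(repeatAUC) else 0,
       repeatAUC = repeatAUC)
}

#' Cross-validated AUC of each gene alone
#'
#' Evaluates [cvAUC()] for every panel gene by itself, quantifying each
#' marker's individual ability to separate NTAC from NTAB.
#'
#' @inheritParams cvAUC
#' @return data.frame with columns `gene`, `mean_auc`, `sd_auc`, in panel
#'   order.
#' @export
singleGeneAUCs <- function(x, classifier = classifierSpec(),
                           cv = cvSpec()) {
  stopifnot(is(x, "RishScoreSet"))
  res <- lapply(panelGenes(x), function(g) {
    a <- cvAUC(x, g, classifier, cv)
    data.frame(gene = g, mean_auc = a$meanAUC, sd_auc = a$sdAUC)
  })
  do.call(rbind, res)
}

#' Filter-ranked incremental subset selection
#'
#' Starting from an empty gene group, genes are added one at a time in the
#' order produced by [rankGenes()] under the chosen filter criterion; the
#' group is re-scored by [cvAUC()] after every addition, until all genes
#' have been added. The result traces the nested subsets with their mean
#' and SD cross-validated AUC.
#'
#' @inheritParams cvAUC
#' @param criterion filter criterion passed to [rankGenes()].
#' @return A [SelectionTrace-class] of length equal to the panel size.
#' @examples
#' x <- simulateCohort(defaultDesign(), effectPanel(auc = c(TP53 = 0.9)),
#'                     seed = 1)
#' tr <- incrementalSelection(x, "wilcoxon", cv = cvSpec(nRepeats = 2))
#' bestSubset(tr)
#' @export
incrementalSelection <- function(x, criterion = .criteria,
                                 classifier = classifierSpec(),
                                 cv = cvSpec()) {
  criterion <- match.arg(criterion, .criteria)
  ranked <- rankGenes(x, criterion)$gene
  genes <- lapply(seq_along(ranked), function(k) ranked[seq_len(k)])
  aucs <- lapply(genes, function(g) cvAUC(x, g, classifier, cv))
  new("SelectionTrace", criterion = criterion, genes = genes,
      meanAUC = vapply(aucs, `[[`, numeric(1), "meanAUC"),
      sdAUC = vapply(aucs, `[[`, numeric(1), "sdAUC"))
}

#' Best gene subset of a selection trace
#'
#' The subset with the highest mean cross-validated AUC. Ties are resolved
#' toward the smaller subset, then toward the earlier trace position.
#'
#' @param trace a [SelectionTrace-class].
#' @return List with `genes`, `meanAUC`, `size` and `criterion`.
#' @rdname bestSubset
#' @export
setMethod("bestSubset", "SelectionTrace", function(trace) {
  if (!length(trace@genes)) stop("empty selection trace")
  sizes <- lengths(trace@genes)
  best <- which(trace@meanAUC == max(trace@meanAUC))
  best <- best[order(sizes[best], best)][1L]
  list(genes = trace@genes[[best]], meanAUC = trace@meanAUC[best],
       size = sizes[best], criterion = trace@criterion)
})
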