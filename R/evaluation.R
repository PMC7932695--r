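#' @include fit.R
NULL

.checkTwoClass <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2)
    stop("AUC needs at least one positive and one negative")
  labels
}

#' Rank-based AUC
#'
#' Mann-Whitney AUC with ties counted as half: the probability that a
#' random positive scores above a random negative, plus half the tie
#' probability. Equals the trapezoidal area under [rocCurve()].
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @examples
#' aucScore(c(0.9, 0.1), c(1, 0))  # 1
#' @export
aucScore <- function(scores, labels) {
  labels <- .checkTwoClass(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  rk <- rank(scores, ties.method = "average")
  (sum(rk[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve
#'
#' Sweeps thresholds over the unique scores in descending order; the curve
#' starts at (0, 0) and ends at (1, 1), tied scores moving diagonally in a
#' single step. The stored `auc` is the trapezoidal area, identical to
#' [aucScore()].
#'
#' @inheritParams aucScore
#' @return List of class `faidrROC` with elements `fpr`, `tpr`,
#'   `thresholds`, `auc`, `nPos`, `nNeg`.
#' @export
rocCurve <- function(scores, labels) {
  labels <- .checkTwoClass(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  npos <- sum(y == 1); nneg <- sum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)   # last index of each tie group
  tpr <- c(0, cumsum(y == 1)[last] / npos)
  fpr <- c(0, cumsum(y == 0)[last] / nneg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[last]), auc = auc,
                 nPos = npos, nNeg = nneg),
            class = "faidrROC")
}

#' @export
print.faidrROC <- function(x, ...) {
  cat("ROC curve:", length(x$fpr), "points; AUC =", round(x$auc, 4),
      "(Np =", x$nPos, ", Nn =", x$nNeg, ")\n")
  invisible(x)
}

## partition proteins into k folds; optionally stratified by label
.makeFolds <- function(proteins, y, k, seed, stratified = FALSE) {
  set.seed(seed)
  n <- length(proteins)
  if (stratified) {
    fold <- integer(n)
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  split(proteins, fold)
}

#' Protein-level k-fold cross-validation
#'
#' Randomly partitions proteins (never individual IDRs) into `k` folds,
#' fits the multiple-instance model on k-1 folds, scores held-out proteins
#' by the uniform-prior mixture over their IDRs ([predictProtein()]), and
#' reports the AUC per fold and its mean.
#'
#' @param features An [IdrFeatureTable-class].
#' @param annotations Per-protein labels (named vector or
#'   [AnnotationTable-class]).
#' @param functionName Function to evaluate.
#' @param k Number of folds (default 5).
#' @param control A [faidrControl()].
#' @param seed Integer seed for the fold assignment.
#' @param stratified Stratify folds by label to avoid single-class folds on
#'   rare annotations (default FALSE: simple random partition).
#' @param minPositives Refuse to evaluate functions with fewer positives
#'   (default 20).
#' @return List with `meanAuc`, `foldAucs`, `folds` (protein ids per fold).
#' @export
proteinCv <- function(features, annotations, functionName = "function",
                      k = 5, control = faidrControl(), seed = 1,
                      stratified = FALSE, minPositives = 20L) {
  y <- .resolveLabels(features, annotations, functionName)
  if (sum(y) < minPositives)
    stop("only ", sum(y), " positive protein(s); at least ", minPositives,
         " required to attempt evaluation (see minPositives=)")
  prot <- proteinIds(features)
  folds <- .makeFolds(prot, y[prot], k, seed, stratified)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds[[f]]
    train <- setdiff(prot, test)
    if (length(unique(y[train])) < 2 || length(unique(y[test])) < 2)
      stop("fold ", f, " has a single class; consider stratified = TRUE")
    fit <- fitFaidr(subsetByProteins(features, train), y[train],
                    functionName, control)
    p <- predictProtein(fit, subsetByProteins(features, test))
    aucs[f] <- aucScore(p, y[names(p)])
  }
  list(meanAuc = mean(aucs), foldAucs = aucs, folds = folds)
}

#' Held-out IDR-level evaluation
#'
#' Removes a fraction of proteins from training, fits the model to the
#' remaining proteins' protein-level labels, then scores each held-out IDR
#' independently ([predictIdr()]) and evaluates against IDR-level ground
#' truth (e.g. mapped phosphosites or targeting-signal coordinates). This
#' measures whether a model trained only on protein labels localizes
#' function to the correct IDR in unseen proteins.
#'
#' @inheritParams proteinCv
#' @param idrLabels Named 0/1 vector over IDR ids (see [mapSitesToIdrs()]);
#'   must cover the held-out IDRs.
#' @param fraction Fraction of proteins held out (default 0.2).
#' @return List with `roc` (a `faidrROC`), `auc`, `nPos` (count of
#'   positive held-out IDRs), `heldoutProteins`, `fit`.
#' @export
heldoutIdrEval <- function(features, annotations, functionName = "function",
                           idrLabels, fraction = 0.2,
                           control = faidrControl(), seed = 1) {
  y <- .resolveLabels(features, annotations, functionName)
  prot <- proteinIds(features)
  set.seed(seed)
  heldout <- sample(prot, size = max(1L, round(fraction * length(prot))))
  train <- setdiff(prot, heldout)
  fit <- fitFaidr(subsetByProteins(features, train), y[train],
                  functionName, control)
  testTab <- subsetByProteins(features, heldout)
  scores <- predictIdr(fit, testTab)
  miss <- setdiff(names(scores), names(idrLabels))
  if (length(miss))
    stop("IDR labels do not cover ", length(miss), " held-out IDR(s)")
  truth <- idrLabels[names(scores)]
  if (sum(truth) == 0)
    stop("no positive IDR in the held-out set; change seed or fraction")
  roc <- rocCurve(scores, truth)
  list(roc = roc, auc = roc$auc, nPos = sum(truth),
       heldoutProteins = heldout, fit = fit)
}
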