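#' @include AllClasses.R
NULL

## linear predictor clipped before exponentiation; log arguments clamped
.ETA_CLIP <- 700
.LOG_CLAMP <- 1e-12

.clip_eta <- function(eta) pmin(pmax(eta, -.ETA_CLIP), .ETA_CLIP)

.clog <- function(x) log(pmax(x, .LOG_CLAMP))

## resolve per-protein labels: named 0/1 vector, or AnnotationTable + function
.resolveLabels <- function(features, labels, functionName = NULL) {
  prot <- proteinIds(features)
  if (is(labels, "AnnotationTable")) {
    if (is.null(functionName))
      stop("functionName is required when labels is an AnnotationTable")
    if (!functionName %in% functionNames(labels))
      stop("unknown function: ", functionName)
    lab <- annotationMatrix(labels)[, functionName]
    extra <- setdiff(names(lab), prot)
    if (length(extra))
      message(length(extra),
              " annotated protein(s) have no IDR row and are dropped")
    miss <- setdiff(prot, names(lab))
    if (length(miss))
      stop(length(miss), " protein(s) in the feature table lack annotations, ",
           "e.g. ", miss[1])
    lab <- lab[prot]
  } else {
    lab <- labels
    if (!is.null(names(lab))) {
      miss <- setdiff(prot, names(lab))
      if (length(miss))
        stop(length(miss), " protein(s) lack labels, e.g. ", miss[1])
      lab <- lab[prot]
    } else if (length(lab) != length(prot)) {
      stop("unnamed label vector must have one entry per protein")
    }
  }
  lab <- as.numeric(lab)
  if (!all(lab %in% c(0, 1))) stop("labels must be binary 0/1")
  setNames(lab, prot)
}

#' Logistic probability of a function given IDR features
#'
#' Computes \eqn{h = 1 / (1 + e^{-(z b + b_0)})}, the probability that an
#' IDR with feature vector z carries the function, numerically stable for
#' linear predictors up to +/-700.
#'
#' @param z Numeric feature vector, or a matrix with one IDR per row.
#' @param b Coefficient vector, same length as `z` (or `ncol(z)`).
#' @param intercept Scalar intercept (default 0).
#' @return Probability in (0, 1); a vector when `z` is a matrix.
#' @examples
#' logisticProbability(c(1, 1), c(log(3) / 2, log(3) / 2))  # 0.75
#' @export
logisticProbability <- function(z, b, intercept = 0) {
  if (is.matrix(z)) {
    if (ncol(z) != length(b))
      stop("dimension mismatch: ", ncol(z), " features vs ", length(b),
           " coefficients")
    eta <- drop(z %*% b) + intercept
  } else {
    if (length(z) != length(b))
      stop("dimension mismatch: ", length(z), " features vs ", length(b),
           " coefficients")
    eta <- sum(z * b) + intercept
  }
  plogis(.clip_eta(eta))
}

## per-IDR h for a feature table
.idrProbs <- function(features, b, intercept) {
  logisticProbability(featureMatrix(features), b, intercept)
}

#' Marginal log-likelihood of protein labels under the hidden-IDR model
#'
#' For each protein the hidden indicator of which IDR carries the function
#' is marginalized: the protein term is
#' \eqn{\log \sum_j P(X_{ij}=1)\, h(Z_{ij})^{Y_i} (1-h(Z_{ij}))^{1-Y_i}},
#' and the total is the sum over proteins.
#'
#' @param features An [IdrFeatureTable-class].
#' @param labels Per-protein 0/1 labels (named vector, or
#'   [AnnotationTable-class] with `functionName`).
#' @param b,intercept Model parameters.
#' @param prior Optional per-IDR prior \eqn{P(X_{ij}=1)} (named by IDR id or
#'   in row order) summing to 1 within each protein; default uniform
#'   \eqn{1/r_i}.
#' @param functionName Function column when `labels` is an AnnotationTable.
#' @return Scalar log-likelihood.
#' @export
marginalLogLikelihood <- function(features, labels, b, intercept = 0,
                                  prior = NULL, functionName = NULL) {
  y <- .resolveLabels(features, labels, functionName)
  prot <- idrProtein(features)
  h <- .idrProbs(features, b, intercept)
  if (is.null(prior)) {
    r <- idrCounts(features)
    prior <- 1 / r[prot]
  } else {
    if (!is.null(names(prior))) prior <- prior[idrIds(features)]
    sums <- tapply(prior, prot, sum)
    if (any(abs(sums - 1) > 1e-8))
      stop("prior must sum to 1 within each protein (tol 1e-8)")
  }
  yrow <- y[prot]
  lik <- prior * ifelse(yrow == 1, h, 1 - h)
  sum(.clog(tapply(lik, factor(prot, levels = unique(prot)), sum)))
}

#' Expected complete-data log-likelihood
#'
#' The EM lower-bound term
#' \eqn{\sum_i \sum_j \langle X_{ij}\rangle [Y_i \log h(Z_{ij}) +
#' (1-Y_i)\log(1-h(Z_{ij}))]}, with log arguments clamped at the weight
#' floor for numerical safety. With a single IDR per protein and
#' responsibility 1 it reduces to the ordinary logistic log-likelihood.
#'
#' @inheritParams marginalLogLikelihood
#' @param responsibilities Per-IDR responsibilities (row order or named by
#'   IDR id), summing to 1 within each protein.
#' @param weightFloor Clamp for log arguments (default 1e-8).
#' @return Scalar expected complete log-likelihood.
#' @export
expectedCompleteLogLikelihood <- function(features, labels, b, intercept = 0,
                                          responsibilities,
                                          weightFloor = 1e-8,
                                          functionName = NULL) {
  y <- .resolveLabels(features, labels, functionName)
  prot <- idrProtein(features)
  if (!is.null(names(responsibilities)))
    responsibilities <- responsibilities[idrIds(features)]
  sums <- tapply(responsibilities, prot, sum)
  if (any(abs(sums - 1) > 1e-8))
    stop("responsibilities must sum to 1 within each protein")
  h <- .idrProbs(features, b, intercept)
  yrow <- y[prot]
  sum(responsibilities *
        (yrow * log(pmax(h, weightFloor)) +
         (1 - yrow) * log(pmax(1 - h, weightFloor))))
}

#' E-step: posterior responsibility of each IDR
#'
#' By Bayes' theorem with a uniform prior over the IDRs of each protein,
#' \deqn{\langle X_{ij}\rangle = \frac{Y_i h(Z_{ij}) + (1-Y_i)(1-h(Z_{ij}))}
#' {\sum_k Y_i h(Z_{ik}) + (1-Y_i)(1-h(Z_{ik}))}.}
#' Rows sum to 1 within each protein; a protein with a single IDR gets
#' responsibility 1.
#'
#' @inheritParams marginalLogLikelihood
#' @return Numeric vector named by IDR id.
#' @export
eStep <- function(features, labels, b, intercept = 0, functionName = NULL) {
  y <- .resolveLabels(features, labels, functionName)
  prot <- idrProtein(features)
  h <- .idrProbs(features, b, intercept)
  yrow <- y[prot]
  lik <- ifelse(yrow == 1, h, 1 - h)
  denom <- tapply(lik, factor(prot, levels = unique(prot)), sum)[prot]
  stopifnot(all(denom > 0))  # impossible for h in (0,1)
  setNames(as.numeric(lik / denom), idrIds(features))
}

#' Modified IRLS weights
#'
#' The per-IDR quadratic weight of the reweighted least-squares update,
#' \eqn{w_{ij} = \langle X_{ij}\rangle h(Z_{ij}) (1 - h(Z_{ij}))}, floored
#' at `weightFloor` so that saturated probabilities (h near 0 or 1) cannot
#' zero out an observation.
#'
#' @param responsibilities Per-IDR responsibilities.
#' @param h Per-IDR logistic probabilities, aligned with
#'   `responsibilities`.
#' @param weightFloor Minimum weight (default 1e-8).
#' @return Numeric weight vector.
#' @examples
#' irlsWeights(1, 0.5)    # 0.25
#' irlsWeights(0.5, 0.2)  # 0.08
#' @export
irlsWeights <- function(responsibilities, h, weightFloor = 1e-8) {
  stopifnot(length(responsibilities) == length(h), weightFloor > 0)
  pmax(responsibilities * h * (1 - h), weightFloor)
}
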