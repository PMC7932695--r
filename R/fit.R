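#' @include model.R
NULL

#' Control parameters for the EM fit
#'
#' @param lambda Elastic-net penalty strength (default 0.2, the fixed value
#'   used throughout; strong regularization suited to functions with few
#'   positive examples).
#' @param alpha Elastic-net mixing: `alpha = 1` is pure L1; the default
#'   0.99 adds a small L2 ridge for numerical stability of IRLS.
#' @param irlsIterations IRLS iterations per M-step (default 5; the M-step
#'   is deliberately truncated, not run to convergence).
#' @param maxEmIterations Cap on EM rounds (default 100).
#' @param emTolerance Stop when the maximum absolute change in any
#'   responsibility falls below this (default 1e-4).
#' @param weightFloor Replacement for IRLS weights that reach 0
#'   (default 1e-8).
#' @param includeIntercept Fit an unpenalized intercept (default TRUE).
#' @param minPositives Refuse to fit a function with fewer positive
#'   proteins than this (default 5).
#' @param standardize Re-standardize feature columns internally before
#'   fitting (default FALSE: inputs such as evolutionary-signature Z-scores
#'   are already on a standard scale, and re-scaling would double-scale
#'   them).
#' @param seed Optional integer seed recorded with the fit (the EM itself
#'   is deterministic).
#' @return A list of class `faidrControl`.
#' @export
faidrControl <- function(lambda = 0.2, alpha = 0.99, irlsIterations = 5L,
                         maxEmIterations = 100L, emTolerance = 1e-4,
                         weightFloor = 1e-8, includeIntercept = TRUE,
                         minPositives = 5L, standardize = FALSE,
                         seed = NA_integer_) {
  stopifnot(lambda > 0, alpha > 0, alpha <= 1, irlsIterations >= 1,
            maxEmIterations >= 1, emTolerance > 0, weightFloor > 0)
  structure(list(lambda = lambda, alpha = alpha,
                 irlsIterations = as.integer(irlsIterations),
                 maxEmIterations = as.integer(maxEmIterations),
                 emTolerance = emTolerance, weightFloor = weightFloor,
                 includeIntercept = isTRUE(includeIntercept),
                 minPositives = as.integer(minPositives),
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "faidrControl")
}

## elastic-net penalty value lambda * (alpha |b|_1 + (1-alpha)/2 |b|_2^2)
.enetPenalty <- function(b, lambda, alpha) {
  lambda * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
}

#' Elastic-net penalized weighted logistic regression by truncated IRLS
#'
#' Runs `control$irlsIterations` iterations of iteratively reweighted least
#' squares for the observation-weighted logistic log-likelihood under a
#' glmnet-style elastic-net penalty,
#' \deqn{-\frac{1}{W}\sum_i w_i \ell_i(b_0, b) +
#'   \lambda(\alpha \|b\|_1 + \tfrac{1-\alpha}{2}\|b\|_2^2),}
#' where observation weights are normalized to sum to the number of rows
#' (W) and the intercept is unpenalized. Each IRLS iteration solves the
#' penalized weighted least-squares subproblem exactly by coordinate
#' descent; quadratic weights `w_i p_i (1 - p_i)` are floored at
#' `control$weightFloor`. During the EM fit the observation weights are the
#' responsibilities, so the quadratic weight is exactly the modified
#' responsibility-weighted IRLS weight.
#'
#' @param x Numeric design matrix (rows = observations).
#' @param y 0/1 response per row.
#' @param weights Nonnegative observation weights (default 1).
#' @param control A [faidrControl()].
#' @param warmStart Optional list with elements `b` and `intercept` to
#'   start from (default zero).
#' @return List with `coefficients` (named by column), `intercept`,
#'   `iterations` performed, and `objective` (the penalized objective at
#'   the returned parameters).
#' @export
weightedPenalizedLogistic <- function(x, y, weights = NULL,
                                      control = faidrControl(),
                                      warmStart = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  y <- as.numeric(y)
  stopifnot(length(y) == n, all(y %in% c(0, 1)))
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), any(weights > 0))
  w <- weights * n / sum(weights)   # normalize to sum to n
  if (control$standardize) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, sd)
    sdv[sdv == 0] <- 1
    x <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  }
  b <- rep(0, ncol(x))
  b0 <- 0
  if (!is.null(warmStart)) {
    if (!is.null(warmStart$b)) b <- as.numeric(warmStart$b)
    if (!is.null(warmStart$intercept)) b0 <- as.numeric(warmStart$intercept)
  }
  iters <- 0L
  for (it in seq_len(control$irlsIterations)) {
    eta <- .clip_eta(drop(x %*% b) + b0)
    p <- plogis(eta)
    pq <- p * (1 - p)
    v <- pmax(w * pq, control$weightFloor)
    z <- eta + (y - p) / pmax(pq, .LOG_CLAMP)
    sol <- cd_enet(x, z, v, control$lambda, control$alpha, b0, b,
                   control$includeIntercept, 1e-10, 1000L)
    if (!all(is.finite(sol$b)) || !is.finite(sol$b0))
      stop("non-finite coefficients at IRLS iteration ", it)
    delta <- max(abs(sol$b - b), abs(sol$b0 - b0))
    b <- sol$b
    b0 <- sol$b0
    iters <- it
    if (delta < 1e-10) break   # fixed point reached; further passes no-op
  }
  if (control$standardize) {
    b <- b / sdv
    b0 <- b0 - sum(b * mu)
  }
  eta <- .clip_eta(drop(x %*% b) + b0)
  ll <- sum(w * (y * .clog(plogis(eta)) + (1 - y) * .clog(plogis(-eta)))) / n
  list(coefficients = setNames(as.numeric(b), colnames(x)),
       intercept = b0, iterations = iters,
       objective = -ll + .enetPenalty(b, control$lambda, control$alpha))
}

#' Fit the multiple-instance penalized logistic model for one function
#'
#' Alternates an M-step (truncated IRLS elastic-net logistic regression on
#' the per-IDR rows, each row weighted by its current responsibility and
#' carrying its protein's label, warm-started from the previous round) with
#' an E-step (posterior responsibilities by Bayes' theorem), starting from
#' uniform responsibilities \eqn{1/r_i}. Stops when the largest absolute
#' responsibility change falls below `control$emTolerance` or after
#' `control$maxEmIterations` rounds. The penalized marginal log-likelihood
#' (marginal log-likelihood divided by the number of proteins, minus the
#' elastic-net penalty) is recorded at initialization and after every
#' round.
#'
#' @param features An [IdrFeatureTable-class].
#' @param labels Per-protein 0/1 labels: a named vector, or an
#'   [AnnotationTable-class] together with `functionName`.
#' @param functionName Name of the function being fitted (required when
#'   `labels` is an AnnotationTable; otherwise used as a tag).
#' @param control A [faidrControl()].
#' @return A [FaidrFit-class].
#' @examples
#' sim <- generateSynthetic(nProteins = 60, mFeatures = 5, supportSize = 2,
#'                          seed = 1)
#' fit <- fitFaidr(sim@featureTable, sim@annotations, "synthetic")
#' coef(fit)
#' @export
fitFaidr <- function(features, labels, functionName = "function",
                     control = faidrControl()) {
  stopifnot(is(features, "IdrFeatureTable"))
  y <- .resolveLabels(features, labels, functionName)
  npos <- sum(y == 1)
  if (npos < control$minPositives)
    stop("only ", npos, " positive protein(s); at least ",
         control$minPositives, " required (see faidrControl(minPositives=))")
  if (all(y == 1)) stop("at least one negative protein is required")
  x <- featureMatrix(features)
  prot <- idrProtein(features)
  yrow <- y[prot]
  r <- idrCounts(features)
  resp <- setNames(as.numeric(1 / r[prot]), idrIds(features))

  trace <- numeric()
  pen <- function(b, b0) {
    marginalLogLikelihood(features, y, b, b0) / length(y) -
      .enetPenalty(b, control$lambda, control$alpha)
  }
  b <- rep(0, ncol(x))
  b0 <- 0
  trace[1] <- pen(b, b0)
  converged <- FALSE
  nEm <- 0L
  for (em in seq_len(control$maxEmIterations)) {
    m <- weightedPenalizedLogistic(x, yrow, weights = resp, control = control,
                                   warmStart = list(b = b, intercept = b0))
    b <- as.numeric(m$coefficients)
    b0 <- m$intercept
    newResp <- eStep(features, y, b, b0)
    delta <- max(abs(newResp - resp))
    resp <- newResp
    nEm <- em
    trace[em + 1] <- pen(b, b0)
    if (delta < control$emTolerance) { converged <- TRUE; break }
  }
  new("FaidrFit",
      functionName = functionName,
      coefficients = setNames(b, colnames(x)),
      intercept = b0,
      responsibilities = resp,
      proteinId = as.character(prot),
      lambda = control$lambda,
      alpha = control$alpha,
      nEmIterations = nEm,
      converged = converged,
      objectiveTrace = trace,
      control = unclass(control))
}

.checkFeatureMatch <- function(object, features) {
  fn <- featureNames(features)
  if (!identical(fn, names(object@coefficients))) {
    if (!all(names(object@coefficients) %in% fn))
      stop("feature table lacks feature(s) used by the fit")
    if (!all(fn %in% names(object@coefficients)))
      stop("feature table has unknown feature column(s): ",
           paste(head(setdiff(fn, names(object@coefficients)), 3),
                 collapse = ", "))
  }
  featureMatrix(features)[, names(object@coefficients), drop = FALSE]
}

#' @rdname predict-generics
#' @export
setMethod("predictIdr", "FaidrFit", function(object, features, ...) {
  x <- .checkFeatureMatch(object, features)
  setNames(logisticProbability(x, object@coefficients, object@intercept),
           idrIds(features))
})

#' @rdname predict-generics
#' @export
setMethod("predictProtein", "FaidrFit", function(object, features, ...) {
  h <- predictIdr(object, features)
  prot <- idrProtein(features)
  means <- tapply(h, factor(prot, levels = unique(prot)), mean)
  setNames(as.numeric(means), names(means))
})
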