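#' @include fit.R
NULL

#' t-statistics from an unpenalized logistic refit on selected features
#'
#' Takes the features that received nonzero coefficients in the penalized
#' fit, refits a standard (unpenalized) logistic regression on that subset,
#' and returns the Wald t-statistic (coefficient / standard error from the
#' weighted Fisher information) for every feature, with exactly 0 for
#' features outside the subset. The refit design has one row per IDR, each
#' row carrying its protein's label; by default rows are weighted by the
#' fit's final responsibilities (so a protein's label mass concentrates on
#' the IDR inferred to carry the function). Alternatively
#' `rows = "max-responsibility"` keeps only the highest-responsibility IDR
#' of each protein with unit weight.
#'
#' Quasi-separation (non-convergence of the refit) yields capped statistics
#' `sign(coefficient) * tCap` and sets the `"separation"` attribute.
#'
#' @param features An [IdrFeatureTable-class].
#' @param labels Per-protein labels (named vector or
#'   [AnnotationTable-class]).
#' @param fit The penalized [FaidrFit-class] whose support defines the
#'   subset.
#' @param rows `"responsibility"` (default) or `"max-responsibility"`.
#' @param tCap Cap applied under quasi-separation (default 50).
#' @param functionName Function column when `labels` is an AnnotationTable;
#'   defaults to the fit's function.
#' @return Named numeric vector of t-statistics over all features of the
#'   fit (zero outside the selected subset), with attribute `"selected"`
#'   (logical) and `"separation"` (logical flag).
#' @export
refitTstats <- function(features, labels, fit,
                        rows = c("responsibility", "max-responsibility"),
                        tCap = 50, functionName = NULL) {
  rows <- match.arg(rows)
  stopifnot(is(fit, "FaidrFit"))
  if (is.null(functionName)) functionName <- fit@functionName
  y <- .resolveLabels(features, labels, functionName)
  allFeat <- names(fit@coefficients)
  out <- setNames(numeric(length(allFeat)), allFeat)
  sel <- fit@coefficients != 0
  attr(out, "selected") <- setNames(sel, allFeat)
  attr(out, "separation") <- FALSE
  if (!any(sel)) return(out)

  x <- featureMatrix(features)[, allFeat[sel], drop = FALSE]
  prot <- idrProtein(features)
  yrow <- y[prot]
  resp <- fit@responsibilities[idrIds(features)]
  if (rows == "max-responsibility") {
    keep <- as.logical(stats::ave(resp, prot,
                                  FUN = function(v) seq_along(v) ==
                                    which.max(v)))
    x <- x[keep, , drop = FALSE]
    yrow <- yrow[keep]
    w <- rep(1, sum(keep))
  } else {
    w <- as.numeric(resp)
  }
  xm <- unname(as.matrix(x))
  separated <- FALSE
  g <- withCallingHandlers(
    glm(yrow ~ xm, family = binomial(), weights = w),
    warning = function(wn) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(wn)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- coef(g)[-1]           # drop intercept; order follows columns of x
  se <- sqrt(diag(vcov(g)))[-1]
  t <- co / se
  # saturated linear predictors are the reliable symptom of separation:
  # glm can report convergence with astronomically inflated standard errors
  if (max(abs(predict(g))) > 15) separated <- TRUE
  if (separated || !g$converged || any(!is.finite(t)) || any(abs(t) > tCap)) {
    t <- sign(co) * tCap      # direction survives; magnitude is meaningless
    t[is.na(t)] <- 0          # aliased column
    attr(out, "separation") <- TRUE
  }
  out[allFeat[sel]] <- as.numeric(t)
  out
}

#' Assemble per-function t-statistic vectors into an association matrix
#'
#' Rows are functions, columns are features in the order of the first
#' vector (all vectors must cover the same features); entries for
#' unselected features are exactly zero.
#'
#' @param tlist Named list of t-statistic vectors as returned by
#'   [refitTstats()].
#' @return An [AssociationMatrix-class].
#' @export
assembleMatrix <- function(tlist) {
  stopifnot(is.list(tlist), length(tlist) >= 1)
  if (is.null(names(tlist)) || anyDuplicated(names(tlist)) ||
      any(names(tlist) == ""))
    stop("tlist must have unique, non-empty function names")
  feat <- names(tlist[[1]])
  m <- do.call(rbind, lapply(tlist, function(v) {
    if (!setequal(names(v), feat)) stop("feature sets differ across functions")
    as.numeric(v[feat])
  }))
  dimnames(m) <- list(names(tlist), feat)
  sel <- do.call(rbind, lapply(tlist, function(v) {
    s <- attr(v, "selected")
    if (is.null(s)) v[feat] != 0 else as.logical(s[feat])
  }))
  dimnames(sel) <- dimnames(m)
  new("AssociationMatrix", tstatistics = m, selected = sel)
}

#' Filter features of an association matrix by t-statistic threshold
#'
#' Keeps feature columns whose maximum t-statistic over functions is at
#' least `threshold` (inclusive). The default `"signed"` mode uses the
#' signed statistic (a column whose only large statistics are negative is
#' dropped); `"absolute"` uses `|t|`.
#'
#' @param x An [AssociationMatrix-class].
#' @param threshold Positive threshold (default 3).
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return A filtered [AssociationMatrix-class].
#' @export
filterFeatures <- function(x, threshold = 3, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  stopifnot(is(x, "AssociationMatrix"), threshold > 0)
  m <- x@tstatistics
  stat <- if (mode == "absolute") abs(m) else m
  keep <- apply(stat, 2, max) >= threshold
  new("AssociationMatrix",
      tstatistics = m[, keep, drop = FALSE],
      selected = x@selected[, keep, drop = FALSE])
}

#' Uncentered correlation distance
#'
#' \eqn{d(x, y) = 1 - \sum_i x_i y_i / (\|x\| \|y\|)}, ranging over
#' \eqn{[0, 2]}; unlike Pearson distance the vectors are not centered, so
#' sign patterns matter. With a matrix argument, returns the `dist` object
#' over rows.
#'
#' @param x Numeric vector, or a matrix whose rows are compared.
#' @param y Second vector (ignored when `x` is a matrix).
#' @return Scalar distance, or a `stats::dist` over matrix rows.
#' @export
uncenteredCorrelationDistance <- function(x, y = NULL) {
  if (is.matrix(x)) {
    nrm <- sqrt(rowSums(x^2))
    if (any(nrm == 0)) stop("zero-norm row in distance computation")
    s <- (x / nrm) %*% t(x / nrm)
    d <- 1 - s
    d[d < 0] <- 0   # guard tiny negative rounding
    return(as.dist(d))
  }
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm vector in distance computation")
  1 - sum(x * y) / (nx * ny)
}

#' Hierarchically cluster an association matrix
#'
#' Average-linkage agglomerative clustering under uncentered correlation
#' distance, over the rows (functions) or columns (features).
#'
#' @param x An [AssociationMatrix-class] or numeric matrix.
#' @param axis `"rows"` or `"columns"`.
#' @param linkage Agglomeration method (default `"average"`).
#' @return The `stats::hclust` object (leaf order in `$order`, labels in
#'   `$labels`).
#' @export
hierarchicalCluster <- function(x, axis = c("rows", "columns"),
                                linkage = "average") {
  axis <- match.arg(axis)
  m <- if (is(x, "AssociationMatrix")) x@tstatistics else as.matrix(x)
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 2) stop("need at least 2 items to cluster")
  hclust(uncenteredCorrelationDistance(m), method = linkage)
}

#' Write a clustered t-statistic table (CDT-like text)
#'
#' Emits the association matrix with rows (functions) and columns
#' (features) reordered by their dendrograms, in the clustered-data-table
#' layout (GID / UNIQID / NAME / GWEIGHT header columns) consumable by
#' standard tree viewers. With fewer than 2 rows or columns on an axis,
#' that axis keeps its input order.
#'
#' @param x An [AssociationMatrix-class].
#' @param path Output path (conventionally `.cdt`).
#' @return Invisibly, a list with the row and column `hclust` objects (or
#'   `NULL` where an axis was too small to cluster).
#' @export
writeClusteredTable <- function(x, path) {
  stopifnot(is(x, "AssociationMatrix"))
  m <- x@tstatistics
  hr <- if (nrow(m) >= 2) hierarchicalCluster(x, "rows") else NULL
  hc <- if (ncol(m) >= 2) hierarchicalCluster(x, "columns") else NULL
  ro <- if (is.null(hr)) seq_len(nrow(m)) else hr$order
  co <- if (is.null(hc)) seq_len(ncol(m)) else hc$order
  m <- m[ro, co, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("GID", "UNIQID", "NAME", "GWEIGHT", colnames(m)),
                   collapse = "\t"), con)
  writeLines(paste(c("EWEIGHT", "", "", "", rep("1", ncol(m))),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(paste0("GENE", i, "X"), rownames(m)[i],
                       rownames(m)[i], "1",
                       format(m[i, ], digits = 10, trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(list(rows = hr, columns = hc))
}
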