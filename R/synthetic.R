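#' @include AllClasses.R fit.R evaluation.R
NULL

#' Generate a synthetic multiple-instance dataset
#'
#' Draws data with exactly the generative structure the multiple-instance
#' model assumes: for each protein i, the number of IDRs \eqn{r_i} is
#' drawn from `idrCounts` (uniform on 1..4 by default), feature vectors
#' \eqn{Z_{ij}} are i.i.d. standard normal per feature (mimicking Z-score
#' signatures; set `rho > 0` for exchangeable within-row feature
#' correlation), a responsible IDR \eqn{j^*} is drawn uniformly, and the
#' protein label is Bernoulli with the logistic probability of the
#' responsible IDR's features only. The truth (sparse coefficient vector,
#' intercept, responsible index) is stored for recovery analyses.
#'
#' @param nProteins Number of proteins (default 2000).
#' @param mFeatures Number of features (default 164, the signature width).
#' @param idrCounts Values the per-protein IDR count is drawn from,
#'   uniformly (default 1:4).
#' @param supportSize Number of truly nonzero coefficients (default 10).
#' @param effectSize Magnitude of each true coefficient; signs are
#'   randomized per feature (default 2).
#' @param intercept True intercept (default -1, giving a realistic
#'   minority of positives).
#' @param rho Exchangeable within-IDR feature correlation (default 0).
#' @param seed Integer seed; one root generator governs every draw.
#' @param trueCoefficients Optional coefficient vector of length
#'   `mFeatures` to generate from instead of drawing a random support
#'   (used to draw fresh evaluation data from the same truth).
#' @return A [SyntheticIdrDataset-class].
#' @examples
#' sim <- generateSynthetic(nProteins = 50, mFeatures = 8, supportSize = 2,
#'                          seed = 7)
#' sim
#' @export
generateSynthetic <- function(nProteins = 2000, mFeatures = 164,
                              idrCounts = 1:4, supportSize = 10,
                              effectSize = 2, intercept = -1, rho = 0,
                              seed = 1, trueCoefficients = NULL) {
  stopifnot(nProteins >= 10, supportSize <= mFeatures, rho >= 0, rho < 1)
  set.seed(seed)
  prot <- sprintf("P%05d", seq_len(nProteins))
  r <- idrCounts[sample.int(length(idrCounts), nProteins, replace = TRUE)]
  protRow <- rep(prot, r)
  nrow <- length(protRow)
  z <- matrix(rnorm(nrow * mFeatures), nrow, mFeatures)
  if (rho > 0) {
    u <- rnorm(nrow)
    z <- sqrt(rho) * u + sqrt(1 - rho) * z
  }
  colnames(z) <- sprintf("f%03d", seq_len(mFeatures))
  if (is.null(trueCoefficients)) {
    support <- sort(sample(mFeatures, supportSize))
    b <- setNames(numeric(mFeatures), colnames(z))
    b[support] <- effectSize * sample(c(-1, 1), supportSize, replace = TRUE)
  } else {
    stopifnot(length(trueCoefficients) == mFeatures)
    b <- setNames(as.numeric(trueCoefficients), colnames(z))
  }
  jstar <- setNames(vapply(r, function(ri) sample.int(ri, 1L), 1L), prot)
  ## row index of the responsible IDR of each protein
  first <- c(1L, head(cumsum(r), -1) + 1L)
  respRow <- first + jstar - 1L
  h <- logisticProbability(z[respRow, , drop = FALSE], b, intercept)
  y <- rbinom(nProteins, 1L, h)
  tab <- IdrFeatureTable(z, proteinId = protRow)
  ann <- AnnotationTable(matrix(y, ncol = 1,
                                dimnames = list(prot, "synthetic")))
  new("SyntheticIdrDataset", featureTable = tab, annotations = ann,
      trueCoefficients = b, trueIntercept = intercept,
      trueResponsible = jstar,
      spec = list(nProteins = nProteins, mFeatures = mFeatures,
                  idrCounts = idrCounts, supportSize = supportSize,
                  effectSize = effectSize, intercept = intercept,
                  rho = rho, seed = seed))
}

#' Ground-truth recovery report for a fit on synthetic data
#'
#' Summarizes how well a fitted model recovered the generator's truth:
#' support precision/recall (nonzero estimated coefficients vs the true
#' support), sign agreement on the correctly recovered support features,
#' top-1 responsibility accuracy among positive proteins with at least two
#' IDRs (does the highest-responsibility IDR match the generating one),
#' and held-out protein-level AUC on a fresh draw from the same generator
#' spec (seed offset by `freshSeedOffset`).
#'
#' @param dataset The [SyntheticIdrDataset-class] the fit was trained on.
#' @param fit A [FaidrFit-class] trained on `dataset`.
#' @param freshSeedOffset Offset added to the generator seed for the
#'   held-out draw (default 1).
#' @return List with `supportPrecision`, `supportRecall`, `signAgreement`,
#'   `top1Accuracy`, `heldoutAuc`, `nSelected`. Precision and sign
#'   agreement are `NA` when no feature was selected; `top1Accuracy` is
#'   `NA` when no positive protein has 2+ IDRs.
#' @export
recoveryReport <- function(dataset, fit, freshSeedOffset = 1) {
  stopifnot(is(dataset, "SyntheticIdrDataset"), is(fit, "FaidrFit"))
  bTrue <- dataset@trueCoefficients
  bHat <- fit@coefficients[names(bTrue)]
  trueSupp <- names(bTrue)[bTrue != 0]
  estSupp <- names(bHat)[bHat != 0]
  nSel <- length(estSupp)
  recall <- if (length(trueSupp)) mean(trueSupp %in% estSupp) else NA_real_
  precision <- if (nSel) mean(estSupp %in% trueSupp) else NA_real_
  recovered <- intersect(estSupp, trueSupp)
  signAgree <- if (length(recovered))
    mean(sign(bHat[recovered]) == sign(bTrue[recovered])) else NA_real_

  ## responsibility identification among multi-IDR positives
  tab <- dataset@featureTable
  y <- annotationMatrix(dataset@annotations)[, 1]
  r <- idrCounts(tab)
  resp <- fit@responsibilities[idrIds(tab)]
  idx <- idrCoordinates(tab)$idr_index
  prot <- idrProtein(tab)
  multiPos <- names(r)[r >= 2 & y[names(r)] == 1]
  if (length(multiPos)) {
    topIdx <- vapply(multiPos, function(p) {
      rows <- which(prot == p)
      idx[rows[which.max(resp[rows])]]
    }, 1L)
    top1 <- mean(topIdx == dataset@trueResponsible[multiPos])
  } else top1 <- NA_real_

  sp <- dataset@spec
  fresh <- generateSynthetic(sp$nProteins, sp$mFeatures, sp$idrCounts,
                             sp$supportSize, sp$effectSize, sp$intercept,
                             sp$rho, seed = sp$seed + freshSeedOffset,
                             trueCoefficients = dataset@trueCoefficients)
  ## score with the generator's own truth labels for the fresh draw
  scores <- predictProtein(fit, fresh@featureTable)
  yFresh <- annotationMatrix(fresh@annotations)[, 1]
  list(supportPrecision = precision, supportRecall = recall,
       signAgreement = signAgree, top1Accuracy = top1,
       heldoutAuc = aucScore(scores, yFresh[names(scores)]),
       nSelected = nSel)
}
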