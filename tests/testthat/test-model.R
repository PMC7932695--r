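test_that("logistic probability matches closed forms and is stable", {
  expect_equal(logisticProbability(c(1, -1), c(0.3, 0.3)), 0.5)
  expect_equal(logisticProbability(1, log(3)), 0.75)
  expect_equal(logisticProbability(1, -log(9)), 0.1)
  expect_equal(logisticProbability(numeric(0), numeric(0), log(3)), 0.75)
  # extreme linear predictors neither overflow nor return exact 0/1 NaNs
  expect_true(is.finite(logisticProbability(1, 5000)))
  expect_true(is.finite(logisticProbability(1, -5000)))
  expect_error(logisticProbability(c(1, 2), 1), "dimension mismatch")
  m <- matrix(0, 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(logisticProbability(m, rep(0, 3), qlogis(0.9))),
               c(0.9, 0.9))
})

test_that("marginal log-likelihood marginalizes the hidden IDR correctly", {
  # one protein, one IDR, h = 0.5, Y = 1
  t1 <- makeProbTable(list(A = 0.5))
  expect_equal(marginalLogLikelihood(t1, c(A = 1), b = 1), log(0.5))
  # two IDRs h = (0.8, 0.2), uniform prior: log(0.5*0.8 + 0.5*0.2) = log 0.5
  t2 <- makeProbTable(list(A = c(0.8, 0.2)))
  expect_equal(marginalLogLikelihood(t2, c(A = 1), b = 1), log(0.5))
  # non-normalized prior is rejected
  expect_error(marginalLogLikelihood(t2, c(A = 1), b = 1,
                                     prior = c(0.9, 0.3)),
               "sum to 1")
  # equals brute-force enumeration over all hidden assignments
  set.seed(7)
  for (rep in 1:3) {
    hs <- lapply(setNames(1:3, c("P1", "P2", "P3")),
                 function(i) runif(sample(1:3, 1), 0.05, 0.95))
    y <- setNames(rbinom(3, 1, 0.5), names(hs))
    tab <- makeProbTable(hs)
    expect_equal(marginalLogLikelihood(tab, y, b = 1),
                 bruteMarginalLogLik(hs, y), tolerance = 1e-12)
  }
})

test_that("expected complete log-likelihood reduces and substitutes", {
  t1 <- makeProbTable(list(A = 0.7))
  # single IDR with responsibility 1: the ordinary log-likelihood term,
  # and identical to the marginal likelihood when r = 1
  expect_equal(expectedCompleteLogLikelihood(t1, c(A = 1), b = 1,
                                             responsibilities = 1),
               log(0.7))
  expect_equal(expectedCompleteLogLikelihood(t1, c(A = 0), b = 1,
                                             responsibilities = 1),
               marginalLogLikelihood(t1, c(A = 0), b = 1))
  # direct substitution with split responsibilities
  t2 <- makeProbTable(list(A = c(0.8, 0.2)))
  expect_equal(expectedCompleteLogLikelihood(t2, c(A = 1), b = 1,
                                             responsibilities = c(0.5, 0.5)),
               0.5 * log(0.8) + 0.5 * log(0.2))
})

test_that("E-step equals Bayes' rule and normalizes within protein", {
  t1 <- makeProbTable(list(A = 0.9))
  expect_equal(unname(eStep(t1, c(A = 1), b = 1)), 1)
  t2 <- makeProbTable(list(A = c(0.8, 0.2)))
  expect_equal(unname(eStep(t2, c(A = 1), b = 1)), c(0.8, 0.2))
  expect_equal(unname(eStep(t2, c(A = 0), b = 1)), c(0.2, 0.8))
  # brute-force Bayes enumeration on random instances with r_i <= 4
  set.seed(11)
  for (rep in 1:5) {
    n <- 6
    hs <- lapply(setNames(seq_len(n), sprintf("P%02d", seq_len(n))),
                 function(i) runif(sample(1:4, 1), 0.01, 0.99))
    y <- setNames(rbinom(n, 1, 0.5), names(hs))
    tab <- makeProbTable(hs)
    got <- eStep(tab, y, b = 1)
    want <- unlist(lapply(names(hs), function(p)
      bruteEStepProtein(hs[[p]], y[[p]])))
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    sums <- tapply(got, idrProtein(tab), sum)
    expect_true(all(abs(sums - 1) < 1e-10))
  }
})

test_that("modified IRLS weights multiply responsibility into the variance", {
  expect_equal(irlsWeights(1, 0.5), 0.25)
  expect_equal(irlsWeights(0.5, 0.2), 0.08)
  # flooring rule when h saturates
  expect_equal(irlsWeights(1, 1), 1e-8)
  expect_equal(irlsWeights(0, 0.5, weightFloor = 1e-6), 1e-6)
})

test_that("penalized weighted logistic matches shrinkage limit and glmnet", {
  sim <- generateSynthetic(nProteins = 400, mFeatures = 6, idrCounts = 1,
                           supportSize = 2, effectSize = 3, seed = 5)
  x <- featureMatrix(sim@featureTable)
  y <- annotationMatrix(sim@annotations)[, 1]
  # full-shrinkage limit: b = 0, intercept = logit of weighted label mean
  w <- runif(length(y), 0.5, 2)
  big <- weightedPenalizedLogistic(x, y, weights = w,
                                   control = faidrControl(lambda = 1e6))
  expect_true(all(big$coefficients == 0))
  expect_equal(big$intercept, qlogis(weighted.mean(y, w)), tolerance = 1e-6)
  # independent convex-solver oracle: glmnet run to convergence
  skip_if_not_installed("glmnet")
  mine <- weightedPenalizedLogistic(
    x, y, control = faidrControl(lambda = 0.2, irlsIterations = 200))
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0.99, lambda = 0.2,
                      standardize = FALSE, thresh = 1e-12)
  expect_gt(sum(mine$coefficients != 0), 0)  # a nontrivial comparison
  expect_equal(unname(mine$coefficients), as.numeric(g$beta),
               tolerance = 1e-4)
  expect_equal(mine$intercept, as.numeric(g$a0), tolerance = 1e-4)
  # and with non-unit observation weights
  mw <- weightedPenalizedLogistic(
    x, y, weights = w, control = faidrControl(lambda = 0.1,
                                              irlsIterations = 200))
  gw <- glmnet::glmnet(x, y, family = "binomial", weights = w, alpha = 0.99,
                       lambda = 0.1, standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(mw$coefficients), as.numeric(gw$beta),
               tolerance = 1e-4)
})

test_that("lasso keeps an informative feature and drops pure noise", {
  set.seed(9)
  n <- 500
  z <- cbind(signal = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(3 * z[, "signal"]))
  fit <- weightedPenalizedLogistic(z, y, control = faidrControl())
  expect_gt(fit$coefficients["signal"], 0)
  expect_identical(unname(fit$coefficients["noise"]), 0)
})

test_that("single-IDR data reduce the EM fit to one penalized regression", {
  sim <- generateSynthetic(nProteins = 300, mFeatures = 8, idrCounts = 1,
                           supportSize = 2, effectSize = 3, seed = 8)
  tab <- sim@featureTable
  y <- annotationMatrix(sim@annotations)[, 1]
  fit <- fitFaidr(tab, sim@annotations, "synthetic")
  direct <- weightedPenalizedLogistic(featureMatrix(tab), y[idrProtein(tab)],
                                      control = faidrControl())
  expect_identical(fit@coefficients, direct$coefficients)
  expect_identical(fit@intercept, direct$intercept)
  expect_true(all(fit@responsibilities == 1))
  expect_identical(fit@nEmIterations, 1L)
})

test_that("labels permuted against features yield an empty support", {
  sim <- generateSynthetic(nProteins = 400, mFeatures = 20, supportSize = 3,
                           effectSize = 2, seed = 10)
  y <- annotationMatrix(sim@annotations)[, 1]
  set.seed(99)
  yperm <- setNames(sample(y), names(y))
  fit <- fitFaidr(sim@featureTable, yperm, "permuted")
  expect_true(all(coef(fit) == 0))
})

test_that("the fit refuses degenerate label sets", {
  sim <- generateSynthetic(nProteins = 30, mFeatures = 3, supportSize = 1,
                           seed = 1)
  y <- setNames(rep(0L, 30), proteinIds(sim@featureTable))
  y[1:3] <- 1L
  expect_error(fitFaidr(sim@featureTable, y), "3 positive")
  expect_error(fitFaidr(sim@featureTable,
                        setNames(rep(1L, 30), names(y))),
               "negative")
})

test_that("EM improves the penalized marginal log-likelihood", {
  # final >= initial under the default truncated M-step; strictly
  # non-decreasing per round when the M-step runs to inner convergence
  for (s in 1:6) {
    sim <- generateSynthetic(nProteins = 150, mFeatures = 10,
                             supportSize = 2, effectSize = 2.5, seed = s)
    fit <- fitFaidr(sim@featureTable, sim@annotations, "synthetic",
                    faidrControl(lambda = 0.05))
    tr <- fit@objectiveTrace
    expect_gte(tr[length(tr)], tr[1])
    full <- fitFaidr(sim@featureTable, sim@annotations, "synthetic",
                     faidrControl(lambda = 0.05, irlsIterations = 300))
    expect_true(all(diff(full@objectiveTrace) > -1e-6))
  }
})

test_that("per-IDR and per-protein predictions obey their definitions", {
  sim <- generateSynthetic(nProteins = 100, mFeatures = 5, supportSize = 2,
                           effectSize = 3, seed = 4)
  fit <- fitFaidr(sim@featureTable, sim@annotations, "synthetic",
                  faidrControl(lambda = 0.05))
  tab <- sim@featureTable
  p <- predictIdr(fit, tab)
  expect_true(all(p > 0 & p < 1))
  # row-by-row agreement with the logistic probability
  expect_equal(unname(p),
               unname(logisticProbability(featureMatrix(tab), coef(fit),
                                          intercept(fit))))
  # protein score is the uniform mixture = plain mean over the IDRs
  pp <- predictProtein(fit, tab)
  byhand <- tapply(p, idrProtein(tab), mean)[names(pp)]
  expect_equal(pp, setNames(as.numeric(byhand), names(pp)))
  r <- idrCounts(tab)
  single <- names(r)[r == 1][1]
  expect_equal(unname(pp[single]), unname(p[idrProtein(tab) == single]))
  # convexity: protein scores bounded by their IDR extremes
  lo <- tapply(p, idrProtein(tab), min)[names(pp)]
  hi <- tapply(p, idrProtein(tab), max)[names(pp)]
  expect_true(all(pp >= lo - 1e-15 & pp <= hi + 1e-15))
  # explicit two-IDR average: probabilities 0.6 and 0.8 mix to 0.7
  t2 <- makeProbTable(list(A = c(0.6, 0.8)))
  f2 <- new("FaidrFit", functionName = "f", coefficients = c(f1 = 1),
            intercept = 0, responsibilities = setNames(c(0.5, 0.5),
                                                       idrIds(t2)),
            proteinId = c("A", "A"), lambda = 0.2, alpha = 0.99,
            nEmIterations = 1L, converged = TRUE, objectiveTrace = 0,
            control = list())
  expect_equal(unname(predictProtein(f2, t2)), 0.7)
  # unknown feature columns are rejected
  z <- featureMatrix(tab)
  colnames(z)[1] <- "mystery"
  expect_error(predictIdr(fit, IdrFeatureTable(z, idrProtein(tab))),
               "feature")
})

test_that("responsibilities identify the generating IDR above chance", {
  sim <- generateSynthetic(nProteins = 1000, mFeatures = 40, supportSize = 5,
                           effectSize = 2, seed = 1)
  fit <- fitFaidr(sim@featureTable, sim@annotations, "synthetic",
                  faidrControl(lambda = 0.05))
  rep <- recoveryReport(sim, fit)
  y <- annotationMatrix(sim@annotations)[, 1]
  r <- idrCounts(sim@featureTable)
  chance <- mean(1 / r[r >= 2 & y[names(r)] == 1])
  expect_gt(rep$top1Accuracy, chance + 0.1)
  expect_gt(rep$top1Accuracy, 0.5)
})

test_that("permutation null centers held-out protein AUC at one half", {
  sim <- generateSynthetic(nProteins = 200, mFeatures = 10, supportSize = 2,
                           effectSize = 2, seed = 21)
  fresh <- generateSynthetic(nProteins = 200, mFeatures = 10,
                             supportSize = 2, effectSize = 2, seed = 22,
                             trueCoefficients = sim@trueCoefficients)
  y <- annotationMatrix(sim@annotations)[, 1]
  yFresh <- annotationMatrix(fresh@annotations)[, 1]
  set.seed(23)
  aucs <- vapply(1:20, function(i) {
    yperm <- setNames(sample(y), names(y))
    fit <- fitFaidr(sim@featureTable, yperm, "null",
                    faidrControl(lambda = 0.05))
    p <- predictProtein(fit, fresh@featureTable)
    aucScore(p, yFresh[names(p)])
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
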