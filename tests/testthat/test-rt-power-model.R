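test_that("feedforward window follows the 50%-of-max rule", {
  timeMs <- seq(-50, 150)
  ramp <- ifelse(timeMs < 0, 0, pmin(timeMs / 100, 1))
  w <- findFeedforwardWindow(ramp, timeMs)
  expect_equal(w$latencyMs, 50)
  expect_equal(w$windowMs, c(50, 70))

  step <- ifelse(timeMs >= 58, 1, 0)
  expect_equal(findFeedforwardWindow(step, timeMs)$windowMs, c(58, 78))

  expect_equal(findFeedforwardWindow(10 * ramp, timeMs)$latencyMs, 50)
  expect_error(findFeedforwardWindow(rep(2, length(timeMs)), timeMs),
               "flat response")
})

test_that("regression table has one block of simulated trials per used bin", {
  cfg <- simConfig(nChannels = 8L, nTrials = 600L, nItems = 2L,
                   preMs = 150L, postMs = 250L)
  s <- generateSession(cfg, sessionTruth(sinkChannels = 4:6),
                       seed = 60L)
  z <- baselineNormalize(s, mode = "zscore")
  tab <- buildRegressionTable(z, popSize = 50L, nSimsPerBin = 50L,
                              seed = 61L)
  expect_equal(nrow(tab), 24L * 50L)          # fine scheme: 24 used bins
  expect_identical(sort(unique(tab$bin)), 1:24)

  tab2 <- buildRegressionTable(z, popSize = 50L, nSimsPerBin = 50L,
                               seed = 61L)
  expect_identical(tab, tab2)
})

test_that("zero-variance pools give constant SPK within a bin", {
  s <- manualSession(oddballValue = 0.5, distractorValue = 0,
                     nOdd = 8L, nDist = 8L)
  binning <- data.frame(session_id = "manual", trial_id = 1:8,
                        rt_ms = 250, pct_rank = (1:8) / 8,
                        bin = rep(1:2, each = 4L),
                        excluded = FALSE)
  tab <- buildRegressionTable(s, binning = binning, popSize = 10L,
                              nSimsPerBin = 20L, windowMs = c(0, 25),
                              seed = 62L)
  expect_equal(unique(tab$spk), 10L * 0.5)        # popSize x value
  expect_equal(unique(tab$rt), 250)
})

test_that("priors constrain the sign of the coefficients", {
  set.seed(63)
  spk <- runif(200, 0.5, 3)
  rt <- 1 + 2 * spk^0.4 + rnorm(200, 0, 0.1)
  cfgM <- list(chains = 2L, warmup = 150L, totalSamples = 500L,
               thin = 1L)
  pos <- fitPowerModel(data.frame(spk = spk, rt = rt), cfgM, 1,
                       seed = 64L)
  d <- posteriorDraws(pos)
  expect_true(all(d[, "alpha"] > 0))
  expect_true(all(d[, "beta"] > 0))
  expect_true(all(d[, "r"] > 0))
  expect_true(all(d[, "sigma_e"] > 0))
  expect_identical(pos@exponentSign, 1)

  rt2 <- 200 + 100 * spk^(-0.7) + rnorm(200, 0, 5)
  neg <- fitPowerModel(data.frame(spk = spk, rt = rt2), cfgM, -1,
                       seed = 65L)
  expect_true(all(posteriorDraws(neg)[, "r"] < 0))
  expect_lt(posteriorMedians(neg)[["r"]], 0)
})

test_that("signed-exponent fit recovers generative parameters", {
  set.seed(66)
  spk <- exp(rnorm(800, 1.5, 0.5))
  rt <- 200 + 100 * spk^(-0.7) + rnorm(800, 0, 5)
  fit <- fitPowerModel(data.frame(spk = spk, rt = rt),
                       list(chains = 2L, warmup = 300L,
                            totalSamples = 1300L, thin = 2L),
                       exponentSign = -1, seed = 67L)
  ci <- credibleInterval89(fit)
  expect_true(ci["5.5%", "beta"] <= 100 && 100 <= ci["94.5%", "beta"])
  expect_true(ci["5.5%", "r"] <= -0.7 && -0.7 <= ci["94.5%", "r"])
  expect_true(ci["5.5%", "sigma_e"] <= 5 + 1 &&
                ci["94.5%", "sigma_e"] >= 5 - 1)
  expect_true(fit@diagnostics$reliable)
  expect_true(all(fit@diagnostics$rhat < 1.05))
})

test_that("posterior is stable across seeds and row order", {
  set.seed(68)
  spk <- runif(400, 0.5, 3)
  rt <- 1 + 2.7 * spk^0.33 + rnorm(400, 0, 0.05)
  tab <- data.frame(spk = spk, rt = rt)
  cfgM <- list(chains = 2L, warmup = 200L, totalSamples = 900L,
               thin = 1L)
  f1 <- fitPowerModel(tab, cfgM, seed = 69L)
  f2 <- fitPowerModel(tab, cfgM, seed = 70L)
  sds <- apply(posteriorDraws(f1), 2L, sd)
  expect_true(all(abs(posteriorMedians(f1) - posteriorMedians(f2)) <
                    2 * sds))
  f3 <- fitPowerModel(tab[sample(nrow(tab)), ], cfgM, seed = 69L)
  expect_equal(bayesR2(f3), bayesR2(f1), tolerance = 0.05)
})

test_that("vanishing noise drives Bayesian R-squared to one", {
  set.seed(71)
  spk <- runif(500, 0.5, 3)
  rt <- 1 + 2.7 * spk^0.33 + rnorm(500, 0, 1e-3)
  fit <- fitPowerModel(data.frame(spk = spk, rt = rt),
                       list(chains = 2L, warmup = 200L,
                            totalSamples = 900L, thin = 1L),
                       seed = 72L)
  expect_gte(bayesR2(fit), 0.99)
})

test_that("non-positive inputs are rejected", {
  expect_error(fitPowerModel(data.frame(spk = c(1, -1), rt = c(1, 2))),
               "SPK must be positive")
  expect_error(fitPowerModel(data.frame(spk = c(1, 2), rt = c(1, -2))),
               "RT must be positive")
})

test_that("bin scan skips out-of-range windows and ranks signal windows", {
  z <- sharedZScored()
  al <- sharedAlignment()
  cfgM <- list(chains = 2L, warmup = 150L, totalSamples = 650L,
               thin = 1L)
  expect_message(
    scan <- binScan(z, list(al), binWidthsMs = c(5, 20),
                    offsetsMs = c(-100, 58, 300),
                    popSize = 30L, nSimsPerBin = 40L,
                    mcmcConfig = cfgM, seed = 73L),
    "skipped")
  expect_false(any(scan$onsetMs == 300))
  sig <- scan$onsetMs == 58
  # narrow windows can produce non-positive z-scored sums, in which case
  # the fit honestly fails and the scan reports NA; the 20 ms window is
  # the operating point and must fit
  r2Sig <- scan$r2[sig & scan$widthMs == 20]
  expect_true(is.finite(r2Sig))
  # pre-stimulus windows carry no signal: the fit either fails (z-scored
  # sums are not strictly positive) or explains next to nothing
  r2Pre <- scan$r2[scan$onsetMs == -100]
  expect_true(is.na(r2Pre) || r2Pre < r2Sig)
})

test_that("sink-magnitude fit recovers coupling and fails on shuffles", {
  set.seed(74)
  n <- 600L
  mag <- exp(rnorm(n, 1.2, 0.5))
  rt <- 200 + 100 * mag^(-0.7) + rnorm(n, 0, 3)
  bins <- as.integer(cut(rank(rt, ties.method = "first"), 20L))
  tab <- buildCsdRegressionTable(mag, rt, bins, popSize = 40L,
                                 nSimsPerBin = 100L, seed = 75L)
  expect_equal(nrow(tab), 20L * 100L)
  cfgM <- list(chains = 2L, warmup = 300L, totalSamples = 1300L,
               thin = 2L)
  fit <- fitCsdModel(tab, mcmcConfig = cfgM, exponentSign = -1,
                     standardize = TRUE, seed = 76L)
  expect_lt(posteriorMedians(fit)[["r"]], 0)
  expect_gt(bayesR2(fit), 0.5)

  shuf <- tab
  set.seed(77)
  shuf$rt <- sample(shuf$rt)
  null <- fitCsdModel(shuf, mcmcConfig = cfgM, exponentSign = -1,
                      standardize = TRUE, seed = 78L)
  expect_lt(bayesR2(null), 0.05)
})

test_that("a constant predictor is flagged unreliable", {
  set.seed(79)
  fit <- fitPowerModel(data.frame(spk = rep(2, 150),
                                  rt = 5 + rnorm(150, 0, 0.3)),
                       list(chains = 2L, warmup = 100L,
                            totalSamples = 400L, thin = 1L),
                       seed = 80L)
  expect_false(fit@diagnostics$reliable)
})

test_that("the in-package sampler agrees with an external MCMC engine", {
  skip_if_not_installed("rjags")
  set.seed(81)
  spk <- runif(300, 0.5, 3)
  rt <- 1 + 2.7 * spk^0.33 + rnorm(300, 0, 0.05)
  fit <- fitPowerModel(data.frame(spk = spk, rt = rt),
                       list(chains = 2L, warmup = 300L,
                            totalSamples = 1300L, thin = 2L),
                       seed = 82L)

  model <- "
    model {
      for (i in 1:n) {
        mu[i] <- alpha + beta * pow(spk[i], r)
        rtv[i] ~ dnorm(mu[i], tau)
      }
      alpha ~ dlnorm(0, 1 / (0.5 * 0.5))
      beta ~ dlnorm(1, 1 / (0.5 * 0.5))
      r ~ dgamma(1, 3)
      sigma ~ dgamma(0.5, 5)
      tau <- 1 / (sigma * sigma)
    }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(n = 300L, spk = spk, rtv = rt),
                          n.chains = 1, n.adapt = 500, quiet = TRUE)
  draws <- rjags::coda.samples(jm, c("alpha", "beta", "r", "sigma"),
                               n.iter = 3000)[[1L]]
  jagsMed <- apply(as.matrix(draws), 2L, median)
  ours <- posteriorMedians(fit)
  sds <- apply(posteriorDraws(fit), 2L, sd)
  expect_lt(abs(ours[["alpha"]] - jagsMed[["alpha"]]), 4 * sds[["alpha"]])
  expect_lt(abs(ours[["beta"]] - jagsMed[["beta"]]), 4 * sds[["beta"]])
  expect_lt(abs(ours[["r"]] - jagsMed[["r"]]), 4 * sds[["r"]])
  expect_lt(abs(ours[["sigma_e"]] - jagsMed[["sigma"]]),
            4 * sds[["sigma_e"]])
})
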