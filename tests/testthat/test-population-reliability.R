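test_that("winner frequencies sum to 100 across alternatives", {
  set.seed(20)
  pool <- matrix(rnorm(60 * 5), 60, 5)
  res <- simulateSelection(list(oddball = pool + 0.2, distractor = pool),
                           nItems = 6L, popSizes = c(1L, 9L),
                           nSims = 400L, seed = 21L)
  sums <- apply(res@freqAll, c(1L, 2L), sum)
  expect_equal(as.vector(sums), rep(100, length(sums)))
})

test_that("exchangeable pools select the oddball at chance", {
  set.seed(22)
  pool <- matrix(rnorm(500 * 6), 500, 6)
  res <- simulateSelection(list(alternatives = rep(list(pool), 6L)),
                           nItems = 6L, popSizes = c(1L, 49L),
                           nSims = 1000L, seed = 23L)
  tol <- 3 * binomSdPct(1 / 6, 1000L)
  expect_true(all(abs(selectionFreq(res) - 100 / 6) < tol))
})

test_that("a dominant oddball is selected 100% of the time", {
  res <- simulateSelection(list(oddball = matrix(1, 10, 3),
                                distractor = matrix(0, 10, 3)),
                           nItems = 6L, popSizes = c(1L, 9L),
                           nSims = 300L, seed = 24L)
  expect_true(all(selectionFreq(res) == 100))
})

test_that("empty pools and mismatched time axes are rejected", {
  expect_error(simulateSelection(list(oddball = matrix(1, 0, 3),
                                      distractor = matrix(0, 5, 3))),
               "empty response pool")
  expect_error(simulateSelection(list(oddball = matrix(1, 5, 3),
                                      distractor = matrix(0, 5, 4))),
               "time axis")
  expect_message(
    simulateSelection(list(oddball = matrix(1, 2, 2),
                           distractor = matrix(0, 2, 2)),
                      popSizes = 9L, nSims = 50L, seed = 1L),
    "sampling with replacement")
})

test_that("Monte-Carlo selection matches exhaustive enumeration", {
  # one oddball draw of 2 against five distractor draws from {1, 3}:
  # the oddball wins only when every distractor draw is 1
  alts <- c(list(2), rep(list(c(1, 3)), 5L))
  exact <- enumerateSelection(alts, popSize = 1L)
  expect_equal(exact, 100 / 2^5)
  res <- simulateSelection(
    list(oddball = matrix(2, 1, 1), distractor = matrix(c(1, 3), 2, 1)),
    nItems = 6L, popSizes = 1L, nSims = 1000L, seed = 25L)
  expect_lt(abs(selectionFreq(res)[1L] - exact),
            3 * binomSdPct(exact / 100, 1000L))
})

test_that("seeds reproduce selection results exactly", {
  set.seed(26)
  pools <- list(oddball = matrix(rnorm(40 * 4), 40, 4),
                distractor = matrix(rnorm(40 * 4), 40, 4))
  a <- simulateSelection(pools, popSizes = c(1L, 9L), nSims = 200L,
                         seed = 27L)
  b <- simulateSelection(pools, popSizes = c(1L, 9L), nSims = 200L,
                         seed = 27L)
  expect_identical(selectionFreq(a), selectionFreq(b))
})

test_that("a positive oddball shift never lowers expected selection", {
  set.seed(28)
  pool <- matrix(rnorm(300), 300, 1)
  base <- simulateSelection(list(oddball = pool, distractor = pool),
                            nItems = 6L, popSizes = 9L, nSims = 10000L,
                            seed = 29L)
  shifted <- simulateSelection(list(oddball = pool + 0.3,
                                    distractor = pool),
                               nItems = 6L, popSizes = 9L,
                               nSims = 10000L, seed = 29L)
  slack <- 3 * binomSdPct(1 / 6, 10000L) * sqrt(2)
  expect_gt(selectionFreq(shifted)[1L],
            selectionFreq(base)[1L] - slack)
})

test_that("chance window brackets chance and reacts to degenerate pools", {
  set.seed(30)
  nT <- 40L
  timeMs <- seq(-120, -120 + nT - 1)
  pool <- matrix(rnorm(3000 * nT), 3000, nT)
  pools <- list(oddball = pool, distractor = pool, timeMs = timeMs)
  cw <- estimateChanceWindow(pools, popSizes = c(1L, 9L, 49L),
                             nSims = 500L, seed = 31L)
  expect_lt(cw[1L], 100 / 6)
  expect_gt(cw[2L], 100 / 6)

  up <- list(oddball = pool + 10, distractor = pool, timeMs = timeMs)
  cwUp <- estimateChanceWindow(up, popSizes = c(9L, 49L), nSims = 300L,
                               seed = 32L)
  expect_gt(cwUp[1L], 100 / 6)

  short <- list(oddball = pool[, 1:5], distractor = pool[, 1:5],
                timeMs = timeMs[1:5])
  expect_error(estimateChanceWindow(short), "baseline shorter")
})

test_that("the chance window widens with fewer simulations", {
  set.seed(33)
  nT <- 30L
  timeMs <- seq(-110, -110 + nT - 1)
  pool <- matrix(rnorm(5000 * nT), 5000, nT)
  pools <- list(oddball = pool, distractor = pool, timeMs = timeMs)
  wide <- estimateChanceWindow(pools, popSizes = c(1L, 9L),
                               nSims = 100L, seed = 34L)
  narrow <- estimateChanceWindow(pools, popSizes = c(1L, 9L),
                                 nSims = 1000L, seed = 34L)
  expect_gt(diff(wide), diff(narrow))
})

test_that("selection times require a sustained crossing", {
  timeMs <- seq(-50, 149)
  flat <- matrix(100 / 6, length(timeMs), 1L)
  res <- manualSelection(flat, timeMs)
  res <- applyChanceWindow(res, c(10, 25))
  expect_true(is.na(selectionTimes(res)[[1L]]))

  step <- flat
  step[timeMs >= 60 & timeMs < 110, 1L] <- 90
  res <- applyChanceWindow(manualSelection(step, timeMs), c(10, 25))
  expect_equal(unname(selectionTimes(res)[1L]), 60)

  blip <- flat
  blip[timeMs == 80, 1L] <- 90
  res <- applyChanceWindow(manualSelection(blip, timeMs), c(10, 25))
  expect_true(is.na(selectionTimes(res)[[1L]]))
})

test_that("feature selectivity matches trivial and Gaussian oracles", {
  green <- rnorm(300)
  expect_equal(featureSelectivity(green + 1, green, nDraw = 50L,
                                  nSims = 300L, seed = 35L), 100)
  same <- rnorm(500)
  est <- featureSelectivity(same, same, nDraw = 100L, nSims = 1000L,
                            seed = 36L)
  expect_lt(abs(est - 50), 3 * binomSdPct(0.5, 1000L))

  set.seed(37)
  red <- rnorm(50000, 1, 1); grn <- rnorm(50000, 0.9, 1)
  est <- featureSelectivity(red, grn, nDraw = 100L, nSims = 1000L,
                            seed = 38L)
  expect_lt(abs(est - 100 * pnorm(0.1 * sqrt(100) / sqrt(2))), 6)

  expect_message(
    featureSelectivity(rnorm(20), rnorm(20), nDraw = 100L,
                       nSims = 100L, seed = 39L),
    "sampling with replacement")
})

test_that("within-trial selection matches its column-sum construction", {
  s <- manualSession(oddballValue = 1, distractorValue = 0)
  res <- withinTrialSelection(s, nSims = 200L, seed = 40L)
  expect_true(all(selectionFreq(res) == 100))

  z <- sharedZScored()
  al <- sharedAlignment()
  a <- withinTrialSelection(z, list(al), nSims = 300L, seed = 41L)
  ch <- which(compartments(al) != "outside")
  colsum <- apply(mua(z)[ch, , , drop = FALSE], c(2L, 3L), sum)
  tt <- trialTable(z)
  pools <- list(
    oddball = t(colsum[, tt$correct & tt$rf_item == "target"]),
    distractor = t(colsum[, tt$correct & tt$rf_item == "distractor"]),
    timeMs = timeAxis(z))
  b <- simulateSelection(pools, popSizes = 1L, nSims = 300L, seed = 41L)
  expect_identical(selectionFreq(a), selectionFreq(b))
})

test_that("error trials drive signed selection below zero", {
  truth <- sessionTruth(errorRate = 0.35)
  s <- generateSession(testCfg(nTrials = 300L), truth, seed = 42L)
  z <- baselineNormalize(s, mode = "zscore")
  al <- findGranularSink(computeCSD(s))
  err <- suppressMessages(
    errorTrialSelection(z, list(al), popSizes = c(49L, 250L),
                        nSims = 500L, seed = 43L))
  timeMs <- timeAxis(s)
  win <- timeMs >= 58 & timeMs <= 78
  expect_lt(mean(err$signed[win, "250"]), 0)

  # sparse pools are flagged (one warning per pool below the floor)
  w <- capture_warnings(
    suppressMessages(errorTrialSelection(z, list(al), popSizes = 1L,
                                         nSims = 10L,
                                         minTrials = 100000L)))
  expect_true(any(grepl("Monte-Carlo error", w)))

  # correct trials: oddball frequency sits above chance post-stimulus
  pools <- buildResponsePools(z, al)
  ok <- simulateSelection(pools, popSizes = 250L, nSims = 500L,
                          seed = 44L)
  expect_gt(mean(selectionFreq(ok)[win, 1L]) - ok@chance, 0)
})

test_that("baseline bias test is calibrated and handles constant groups", {
  set.seed(45)
  nT <- 60L
  timeMs <- seq(-60, -1)
  pool <- matrix(rnorm(2000 * nT), 2000, nT)
  pools <- list(oddball = pool, distractor = pool, timeMs = timeMs)
  null <- baselineBias(pools, pools, popSize = 9L, nSims = 400L,
                       seed = 46L)
  expect_gt(null$p.value, 0.05)

  up <- list(oddball = pool + 10, distractor = pool, timeMs = timeMs)
  bias <- baselineBias(up, pools, popSize = 9L, nSims = 400L,
                       seed = 47L)
  expect_true(is.finite(bias$statistic))   # group A is constant (100%)
  expect_true(all(bias$groupA == 100))
  expect_gt(bias$statistic, 10)
  expect_lt(bias$p.value, 1e-6)
})

test_that("geometry conditioning filters the intended trials", {
  z <- sharedZScored()
  tt <- trialTable(z)
  adj <- buildResponsePools(z, sharedAlignment(), geometry = "adjacent")
  ch <- sum(compartments(sharedAlignment()) != "outside")
  nAdj <- sum(tt$correct & tt$rf_item == "distractor" &
                tt$rf_geometry == "adjacent")
  expect_equal(nrow(adj$distractor), ch * nAdj)

  bad <- z
  bad@trials$rf_geometry <- NULL
  expect_error(adjacencyConditionedSelection(bad), "rf_geometry")
})

test_that("suppressing adjacent distractors raises adjacent-condition selection", {
  z <- sharedZScored()
  al <- sharedAlignment()
  tt <- trialTable(z)
  post <- which(timeAxis(z) >= 0)
  sup <- which(tt$rf_item == "distractor" & tt$rf_geometry == "adjacent")
  mod <- z
  mod@mua[, post, sup] <- mod@mua[, post, sup] - 2
  res <- adjacencyConditionedSelection(mod, list(al),
                                       popSizes = 250L, nSims = 400L,
                                       seed = 48L)
  win <- timeAxis(z) >= 58 & timeAxis(z) <= 78
  expect_gt(mean(selectionFreq(res$adjacent)[win, 1L]),
            mean(selectionFreq(res$opposite)[win, 1L]))
})

test_that("depth-resolved selection is at chance for uniform pools", {
  s <- manualSession(oddballValue = 0, distractorValue = 0, nOdd = 20L,
                     nDist = 40L)
  set.seed(49)
  s@mua[] <- rnorm(length(s@mua))
  al <- new("LaminarAlignment", markerChannel = 2L,
            compartments = c("middle", "middle"), sinkOnsetMs = 50)
  # depth d maps to channel marker - 10 + d; only depths 9 and 10 exist.
  # popSize 1 keeps finite-pool bias negligible (drawing many summands
  # from a small pool amplifies the pool's chance mean offsets)
  res <- depthResolvedSelection(list(s), list(al), popSize = 1L,
                                nSims = 500L, seed = 50L)
  present <- !vapply(res, is.null, logical(1))
  expect_identical(unname(which(present)), c(9L, 10L))
  freq <- selectionFreq(res[[9L]])
  expect_lt(abs(mean(freq) - 100 / 6), 3 * binomSdPct(1 / 6, 500L))
})
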