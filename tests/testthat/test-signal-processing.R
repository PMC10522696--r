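test_that("envelope chain removes DC and rejects low sample rates", {
  fs <- 20000
  x <- rep(5, 4000)
  env <- extractMuaEnvelope(x, fs)
  # steady state (away from filtfilt edge transients): DC is rejected to
  # the numerical leakage floor of the IIR cascade, < 0.01% of the input
  core <- env[1001:3000]
  expect_true(all(abs(core) < 1e-4 * 5))
  expect_error(extractMuaEnvelope(x, 8000), "sample rate")
})

test_that("envelope plateau scales linearly with input amplitude", {
  fs <- 20000
  t <- seq_len(8000) / fs
  mk <- function(A) A * sin(2 * pi * 2000 * t)
  plateau <- function(env) median(env[2000:6000])
  p1 <- plateau(extractMuaEnvelope(mk(1), fs))
  p2 <- plateau(extractMuaEnvelope(mk(2), fs))
  expect_gt(p1, 0)
  expect_equal(p2 / p1, 2, tolerance = 0.01)
})

test_that("envelope is invariant to polarity flip and reproducible", {
  fs <- 20000
  set.seed(42)
  x <- rnorm(4000)
  expect_equal(extractMuaEnvelope(x, fs), extractMuaEnvelope(-x, fs))
  expect_identical(extractMuaEnvelope(x, fs), extractMuaEnvelope(x, fs))
})

test_that("baseline correction zeroes the pre-stimulus mean exactly", {
  x <- array(5, dim = c(2L, 150L, 3L))
  out <- baselineNormalize(x, timeZero = 101L, mode = "correct")
  expect_true(all(out == 0))

  set.seed(9)
  x <- array(rnorm(4 * 200 * 10, mean = 3, sd = 2),
             dim = c(4L, 200L, 10L))
  z <- baselineNormalize(x, timeZero = 101L, mode = "zscore")
  baseIdx <- 1:100
  mu <- apply(z[, baseIdx, , drop = FALSE], c(1L, 3L), mean)
  sd0 <- apply(z[, baseIdx, , drop = FALSE], c(1L, 3L), sd)
  expect_true(all(abs(mu) < 1e-10))
  expect_true(all(abs(sd0 - 1) < 1e-10))
})

test_that("baseline correction preserves post-stimulus shape", {
  set.seed(10)
  x <- array(rnorm(2 * 160 * 4), dim = c(2L, 160L, 4L))
  out <- baselineNormalize(x, timeZero = 101L, mode = "correct")
  expect_equal(out[, 120L, ] - out[, 140L, ], x[, 120L, ] - x[, 140L, ])
})

test_that("zero baseline SD is flagged, not silently divided", {
  x <- array(rnorm(2 * 150 * 2), dim = c(2L, 150L, 2L))
  x[1L, 1:100, 1L] <- 7                       # flat baseline
  out <- baselineNormalize(x, timeZero = 101L, mode = "zscore")
  flagged <- attr(out, "flagged")
  expect_equal(unname(flagged[1L, ]), c(1L, 1L))
  expect_true(all(is.na(out[1L, , 1L])))
  expect_false(anyNA(out[2L, , ]))
})

test_that("CSD is zero on depth-linear potentials and matches hand arithmetic", {
  nCh <- 8L
  lin <- array(rep(2 * seq_len(nCh) + 1, times = 20L),
               dim = c(nCh, 20L, 1L))
  csd <- computeCSD(lin, spacingMm = 0.1, timeZero = 11L)
  expect_true(all(abs(csdValues(csd)[2:(nCh - 1L), , ]) < 1e-9))
  expect_true(all(is.na(csdValues(csd)[c(1L, nCh), , ])))
  expect_identical(validChannels(csd), 2:(nCh - 1L))

  x <- matrix(c(1, 4, 9), nrow = 3L, ncol = 12L)
  csd <- computeCSD(x, spacingMm = 0.1, sigma = 0.4, timeZero = 11L)
  expect_equal(unique(as.vector(csdValues(csd)[2L, , ])), -80)
  expect_error(computeCSD(matrix(1, 2L, 10L)), ">= 3 channels")
})

test_that("CSD is linear in its input", {
  set.seed(11)
  a <- array(rnorm(6 * 15 * 2), dim = c(6L, 15L, 2L))
  b <- array(rnorm(6 * 15 * 2), dim = c(6L, 15L, 2L))
  cab <- csdValues(computeCSD(a + b, timeZero = 11L))
  ca <- csdValues(computeCSD(a, timeZero = 11L))
  cb <- csdValues(computeCSD(b, timeZero = 11L))
  expect_equal(cab, ca + cb, tolerance = 1e-12)
})

test_that("granular sink detection recovers a constructed sink", {
  nCh <- 32L; nT <- 300L; tz <- 101L
  set.seed(12)
  vals <- array(rnorm(nCh * nT, sd = 0.05), dim = c(nCh, nT, 1L))
  vals[c(1L, nCh), , ] <- NA
  vals[14:18, (tz + 50L):nT, ] <- vals[14:18, (tz + 50L):nT, ] - 5
  al <- findGranularSink(manualCsd(vals, timeZero = tz))
  expect_identical(markerChannel(al), 18L)
  expect_identical(which(compartments(al) == "middle"), 14:18)
  expect_identical(which(compartments(al) == "upper"), 9:13)
  expect_identical(which(compartments(al) == "deep"), 19:23)
  expect_equal(al@sinkOnsetMs, 50)
})

test_that("pure noise raises a no-discernable-profile error", {
  set.seed(13)
  vals <- array(rnorm(16L * 300L * 2L), dim = c(16L, 300L, 2L))
  vals[c(1L, 16L), , ] <- NA
  expect_error(findGranularSink(manualCsd(vals, timeZero = 101L)),
               "no discernable CSD profile")
})

test_that("the earliest of two sinks anchors the alignment", {
  nCh <- 20L; nT <- 300L; tz <- 101L
  set.seed(14)
  vals <- array(rnorm(nCh * nT, sd = 0.05), dim = c(nCh, nT, 1L))
  vals[c(1L, nCh), , ] <- NA
  vals[10:12, (tz + 60L):nT, ] <- vals[10:12, (tz + 60L):nT, ] - 5
  vals[4:6, (tz + 90L):nT, ] <- vals[4:6, (tz + 90L):nT, ] - 5
  al <- findGranularSink(manualCsd(vals, timeZero = tz))
  expect_identical(markerChannel(al), 12L)
  expect_equal(al@sinkOnsetMs, 60)
})

test_that("sink magnitude averages the middle compartment and window", {
  nCh <- 20L; nT <- 300L; tz <- 101L
  al <- new("LaminarAlignment", markerChannel = 12L,
            compartments = {
              comp <- rep("outside", nCh); comp[8:12] <- "middle"; comp
            },
            sinkOnsetMs = 50)
  mk <- function(fill) manualCsd(array(fill, dim = c(nCh, nT, 3L)),
                                 timeZero = tz)
  expect_equal(granularSinkMagnitude(mk(-2), al), rep(2, 3))
  expect_equal(granularSinkMagnitude(mk(0), al), rep(0, 3))

  vals <- array(0, dim = c(nCh, nT, 2L))
  vals[8:12, , ] <- -(1:5)
  expect_equal(granularSinkMagnitude(manualCsd(vals, timeZero = tz), al),
               rep(3, 2))
  expect_error(granularSinkMagnitude(mk(0), al, windowMs = c(58, 1000)),
               "window")
})

test_that("alignment recovers the injected sink across random sessions", {
  set.seed(15)
  for (i in 1:8) {
    bottom <- sample(12:26, 1L)
    truth <- sessionTruth(sinkChannels = (bottom - 4L):bottom)
    # 100 trials: enough averaging for the trial-mean CSD to sit clearly
    # above the k = 2 baseline-SD threshold at every contact of the sink
    s <- generateSession(testCfg(nTrials = 100L), truth, seed = 1000L + i)
    al <- findGranularSink(computeCSD(s))
    expect_identical(markerChannel(al), bottom)
  }
})
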