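# Shared fixtures, generated in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# compact probe/time settings so fixtures stay fast
testCfg <- function(nTrials = 200L, ...) {
  simConfig(nTrials = nTrials, preMs = 150L, postMs = 250L, ...)
}

# minimal 4-channel probe for cheap behavioural fixtures
microCfg <- function(nTrials = 120L, ...) {
  simConfig(nChannels = 4L, nTrials = nTrials, preMs = 100L,
            postMs = 30L, ...)
}

microTruth <- function(...) {
  sessionTruth(sinkChannels = 2:3, ...)
}

sharedSession <- function() {
  memo("session", generateSession(testCfg(), sessionTruth(), seed = 101L))
}

sharedZScored <- function() {
  memo("zscored", baselineNormalize(sharedSession(), mode = "zscore"))
}

sharedCsd <- function() memo("csd", computeCSD(sharedSession()))

sharedAlignment <- function() memo("align", findGranularSink(sharedCsd()))

sharedPools <- function() {
  memo("pools", buildResponsePools(sharedZScored(), sharedAlignment()))
}

# a bare-bones SessionRecording built by hand (two channels)
manualSession <- function(oddballValue = 1, distractorValue = 0,
                          nOdd = 6L, nDist = 12L, nTime = 130L,
                          timeZero = 101L) {
  nTr <- nOdd + nDist
  mua <- array(distractorValue, dim = c(2L, nTime, nTr))
  mua[, , seq_len(nOdd)] <- oddballValue
  trials <- data.frame(
    trial_id = seq_len(nTr), session_id = "manual",
    rt_ms = 250, correct = TRUE,
    target_color = "red", target_position = 0L, rf_position = 0L,
    rf_item = rep(c("target", "distractor"), c(nOdd, nDist)),
    rf_geometry = rep(c("other", "adjacent"), c(nOdd, nDist)),
    block_index = 1L, trial_in_block = seq_len(nTr),
    chosen_position = 0L, foreperiod_ms = 1000,
    s_drive = 1, stringsAsFactors = FALSE)
  new("SessionRecording", lfp = mua, mua = mua, sampleRate = 1000,
      timeZero = timeZero, channelSpacingMm = 0.1, trials = trials,
      groundTruth = list(), meta = list())
}

# CSDMatrix built directly from a values array
manualCsd <- function(values, timeZero = 101L, spacingMm = 0.1) {
  nCh <- dim(values)[1L]
  new("CSDMatrix", values = values, validChannels = 2:(nCh - 1L),
      sampleRate = 1000, timeZero = as.integer(timeZero),
      channelSpacingMm = spacingMm)
}

# SelectionResult built directly from a frequency matrix
manualSelection <- function(freq, timeMs, popSizes = 250L,
                            nItems = 6L) {
  freqAll <- array(NA_real_, dim = c(nrow(freq), ncol(freq), nItems))
  freqAll[, , 1L] <- freq
  new("SelectionResult", freq = freq, freqAll = freqAll,
      timeMs = timeMs, popSizes = as.integer(popSizes),
      nSims = 1000L, nItems = as.integer(nItems),
      chance = 100 / nItems, chanceWindow = c(NA_real_, NA_real_),
      selectionTimeMs = stats::setNames(
        rep(NA_real_, length(popSizes)), as.character(popSizes)))
}

# exhaustive winner-take-all oracle: for small pools and population
# sizes, enumerate every combination of draws and average the oddball's
# win probability (ties split uniformly)
enumerateSelection <- function(alternatives, popSize) {
  sums <- lapply(alternatives, function(pool) {
    draws <- as.matrix(expand.grid(rep(list(pool), popSize)))
    rowSums(draws)
  })
  combos <- as.matrix(expand.grid(sums))
  mx <- apply(combos, 1L, max)
  winners <- combos == mx
  mean(winners[, 1L] / rowSums(winners)) * 100
}

# binomial Monte-Carlo SD (percent) of a selection frequency
binomSdPct <- function(p, nSims) 100 * sqrt(p * (1 - p) / nSims)
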