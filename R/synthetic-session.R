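#' Simulation configuration for synthetic laminar sessions
#'
#' Probe and task geometry for the synthetic session generator. Defaults
#' follow the recording setup the analysis expects: a 32-contact linear
#' array with 0.1 mm spacing spanning cortex, six-item pop-out search with
#' block-structured target-feature repetition (5-15 trials per block), and
#' a millisecond-resolution analysis time base.
#'
#' @param nChannels number of probe contacts.
#' @param channelSpacingMm inter-electrode spacing (mm).
#' @param sampleRateHz sampling rate of the stored LFP/MUA-envelope arrays
#'   (Hz). Arrays are stored at analysis resolution; broadband filtering is
#'   demonstrated separately by [extractMuaEnvelope()].
#' @param nTrials number of trials to simulate.
#' @param nItems number of search-array items.
#' @param blockLengthRange integer range of block lengths (trials) between
#'   target-feature swaps.
#' @param preMs,postMs pre- and post-stimulus extent of the time axis (ms).
#' @param rfPosition ring position (0-based) of the array item inside the
#'   recorded receptive field.
#'
#' @return a validated `simConfig` list.
#' @export
simConfig <- function(nChannels = 32L, channelSpacingMm = 0.1,
                      sampleRateHz = 1000, nTrials = 400L, nItems = 6L,
                      blockLengthRange = c(5L, 15L),
                      preMs = 200L, postMs = 400L, rfPosition = 0L) {
  cfg <- list(nChannels = as.integer(nChannels),
              channelSpacingMm = channelSpacingMm,
              sampleRateHz = sampleRateHz,
              nTrials = as.integer(nTrials),
              nItems = as.integer(nItems),
              blockLengthRange = as.integer(blockLengthRange),
              preMs = as.integer(preMs), postMs = as.integer(postMs),
              rfPosition = as.integer(rfPosition))
  if (cfg$nItems < 2L)
    stop("configuration error: nItems must be >= 2")
  if (cfg$nChannels < 3L)
    stop("configuration error: nChannels must be >= 3")
  if (length(cfg$blockLengthRange) != 2L ||
      cfg$blockLengthRange[1L] < 1L ||
      cfg$blockLengthRange[1L] > cfg$blockLengthRange[2L])
    stop("configuration error: blockLengthRange must be [min, max], min >= 1")
  if (cfg$preMs < 100L)
    stop("configuration error: need >= 100 ms pre-stimulus")
  if (cfg$rfPosition < 0L || cfg$rfPosition >= cfg$nItems)
    stop("configuration error: rfPosition outside the array")
  class(cfg) <- "simConfig"
  cfg
}

#' Generative ground truth for synthetic sessions
#'
#' Parameters of the generative model tying neural responses to behaviour.
#' On each correct trial a single feedforward drive S (lognormal across
#' trials) scales both the multiunit transient of the oddball-in-RF
#' condition and the granular current sink, and sets reaction time through
#' the power law RT = alpha + beta * S^r plus truncated Gaussian noise
#' (floor 100 ms). Error trials redirect the oddball's amplitude boost to
#' the errantly chosen distractor and add a small pre-stimulus baseline
#' bias to it.
#'
#' @param alpha baseline RT offset (ms).
#' @param beta power-law coefficient (ms per unit drive^r).
#' @param r power-law exponent (dimensionless; negative means stronger
#'   drives produce faster responses).
#' @param latencyMs evoked-response onset latency (ms post-stimulus).
#' @param sinkChannels integer channel range of the granular input sink;
#'   the deepest sink channel is the functional L4/5 marker.
#' @param colorPref preferred color of the recorded column ("red"/"green").
#' @param colorGain multiplicative response gain for the preferred vs
#'   non-preferred RF stimulus color (0 = unselective).
#' @param errorRate fraction of error trials in [0, 1].
#' @param primingBaselineShift tonic shift (z-units) added to the column
#'   on primed trials whose target color matches `colorPref`.
#' @param rtNoiseSd SD of the truncated Gaussian RT noise (ms).
#' @param driveMeanLog,driveSdLog lognormal parameters of the per-trial
#'   feedforward drive S.
#' @param distractorAmp mean evoked amplitude (z-units) when a distractor
#'   occupies the RF.
#' @param boostCompartment "all" responds across all in-cortex channels;
#'   "middle" confines the condition-dependent evoked response to the
#'   granular compartment, leaving other depths stimulus-blind.
#' @param noiseSd per-sample envelope noise SD (defines the z-unit scale).
#' @param lfpNoiseSd Ornstein-Uhlenbeck LFP noise SD (volts).
#' @param errorBaselineBias pre-stimulus bias (z-units) on the chosen
#'   distractor's response in error trials.
#'
#' @return a validated `sessionTruth` list.
#' @export
sessionTruth <- function(alpha = 200, beta = 100, r = -0.7,
                         latencyMs = 58, sinkChannels = 14:18,
                         colorPref = c("red", "green"), colorGain = 0.3,
                         errorRate = 0.12, primingBaselineShift = 0,
                         rtNoiseSd = 15,
                         driveMeanLog = log(2), driveSdLog = 0.35,
                         distractorAmp = 1.0,
                         boostCompartment = c("all", "middle"),
                         noiseSd = 1.0, lfpNoiseSd = 10e-6,
                         errorBaselineBias = 0.3) {
  truth <- list(alpha = alpha, beta = beta, r = r, latencyMs = latencyMs,
                sinkChannels = as.integer(sinkChannels),
                colorPref = match.arg(colorPref), colorGain = colorGain,
                errorRate = errorRate,
                primingBaselineShift = primingBaselineShift,
                rtNoiseSd = rtNoiseSd, driveMeanLog = driveMeanLog,
                driveSdLog = driveSdLog, distractorAmp = distractorAmp,
                boostCompartment = match.arg(boostCompartment),
                noiseSd = noiseSd, lfpNoiseSd = lfpNoiseSd,
                errorBaselineBias = errorBaselineBias)
  if (truth$errorRate < 0 || truth$errorRate > 1)
    stop("configuration error: errorRate must lie in [0, 1]")
  if (truth$latencyMs <= 0)
    stop("configuration error: latencyMs must be > 0")
  class(truth) <- "sessionTruth"
  truth
}

# Difference-of-gamma evoked transient, peak normalised to 1 at ~30 ms
# after response onset. `u` in ms relative to onset.
evokedTemplate <- function(u) {
  g <- ifelse(u <= 0, 0,
              stats::dgamma(u, shape = 4, scale = 10) -
                0.4 * stats::dgamma(u, shape = 6, scale = 15))
  g / max(stats::dgamma((4 - 1) * 10, shape = 4, scale = 10) -
            0.4 * stats::dgamma((4 - 1) * 10, shape = 6, scale = 15))
}

# Depth profile of LFP whose discrete second spatial difference is a
# uniform positive curvature over the sink channels (so the CSD is a
# uniform sink there and exactly zero on all other interior channels).
sinkLfpProfile <- function(nChannels, sinkChannels, spacingMm, peakVolt) {
  curv <- numeric(nChannels)
  curv[sinkChannels] <- 1
  x <- numeric(nChannels)
  for (d in 2:(nChannels - 1L))
    x[d + 1L] <- 2 * x[d] - x[d - 1L] + curv[d] * spacingMm^2
  # remove best-fit linear trend (CSD-invariant) to keep values bounded
  d <- seq_len(nChannels)
  fit <- stats::lm.fit(cbind(1, d), x)
  x <- x - fit$fitted.values
  x * (peakVolt / max(abs(x)))
}

# Ornstein-Uhlenbeck noise, one path per (channel, trial), time constant
# tauMs, stationary SD sdVolt.
ouNoise <- function(nChannels, nTime, nTrials, sdVolt, tauMs = 20,
                    dtMs = 1) {
  a <- exp(-dtMs / tauMs)
  innovSd <- sdVolt * sqrt(1 - a^2)
  out <- array(0, dim = c(nChannels, nTime, nTrials))
  state <- matrix(stats::rnorm(nChannels * nTrials, sd = sdVolt),
                  nChannels, nTrials)
  for (t in seq_len(nTime)) {
    state <- a * state +
      matrix(stats::rnorm(nChannels * nTrials, sd = innovSd),
             nChannels, nTrials)
    out[, t, ] <- state
  }
  out
}

#' Foreperiod delays from a nonaging (flat-hazard) distribution
#'
#' Draws fixation-to-array delays from an exponential distribution
#' truncated to 750-1250 ms, which keeps the hazard of stimulus onset
#' approximately flat over the interior of the support so elapsed time
#' carries no information about imminent onset.
#'
#' @param n number of delays.
#' @param seed optional RNG seed.
#' @param rangeMs support of the foreperiod (ms).
#' @param ratePerMs exponential hazard rate (1/ms).
#' @return numeric vector of delays (ms), all within `rangeMs`.
#' @export
generateForeperiods <- function(n, seed = NULL, rangeMs = c(750, 1250),
                                ratePerMs = 0.01) {
  stopifnot(n >= 0)
  if (n == 0) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  span <- rangeMs[2] - rangeMs[1]
  u <- stats::runif(n)
  # inverse CDF of exponential truncated to [0, span]
  rangeMs[1] - log(1 - u * (1 - exp(-ratePerMs * span))) / ratePerMs
}

#' Generate a synthetic laminar session
#'
#' Simulates one laminar V4-like session of six-item color pop-out search:
#' a block-structured trial table (target feature repeats 5-15 trials,
#' then swaps), LFP with an Ornstein-Uhlenbeck background and a
#' stimulus-locked granular current sink, and multiunit envelopes whose
#' oddball-in-RF feedforward amplitude S sets reaction time through
#' RT = alpha + beta * S^r + noise. All randomness derives from `seed`,
#' so identical seeds give byte-identical sessions.
#'
#' @param cfg a [simConfig()].
#' @param truth a [sessionTruth()].
#' @param seed integer RNG seed.
#' @param sessionId identifier stored in the trial table.
#' @return a [SessionRecording-class] with ground truth attached.
#' @export
generateSession <- function(cfg = simConfig(), truth = sessionTruth(),
                            seed = 1L, sessionId = "synthetic-01") {
  if (!inherits(cfg, "simConfig")) stop("cfg must come from simConfig()")
  if (!inherits(truth, "sessionTruth"))
    stop("truth must come from sessionTruth()")
  if (any(truth$sinkChannels < 2L) ||
      any(truth$sinkChannels > cfg$nChannels - 1L))
    stop("configuration error: sinkChannels must lie on interior contacts")
  set.seed(seed)

  nCh <- cfg$nChannels
  nTime <- cfg$preMs + cfg$postMs + 1L
  timeZero <- cfg$preMs + 1L
  nTr <- cfg$nTrials
  marker <- max(truth$sinkChannels)

  ## ---- trial table -------------------------------------------------
  # block structure: target color alternates between blocks
  blockLens <- integer(0)
  while (sum(blockLens) < nTr)
    blockLens <- c(blockLens, sample(cfg$blockLengthRange[1L]:
                                       cfg$blockLengthRange[2L], 1L))
  blockIdx <- rep(seq_along(blockLens), blockLens)[seq_len(nTr)]
  trialInBlock <- unlist(lapply(blockLens, seq_len))[seq_len(nTr)]
  firstColor <- sample(c("red", "green"), 1L)
  colors <- c("red", "green")
  targetColor <- ifelse(blockIdx %% 2L == 1L, firstColor,
                        setdiff(colors, firstColor))

  targetPos <- sample.int(cfg$nItems, nTr, replace = TRUE) - 1L
  rfPos <- cfg$rfPosition
  rfIsTarget <- targetPos == rfPos
  ringDist <- pmin((targetPos - rfPos) %% cfg$nItems,
                   (rfPos - targetPos) %% cfg$nItems)
  rfGeometry <- ifelse(rfIsTarget, "other",
                       ifelse(ringDist == 1L, "adjacent",
                              ifelse(ringDist == cfg$nItems %/% 2L,
                                     "opposite", "other")))

  correct <- stats::runif(nTr) >= truth$errorRate
  chosenPos <- targetPos
  if (any(!correct)) {
    for (i in which(!correct)) {
      alt <- setdiff(seq_len(cfg$nItems) - 1L, targetPos[i])
      chosenPos[i] <- sample(alt, 1L)
    }
  }

  # feedforward drive of the item that captured attention
  S <- stats::rlnorm(nTr, truth$driveMeanLog, truth$driveSdLog)
  rtClean <- truth$alpha + truth$beta * S^truth$r
  rtNoise <- if (truth$rtNoiseSd > 0)
    stats::rnorm(nTr, 0, truth$rtNoiseSd) else 0
  rt <- pmax(100, rtClean + rtNoise)

  foreperiod <- generateForeperiods(nTr)

  trials <- data.frame(
    trial_id = seq_len(nTr),
    session_id = sessionId,
    rt_ms = rt,
    correct = correct,
    target_color = targetColor,
    target_position = targetPos,
    rf_position = rfPos,
    rf_item = ifelse(rfIsTarget, "target", "distractor"),
    rf_geometry = rfGeometry,
    block_index = blockIdx,
    trial_in_block = trialInBlock,
    chosen_position = chosenPos,
    foreperiod_ms = foreperiod,
    s_drive = S,
    stringsAsFactors = FALSE
  )

  ## ---- evoked amplitudes per trial ---------------------------------
  # RF stimulus color: target color if the target sits in the RF,
  # otherwise the (single) distractor color
  rfColor <- ifelse(rfIsTarget, targetColor,
                    ifelse(targetColor == "red", "green", "red"))
  colorFactor <- ifelse(rfColor == truth$colorPref,
                        1 + truth$colorGain, 1 - truth$colorGain)

  distAmp <- stats::rlnorm(nTr, log(truth$distractorAmp), truth$driveSdLog)
  # attention-capturing item in RF gets the feedforward drive S:
  # on correct trials that is the oddball; on error trials the errantly
  # chosen distractor
  rfCaptured <- (correct & rfIsTarget) |
    (!correct & !rfIsTarget & chosenPos == rfPos)
  amp <- ifelse(rfCaptured, S, distAmp)
  amp <- amp * colorFactor

  ## ---- multiunit envelopes ----------------------------------------
  compart <- rep("outside", nCh)
  compart[max(1L, marker - 4L):marker] <- "middle"
  if (marker - 5L >= 1L)
    compart[max(1L, marker - 9L):(marker - 5L)] <- "upper"
  if (marker + 1L <= nCh)
    compart[(marker + 1L):min(nCh, marker + 5L)] <- "deep"
  inCortex <- compart != "outside"
  responsive <- if (truth$boostCompartment == "middle")
    compart == "middle" else inCortex

  tMs <- (seq_len(nTime) - timeZero)  # ms relative to onset at 1 kHz
  jitter <- stats::runif(nTr, -2, 2)

  baselineLevel <- 10
  muaArr <- array(stats::rnorm(nCh * nTime * nTr, 0, truth$noiseSd),
                  dim = c(nCh, nTime, nTr)) + baselineLevel

  # tonic priming shift: primed trials (>= 3rd repetition) whose target
  # color matches the column preference get elevated ongoing activity
  primedPref <- trialInBlock >= 3L & targetColor == truth$colorPref
  if (truth$primingBaselineShift != 0 && any(primedPref)) {
    shift <- truth$primingBaselineShift
    muaArr[inCortex, , primedPref] <- muaArr[inCortex, , primedPref] + shift
  }

  # pre-stimulus bias preceding errant capture of the RF distractor
  errBias <- !correct & rfCaptured
  if (truth$errorBaselineBias != 0 && any(errBias)) {
    muaArr[responsive, , errBias] <-
      muaArr[responsive, , errBias] + truth$errorBaselineBias
  }

  for (i in seq_len(nTr)) {
    g <- evokedTemplate(tMs - truth$latencyMs - jitter[i])
    muaArr[responsive, , i] <- muaArr[responsive, , i] +
      amp[i] * matrix(g, sum(responsive), nTime, byrow = TRUE)
  }

  ## ---- LFP with granular sink --------------------------------------
  lfpArr <- ouNoise(nCh, nTime, nTr, truth$lfpNoiseSd)
  profile <- sinkLfpProfile(nCh, truth$sinkChannels, cfg$channelSpacingMm,
                            peakVolt = 150e-6)
  for (i in seq_len(nTr)) {
    g <- evokedTemplate(tMs - truth$latencyMs - jitter[i])
    lfpArr[, , i] <- lfpArr[, , i] + amp[i] * outer(profile, g)
  }

  meta <- list(schema = "lamsel-session-1", seed = seed,
               units = list(lfp = "V", mua = "envelope units"),
               compartmentsTrue = compart)
  new("SessionRecording", lfp = lfpArr, mua = muaArr,
      sampleRate = cfg$sampleRateHz, timeZero = timeZero,
      channelSpacingMm = cfg$channelSpacingMm, trials = trials,
      groundTruth = unclass(truth), meta = meta)
}
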