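#' Multiunit envelope from broadband voltage
#'
#' Estimates multiunit activity power from a broadband extracellular
#' trace: 4th-order Butterworth band-pass 0.5-5 kHz (the predominant
#' spiking band), full-wave rectification, then a 4th-order low-pass at
#' 0.25 kHz (half the band-pass high-pass corner). Filters are applied
#' forward-backward (zero phase) so envelope latencies are not distorted.
#'
#' @param broadband numeric vector, or matrix with one trace per row.
#' @param sampleRateHz sampling rate of `broadband`; must exceed 10 kHz so
#'   the 5 kHz band edge is below Nyquist.
#' @param bandHz band-pass corners (Hz).
#' @param envelopeCutHz low-pass corner applied after rectification (Hz).
#' @return envelope with the same shape as the input; non-negative up to
#'   filter ringing.
#' @export
extractMuaEnvelope <- function(broadband, sampleRateHz,
                               bandHz = c(500, 5000),
                               envelopeCutHz = 250) {
  if (sampleRateHz <= 2 * bandHz[2])
    stop(sprintf(
      "sample rate %.0f Hz too low for a %.0f Hz band edge (need > %.0f Hz)",
      sampleRateHz, bandHz[2], 2 * bandHz[2]))
  bp <- signal::butter(4, bandHz / (sampleRateHz / 2), type = "pass")
  lp <- signal::butter(4, envelopeCutHz / (sampleRateHz / 2), type = "low")
  chain <- function(x) {
    rect <- abs(signal::filtfilt(bp, x))
    signal::filtfilt(lp, rect)
  }
  if (is.matrix(broadband)) t(apply(broadband, 1L, chain)) else chain(broadband)
}

#' Baseline-correct or z-score trial arrays
#'
#' Per trial and channel, subtracts the mean of the 100 ms window
#' immediately preceding stimulus onset ("correct"), or additionally
#' divides by the SD of that baseline window ("zscore"). Channel-trials
#' with zero baseline SD cannot be z-scored and are returned as NA with a
#' `flagged` attribute so downstream pooling can drop them.
#'
#' @param x numeric array channel x time x trial, or a
#'   [SessionRecording-class] (whose `mua` array is normalized).
#' @param timeZero stimulus-onset sample index (taken from the recording
#'   when `x` is a SessionRecording).
#' @param mode "correct" (subtract baseline mean) or "zscore".
#' @param sampleRateHz sampling rate, used to size the 100 ms window.
#' @param baselineMs baseline window length (ms).
#' @return object of the same type as `x`.
#' @export
baselineNormalize <- function(x, timeZero = NULL,
                              mode = c("correct", "zscore"),
                              sampleRateHz = 1000, baselineMs = 100) {
  mode <- match.arg(mode)
  if (is(x, "SessionRecording")) {
    x@mua <- baselineNormalize(x@mua, timeZero(x), mode,
                               sampleRate(x), baselineMs)
    return(x)
  }
  stopifnot(length(dim(x)) == 3L, !is.null(timeZero))
  nBase <- round(baselineMs / 1000 * sampleRateHz)
  if (timeZero - 1L < nBase)
    stop(sprintf("need >= %d pre-stimulus samples, found %d",
                 nBase, timeZero - 1L))
  baseIdx <- (timeZero - nBase):(timeZero - 1L)
  base <- x[, baseIdx, , drop = FALSE]
  mu <- apply(base, c(1L, 3L), mean)
  out <- sweep3(x, mu, `-`)
  flagged <- NULL
  if (mode == "zscore") {
    sd0 <- apply(base, c(1L, 3L), stats::sd)
    bad <- sd0 <= 0
    if (any(bad)) {
      flagged <- which(bad, arr.ind = TRUE)
      colnames(flagged) <- c("channel", "trial")
      sd0[bad] <- NA_real_
    }
    out <- sweep3(out, sd0, `/`)
  }
  attr(out, "flagged") <- flagged
  out
}

# sweep a channel x trial matrix across the time dimension of a
# channel x time x trial array
sweep3 <- function(arr, m, op) {
  d <- dim(arr)
  full <- aperm(array(m, dim = c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
  op(arr, full)
}

#' Current source density from laminar LFP
#'
#' Estimates net local transmembrane current as the negative second
#' spatial difference of voltage along the probe:
#' CSD(t, d) = -sigma * (x(t, d-z) + x(t, d+z) - 2 x(t, d)) / z^2,
#' with z the inter-electrode distance. Negative values are current
#' sinks. The first and last contacts have no defined second difference
#' and are returned as NA and excluded from `validChannels`.
#'
#' @param x numeric array channel x time x trial (or channel x time
#'   matrix), or a [SessionRecording-class].
#' @param spacingMm inter-electrode distance z (mm).
#' @param sigma tissue conductivity multiplier; default 0.4 (S/m scale),
#'   configurable since only relative magnitudes matter downstream.
#' @param sampleRateHz,timeZero sampling metadata carried into the
#'   result (taken from the recording when given one).
#' @return a [CSDMatrix-class].
#' @export
computeCSD <- function(x, spacingMm = 0.1, sigma = 0.4,
                       sampleRateHz = 1000, timeZero = 1L) {
  if (is(x, "SessionRecording")) {
    return(computeCSD(lfp(x), x@channelSpacingMm, sigma,
                      sampleRate(x), timeZero(x)))
  }
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  nCh <- dim(x)[1L]
  if (nCh < 3L) stop("CSD requires >= 3 channels")
  vals <- array(NA_real_, dim = dim(x))
  up <- x[1:(nCh - 2L), , , drop = FALSE]
  dn <- x[3:nCh, , , drop = FALSE]
  mid <- x[2:(nCh - 1L), , , drop = FALSE]
  vals[2:(nCh - 1L), , ] <- -sigma * (up + dn - 2 * mid) / spacingMm^2
  new("CSDMatrix", values = vals, validChannels = 2:(nCh - 1L),
      sampleRate = sampleRateHz, timeZero = as.integer(timeZero),
      channelSpacingMm = spacingMm)
}

#' Locate the initial granular sink and align laminar compartments
#'
#' Finds the earliest post-stimulus contiguous channel region of the
#' trial-averaged CSD that stays below -k baseline SDs for at least
#' `sustainMs`. The deepest channel of that region is the functional
#' L4/5 marker; the middle compartment is the 0.5 mm (5 channels at
#' 0.1 mm spacing) ending at the marker, the upper compartment the
#' 0.5 mm above that, and the deep compartment the 0.5 mm below.
#'
#' Because background LFP fluctuations are temporally correlated, a
#' single-channel threshold crossing is not enough: a genuine sink has
#' spatial extent, so a crossing only counts when at least one
#' neighbouring channel is concurrently suprathreshold (the second
#' spatial difference anticorrelates noise on neighbouring channels,
#' making a two-channel coincidence very unlikely under noise alone).
#'
#' @param csd a [CSDMatrix-class].
#' @param k sink threshold in baseline SDs.
#' @param sustainMs minimum suprathreshold duration (ms).
#' @param onsetTolMs channels whose sink onset falls within this many ms
#'   of the earliest onset are grouped into the initial sink region.
#' @param requireNeighbour demand a concurrently suprathreshold
#'   neighbouring channel (set FALSE for single-channel constructions).
#' @return a [LaminarAlignment-class].
#' @export
findGranularSink <- function(csd, k = 2, sustainMs = 5, onsetTolMs = 10,
                             requireNeighbour = TRUE) {
  stopifnot(is(csd, "CSDMatrix"))
  avg <- apply(csd@values, c(1L, 2L), mean)      # channel x time
  tz <- csd@timeZero
  if (tz < 11L) stop("baseline period too short for sink detection")
  msPerSample <- 1000 / csd@sampleRate
  sustainN <- max(1L, ceiling(sustainMs / msPerSample))

  baseIdx <- 1:(tz - 1L)
  postIdx <- tz:ncol(avg)
  nCh <- nrow(avg)
  B <- matrix(FALSE, nCh, length(postIdx))
  for (ch in csd@validChannels) {
    thr <- -k * stats::sd(avg[ch, baseIdx])
    B[ch, ] <- avg[ch, postIdx] < thr
  }
  if (requireNeighbour) {
    nb <- rbind(FALSE, B[-nCh, , drop = FALSE]) |
      rbind(B[-1L, , drop = FALSE], FALSE)
    B <- B & nb
  }
  onset <- rep(NA_real_, nCh)
  for (ch in csd@validChannels) {
    below <- B[ch, ]
    r <- rle(below)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= sustainN)
    if (length(hit)) {
      start <- ends[hit[1L]] - r$lengths[hit[1L]] + 1L
      onset[ch] <- (postIdx[start] - tz) * msPerSample
    }
  }
  if (all(is.na(onset)))
    stop("no discernable CSD profile: no suprathreshold sink found")

  first <- min(onset, na.rm = TRUE)
  inSink <- !is.na(onset) & onset <= first + onsetTolMs
  # contiguous run containing the earliest-onset channel
  seedCh <- which(onset == first)[1L]
  run <- seedCh
  ch <- seedCh
  while (ch > 1L && inSink[ch - 1L]) { ch <- ch - 1L; run <- c(ch, run) }
  ch <- seedCh
  while (ch < length(inSink) && inSink[ch + 1L]) {
    ch <- ch + 1L; run <- c(run, ch)
  }
  marker <- max(run)

  nCh <- nrow(avg)
  compart <- rep("outside", nCh)
  compart[max(1L, marker - 4L):marker] <- "middle"
  if (marker - 5L >= 1L)
    compart[max(1L, marker - 9L):(marker - 5L)] <- "upper"
  if (marker + 1L <= nCh)
    compart[(marker + 1L):min(nCh, marker + 5L)] <- "deep"

  new("LaminarAlignment", markerChannel = as.integer(marker),
      compartments = compart, sinkOnsetMs = first)
}

#' Per-trial granular sink magnitude
#'
#' Averages the CSD over the 5 channels immediately above the L4/5
#' marker (the middle compartment) and a post-stimulus window, per
#' trial, and reports the negated mean so that larger values mean a
#' stronger sink.
#'
#' @param csd a [CSDMatrix-class].
#' @param align a [LaminarAlignment-class].
#' @param windowMs window in ms post-stimulus, default the feedforward
#'   window 58-78 ms.
#' @return numeric vector, one magnitude per trial.
#' @export
granularSinkMagnitude <- function(csd, align, windowMs = c(58, 78)) {
  stopifnot(is(csd, "CSDMatrix"), is(align, "LaminarAlignment"))
  msPerSample <- 1000 / csd@sampleRate
  idx <- csd@timeZero + round(windowMs / msPerSample)
  nTime <- dim(csd@values)[2L]
  if (idx[1L] < 1L || idx[2L] > nTime)
    stop("magnitude window falls outside the recording")
  chans <- intersect(max(1L, align@markerChannel - 4L):align@markerChannel,
                     csd@validChannels)
  sub <- csd@values[chans, idx[1L]:idx[2L], , drop = FALSE]
  -apply(sub, 3L, mean)
}
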