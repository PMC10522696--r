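#' @import methods
NULL

#' SessionRecording: one laminar recording session
#'
#' Container for a single laminar probe session: local field potential and
#' multiunit-envelope arrays organised channel x time x trial, sampling
#' metadata, and the per-trial behaviour table. Channel 0-based depth order
#' is not used; channel 1 is the most superficial contact and channel
#' indices increase with cortical depth.
#'
#' @slot lfp numeric array, channel x time x trial (volts).
#' @slot mua numeric array, channel x time x trial (envelope units, or
#'   z-units after [baselineNormalize()]).
#' @slot sampleRate sampling rate in Hz.
#' @slot timeZero sample index of stimulus (search array) onset.
#' @slot channelSpacingMm inter-electrode spacing in millimetres.
#' @slot trials data.frame, one row per trial (see [generateSession()] for
#'   the column dictionary).
#' @slot groundTruth list of generative parameters when the session is
#'   synthetic; empty list for real data.
#' @slot meta free-form list (units, schema version, acquisition notes).
#'
#' @export
setClass("SessionRecording",
  representation(
    lfp = "array",
    mua = "array",
    sampleRate = "numeric",
    timeZero = "integer",
    channelSpacingMm = "numeric",
    trials = "data.frame",
    groundTruth = "list",
    meta = "list"
  ),
  prototype(
    sampleRate = 1000,
    timeZero = 1L,
    channelSpacingMm = 0.1,
    groundTruth = list(),
    meta = list()
  )
)

setValidity("SessionRecording", function(object) {
  msgs <- character()
  if (length(dim(object@lfp)) != 3L)
    msgs <- c(msgs, "lfp must be a channel x time x trial array")
  if (!identical(dim(object@lfp), dim(object@mua)))
    msgs <- c(msgs, "lfp and mua must share dimensions")
  nTrial <- dim(object@mua)[3L]
  if (nrow(object@trials) != nTrial)
    msgs <- c(msgs, sprintf("trial table has %d rows but arrays hold %d trials",
                            nrow(object@trials), nTrial))
  preMs <- (object@timeZero - 1L) / object@sampleRate * 1000
  if (preMs < 100)
    msgs <- c(msgs, sprintf(
      "time axis must include >= 100 ms pre-stimulus (found %.1f ms)", preMs))
  if (length(msgs)) msgs else TRUE
})

#' CSDMatrix: current source density estimate
#'
#' Second-spatial-derivative current source density computed from laminar
#' LFP. Negative values indicate current sinks (net local depolarisation).
#' The first and last probe contacts have no defined second difference and
#' are excluded from `validChannels`.
#'
#' @slot values numeric array, channel x time x trial (edge channels NA).
#' @slot validChannels integer vector of interior channel indices.
#' @slot sampleRate sampling rate in Hz.
#' @slot timeZero stimulus-onset sample index.
#' @slot channelSpacingMm inter-electrode spacing in millimetres.
#'
#' @export
setClass("CSDMatrix",
  representation(
    values = "array",
    validChannels = "integer",
    sampleRate = "numeric",
    timeZero = "integer",
    channelSpacingMm = "numeric"
  )
)

setValidity("CSDMatrix", function(object) {
  nCh <- dim(object@values)[1L]
  if (any(object@validChannels %in% c(1L, nCh)))
    return("validChannels must exclude the first and last probe contacts")
  TRUE
})

#' LaminarAlignment: functional depth alignment of a session
#'
#' Depth alignment anchored on the bottom of the earliest post-stimulus
#' granular (L4) current sink. With 0.1 mm contact spacing the middle
#' compartment spans the 5 channels ending at the marker (0.5 mm), the
#' upper compartment the 5 channels above that, and the deep compartment
#' the 5 channels below the marker.
#'
#' @slot markerChannel channel index of the bottom of the initial sink
#'   (the functional L4/5 boundary).
#' @slot compartments character vector over channels with values
#'   "upper", "middle", "deep" or "outside".
#' @slot sinkOnsetMs onset time (ms post-stimulus) of the detected sink.
#'
#' @export
setClass("LaminarAlignment",
  representation(
    markerChannel = "integer",
    compartments = "character",
    sinkOnsetMs = "numeric"
  )
)

setValidity("LaminarAlignment", function(object) {
  ok <- all(object@compartments %in% c("upper", "middle", "deep", "outside"))
  if (!ok) return("compartments must be upper/middle/deep/outside")
  m <- object@markerChannel
  mid <- which(object@compartments == "middle")
  if (length(mid) && (max(mid) != m))
    return("middle compartment must end at the marker channel")
  TRUE
})

#' SelectionResult: population reliability selection surface
#'
#' Winner-take-all selection frequency of the oddball alternative across
#' time and population size, with the empirical chance window and the
#' first reliable crossing time per population size.
#'
#' @slot freq matrix time x population size, percent of simulations in
#'   which the oddball alternative evoked the largest summed response.
#' @slot freqAll array time x population size x alternative; per-timepoint
#'   winner frequencies over all alternatives (columns sum to 100).
#' @slot timeMs time axis in ms relative to stimulus onset.
#' @slot popSizes population sizes simulated.
#' @slot nSims Monte-Carlo simulations per (time, size) cell.
#' @slot nItems number of search alternatives.
#' @slot chance theoretical chance level, 100 / nItems (percent).
#' @slot chanceWindow empirical 99% baseline interval (percent), or NA.
#' @slot selectionTimeMs named numeric per population size: first
#'   sustained suprathreshold time (ms), NA if never crossed.
#'
#' @export
setClass("SelectionResult",
  representation(
    freq = "matrix",
    freqAll = "array",
    timeMs = "numeric",
    popSizes = "integer",
    nSims = "integer",
    nItems = "integer",
    chance = "numeric",
    chanceWindow = "numeric",
    selectionTimeMs = "numeric"
  ),
  prototype(chanceWindow = c(NA_real_, NA_real_), selectionTimeMs = numeric())
)

setValidity("SelectionResult", function(object) {
  msgs <- character()
  if (any(object@freq < 0 | object@freq > 100, na.rm = TRUE))
    msgs <- c(msgs, "selection frequencies must lie in [0, 100]")
  if (!identical(dim(object@freq),
                 c(length(object@timeMs), length(object@popSizes))))
    msgs <- c(msgs, "freq must be time x popSizes")
  cw <- object@chanceWindow
  if (!any(is.na(cw)) && (cw[1] > object@chance || cw[2] < object@chance))
    msgs <- c(msgs, "chance window must contain the chance level")
  if (length(msgs)) msgs else TRUE
})

#' PowerFitResult: posterior of the reaction-time power model
#'
#' Posterior draws and summaries for the power-function regression
#' RT_i ~ N(alpha + beta * SPK_i^r, sigma_e).
#'
#' @slot draws matrix of posterior draws, columns alpha, beta, r, sigma_e
#'   (r on the signed scale actually fitted).
#' @slot medians named posterior medians.
#' @slot ci89 2 x 4 matrix of equal-tailed 89% credible bounds
#'   (rows "5.5%", "94.5%").
#' @slot r2 Bayesian R-squared, var(fit) / (var(fit) + var(residual))
#'   summarised over draws.
#' @slot mcmcConfig list: chains, warmup, totalSamples, thin.
#' @slot diagnostics list: rhat (per parameter), neff, reliable flag.
#' @slot exponentSign +1 for the positive-support exponent prior, -1 for
#'   the signed variant r' = -r.
#' @slot scaling list recording any standardisation applied to RT and SPK.
#'
#' @export
setClass("PowerFitResult",
  representation(
    draws = "matrix",
    medians = "numeric",
    ci89 = "matrix",
    r2 = "numeric",
    mcmcConfig = "list",
    diagnostics = "list",
    exponentSign = "numeric",
    scaling = "list"
  )
)

setValidity("PowerFitResult", function(object) {
  msgs <- character()
  p <- colnames(object@draws)
  need <- c("alpha", "beta", "r", "sigma_e")
  if (!all(need %in% p))
    msgs <- c(msgs, "draws must have columns alpha, beta, r, sigma_e")
  if (all(need %in% names(object@medians))) {
    lo <- object@ci89[1L, need]; hi <- object@ci89[2L, need]
    md <- object@medians[need]
    if (any(lo > md + 1e-12) || any(hi < md - 1e-12))
      msgs <- c(msgs, "89% CI must bracket the posterior median")
  }
  if (length(object@r2) == 1L && !is.na(object@r2) &&
      (object@r2 < 0 || object@r2 > 1))
    msgs <- c(msgs, "r2 must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
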