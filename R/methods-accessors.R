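#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("lfp", "SessionRecording", function(x, ...) x@lfp)
#' @rdname accessors
#' @export
setMethod("mua", "SessionRecording", function(x, ...) x@mua)
#' @rdname accessors
#' @export
setMethod("trialTable", "SessionRecording", function(x, ...) x@trials)
#' @rdname accessors
#' @export
setMethod("sampleRate", "SessionRecording", function(x, ...) x@sampleRate)
#' @rdname accessors
#' @export
setMethod("timeZero", "SessionRecording", function(x, ...) x@timeZero)
#' @rdname accessors
#' @export
setMethod("groundTruth", "SessionRecording", function(x, ...) x@groundTruth)

#' @rdname accessors
#' @export
setMethod("timeAxis", "SessionRecording", function(x, ...) {
  (seq_len(dim(x@mua)[2L]) - x@timeZero) / x@sampleRate * 1000
})

#' @rdname accessors
#' @export
setMethod("timeAxis", "CSDMatrix", function(x, ...) {
  (seq_len(dim(x@values)[2L]) - x@timeZero) / x@sampleRate * 1000
})

#' @rdname accessors
#' @export
setMethod("csdValues", "CSDMatrix", function(x, ...) x@values)
#' @rdname accessors
#' @export
setMethod("validChannels", "CSDMatrix", function(x, ...) x@validChannels)
#' @rdname accessors
#' @export
setMethod("sampleRate", "CSDMatrix", function(x, ...) x@sampleRate)
#' @rdname accessors
#' @export
setMethod("timeZero", "CSDMatrix", function(x, ...) x@timeZero)

#' @rdname accessors
#' @export
setMethod("markerChannel", "LaminarAlignment", function(x, ...) x@markerChannel)
#' @rdname accessors
#' @export
setMethod("compartments", "LaminarAlignment", function(x, ...) x@compartments)

#' @rdname accessors
#' @export
setMethod("selectionFreq", "SelectionResult", function(x, ...) x@freq)
#' @rdname accessors
#' @export
setMethod("popSizes", "SelectionResult", function(x, ...) x@popSizes)
#' @rdname accessors
#' @export
setMethod("timeAxis", "SelectionResult", function(x, ...) x@timeMs)
#' @rdname accessors
#' @export
setMethod("chanceBounds", "SelectionResult", function(x, ...) x@chanceWindow)
#' @rdname accessors
#' @export
setMethod("selectionTimes", "SelectionResult", function(x, ...) x@selectionTimeMs)

#' @rdname accessors
#' @export
setMethod("posteriorDraws", "PowerFitResult", function(x, ...) x@draws)
#' @rdname accessors
#' @export
setMethod("posteriorMedians", "PowerFitResult", function(x, ...) x@medians)
#' @rdname accessors
#' @export
setMethod("credibleInterval89", "PowerFitResult", function(x, ...) x@ci89)
#' @rdname accessors
#' @export
setMethod("bayesR2", "PowerFitResult", function(x, ...) x@r2)

setMethod("show", "SessionRecording", function(object) {
  d <- dim(object@mua)
  cat("SessionRecording:", d[1L], "channels x", d[2L], "samples x",
      d[3L], "trials\n")
  cat("  sample rate:", object@sampleRate, "Hz; stimulus onset at sample",
      object@timeZero, "\n")
  cat("  channel spacing:", object@channelSpacingMm, "mm\n")
  if (nrow(object@trials)) {
    acc <- mean(object@trials$correct)
    cat(sprintf("  trials: %d (%.1f%% correct)\n", nrow(object@trials),
                100 * acc))
  }
  if (length(object@groundTruth))
    cat("  synthetic session with stored ground truth\n")
})

setMethod("show", "CSDMatrix", function(object) {
  d <- dim(object@values)
  cat("CSDMatrix:", d[1L], "channels x", d[2L], "samples x", d[3L],
      "trials (sinks negative)\n")
  cat("  valid channels:", min(object@validChannels), "-",
      max(object@validChannels), "\n")
})

setMethod("show", "LaminarAlignment", function(object) {
  cat("LaminarAlignment: marker (bottom of granular sink) at channel",
      object@markerChannel, "\n")
  for (comp in c("upper", "middle", "deep")) {
    ch <- which(object@compartments == comp)
    if (length(ch))
      cat(sprintf("  %-6s channels %d-%d\n", comp, min(ch), max(ch)))
  }
  cat(sprintf("  sink onset %.1f ms post-stimulus\n", object@sinkOnsetMs))
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", length(object@timeMs), "timepoints x",
      length(object@popSizes), "population sizes;",
      object@nSims, "simulations each\n")
  cat(sprintf("  %d alternatives, chance %.2f%%\n", object@nItems,
              object@chance))
  cw <- object@chanceWindow
  if (!any(is.na(cw)))
    cat(sprintf("  chance window [%.2f, %.2f]%%\n", cw[1], cw[2]))
  st <- object@selectionTimeMs
  if (length(st) && any(!is.na(st)))
    cat(sprintf("  earliest selection time %.0f ms (population size %s)\n",
                min(st, na.rm = TRUE),
                names(st)[which.min(st)]))
})

setMethod("show", "PowerFitResult", function(object) {
  cat("PowerFitResult: RT ~ N(alpha + beta * SPK^r, sigma_e)\n")
  for (p in c("alpha", "beta", "r", "sigma_e")) {
    cat(sprintf("  %-7s M = %8.4f, 89%% CI [%8.4f, %8.4f]\n", p,
                object@medians[p], object@ci89[1L, p], object@ci89[2L, p]))
  }
  cat(sprintf("  Bayesian R2 = %.3f\n", object@r2))
  if (!is.null(object@diagnostics$reliable) && !object@diagnostics$reliable)
    cat("  WARNING: diagnostics flag this fit as unreliable\n")
})
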