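#' Write a session container
#'
#' Serialises a [SessionRecording-class] to a single versioned container
#' file (R serialisation, schema "lamsel-session-1") so write/read is a
#' lossless, bit-exact round trip. The trial table can additionally be
#' exported as a diffable CSV with [writeTrialTable()].
#'
#' @param rec a [SessionRecording-class].
#' @param path output file path (conventionally `.lamsel.rds`).
#' @return `path`, invisibly.
#' @export
writeSession <- function(rec, path) {
  stopifnot(is(rec, "SessionRecording"))
  obj <- list(schema = "lamsel-session-1",
              lfp = rec@lfp, mua = rec@mua,
              sampleRate = rec@sampleRate, timeZero = rec@timeZero,
              channelSpacingMm = rec@channelSpacingMm,
              trials = rec@trials, groundTruth = rec@groundTruth,
              meta = rec@meta)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a session container
#'
#' @param path file written by [writeSession()].
#' @return a [SessionRecording-class].
#' @export
readSession <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read session container '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  if (!is.list(obj) || is.null(obj$schema))
    stop("unknown container: missing field 'schema'")
  if (!identical(obj$schema, "lamsel-session-1"))
    stop(sprintf("unknown schema version '%s'", obj$schema))
  need <- c("lfp", "mua", "sampleRate", "timeZero", "channelSpacingMm",
            "trials")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop(sprintf("container missing field(s): %s",
                 paste(miss, collapse = ", ")))
  if (!identical(dim(obj$lfp), dim(obj$mua)))
    stop("container field shape mismatch: lfp vs mua")
  new("SessionRecording", lfp = obj$lfp, mua = obj$mua,
      sampleRate = obj$sampleRate, timeZero = as.integer(obj$timeZero),
      channelSpacingMm = obj$channelSpacingMm, trials = obj$trials,
      groundTruth = if (is.null(obj$groundTruth)) list() else
        obj$groundTruth,
      meta = if (is.null(obj$meta)) list() else obj$meta)
}

#' Export the trial table as CSV
#'
#' @param rec a [SessionRecording-class] (or a trial data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrialTable <- function(rec, path) {
  tt <- if (is(rec, "SessionRecording")) trialTable(rec) else rec
  utils::write.csv(tt, path, row.names = FALSE)
  invisible(path)
}

#' Tidy table of a selection surface
#'
#' @param result a [SelectionResult-class].
#' @return data.frame: time_ms, pop_size, freq, lo, hi.
#' @export
selectionToTable <- function(result) {
  stopifnot(is(result, "SelectionResult"))
  cw <- chanceBounds(result)
  data.frame(
    time_ms = rep(result@timeMs, times = length(result@popSizes)),
    pop_size = rep(result@popSizes, each = length(result@timeMs)),
    freq = as.vector(selectionFreq(result)),
    lo = cw[1L], hi = cw[2L])
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Executes the requested stages in order -- simulate, preprocess
#' (z-scoring), align (CSD + granular sink), pra (selection surface with
#' chance window and selection times), fit-rt (power model), priming
#' (labels + baseline effect when the generator includes a shift), and
#' report (CSV/JSON/PDF artifacts) -- logging the seed and parameters of
#' every randomized stage. Rerunning with the same config and seed
#' reproduces all outputs.
#'
#' @param config list; recognised elements: `stages` (character subset
#'   of the above, in order), `cfg` ([simConfig()]), `truth`
#'   ([sessionTruth()]), `popSizes`, `nSims`, `popSize` (regression),
#'   `nSimsPerBin`, `mcmcConfig`, `exponentSign`.
#' @param seed integer seed governing every randomized stage.
#' @param outDir output directory for report artifacts.
#' @param verbose print stage progress.
#' @return list of stage results (session, zscored, csd, alignment,
#'   selection, fit, priming, files).
#' @export
runPipeline <- function(config = list(), seed = 1L,
                        outDir = tempfile("lamsel-report-"),
                        verbose = TRUE) {
  allStages <- c("simulate", "preprocess", "align", "pra", "fit-rt",
                 "priming", "report")
  stages <- config$stages %||% allStages
  bad <- setdiff(stages, allStages)
  if (length(bad))
    stop(sprintf("unknown pipeline stage(s): %s",
                 paste(bad, collapse = ", ")))
  say <- function(...) if (verbose) message(sprintf(...))
  out <- list(seed = seed)
  run <- function(stage, expr) {
    say("[%s] starting (seed %d)", stage, seed)
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  if ("simulate" %in% stages) {
    out$session <- run("simulate",
      generateSession(config$cfg %||% simConfig(),
                      config$truth %||% sessionTruth(), seed = seed))
  }
  if ("preprocess" %in% stages) {
    out$zscored <- run("preprocess",
      baselineNormalize(out$session, mode = "zscore"))
  }
  if ("align" %in% stages) {
    out$csd <- run("align", computeCSD(out$session))
    out$alignment <- run("align", findGranularSink(out$csd))
  }
  if ("pra" %in% stages) {
    out$selection <- run("pra", {
      pools <- buildResponsePools(out$zscored, out$alignment)
      popSizes <- config$popSizes %||% c(1L, 9L, 49L, 131L, 225L, 250L)
      nSims <- config$nSims %||% 1000L
      set.seed(seed + 1L)
      cw <- estimateChanceWindow(pools, popSizes = popSizes,
                                 nSims = nSims)
      res <- simulateSelection(pools, popSizes = popSizes,
                               nSims = nSims)
      applyChanceWindow(res, cw)
    })
  }
  if ("fit-rt" %in% stages) {
    out$fit <- run("fit-rt", {
      set.seed(seed + 2L)
      tab <- buildRegressionTable(out$zscored, out$alignment,
                                  popSize = config$popSize %||% 100L,
                                  nSimsPerBin =
                                    config$nSimsPerBin %||% 200L)
      fitPowerModel(tab,
                    mcmcConfig = config$mcmcConfig %||%
                      list(chains = 2L, warmup = 500L,
                           totalSamples = 2000L, thin = 2L),
                    exponentSign = config$exponentSign %||% -1,
                    standardize = TRUE, seed = seed + 3L)
    })
  }
  if ("priming" %in% stages) {
    out$priming <- run("priming", {
      tt <- trialTable(out$session)
      list(labels = labelPriming(tt),
           accuracy = accuracySummary(tt))
    })
  }
  if ("report" %in% stages) {
    out$files <- run("report", {
      dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
      files <- character(0)
      f <- file.path(outDir, "selection.csv")
      utils::write.csv(selectionToTable(out$selection), f,
                       row.names = FALSE)
      files <- c(files, f)
      f <- file.path(outDir, "fit.json")
      jsonlite::write_json(list(
        medians = as.list(posteriorMedians(out$fit)),
        ci89 = apply(credibleInterval89(out$fit), 2L, as.numeric,
                     simplify = FALSE),
        r2 = bayesR2(out$fit),
        seed = seed), f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
      f <- file.path(outDir, "selection-surface.pdf")
      grDevices::pdf(f, width = 6, height = 4)
      plotSelection(out$selection)
      grDevices::dev.off()
      files <- c(files, f)
      f <- file.path(outDir, "rt-vs-response.pdf")
      grDevices::pdf(f, width = 6, height = 4)
      plotPowerFit(out$fit)
      grDevices::dev.off()
      files <- c(files, f)
      say("[report] wrote %d artifact(s) to %s", length(files), outDir)
      files
    })
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a selection surface
#'
#' Oddball selection frequency over time, one trace per population
#' size, with the chance level and empirical chance window.
#'
#' @param result a [SelectionResult-class].
#' @export
plotSelection <- function(result) {
  stopifnot(is(result, "SelectionResult"))
  freq <- selectionFreq(result)
  shade <- grDevices::gray.colors(ncol(freq), 0.8, 0.1)
  graphics::matplot(result@timeMs, freq, type = "l", lty = 1,
                    col = shade, xlab = "time from display (ms)",
                    ylab = "oddball selection (%)",
                    main = "population reliability analysis")
  graphics::abline(h = result@chance, lty = 2)
  cw <- chanceBounds(result)
  if (!any(is.na(cw))) graphics::abline(h = cw, lty = 3, col = "red")
  graphics::legend("topleft", bty = "n", lty = 1, col = shade,
                   legend = paste("n =", result@popSizes), cex = 0.7)
}

#' Plot reaction time against population response with the fitted
#' power function
#'
#' @param fit a [PowerFitResult-class].
#' @param table optional regression table to overlay as points.
#' @export
plotPowerFit <- function(fit, table = NULL) {
  stopifnot(is(fit, "PowerFitResult"))
  m <- posteriorMedians(fit)
  if (!is.null(table)) {
    spk <- table$spk / fit@scaling$spkDivisor
    rt <- table$rt / fit@scaling$rtDivisor
    graphics::plot(spk, rt, pch = 16, cex = 0.3,
                   col = grDevices::adjustcolor("black", 0.2),
                   xlab = "population response (standardized)",
                   ylab = "reaction time")
  } else {
    spk <- seq(0.5, 3, length.out = 50)
    graphics::plot(NA, xlim = range(spk),
                   ylim = m[["alpha"]] +
                     m[["beta"]] * range(spk^m[["r"]]),
                   xlab = "population response (standardized)",
                   ylab = "reaction time")
  }
  xs <- seq(min(spk), max(spk), length.out = 200)
  draws <- posteriorDraws(fit)
  idx <- round(seq(1L, nrow(draws), length.out = min(200L, nrow(draws))))
  band <- vapply(xs, function(x) {
    stats::quantile(draws[idx, "alpha"] +
                      draws[idx, "beta"] * x^draws[idx, "r"],
                    c(0.055, 0.5, 0.945))
  }, numeric(3))
  graphics::polygon(c(xs, rev(xs)), c(band[1L, ], rev(band[3L, ])),
                    col = grDevices::adjustcolor("magenta", 0.3),
                    border = NA)
  graphics::lines(xs, band[2L, ], col = "magenta", lwd = 2)
}
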