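#' Rank reaction times within session and bin by percentile
#'
#' Correct trials are ranked by reaction time within each session (so
#' every session contributes equally to every bin), converted to
#' percentiles, and cut into equal-width percentile bins. The coarse
#' scheme uses 4 bins (quartiles); the fine scheme uses 25 bins with the
#' slowest bin flagged as excluded (outliers in otherwise efficient
#' pop-out search).
#'
#' @param trials a trial table (or [SessionRecording-class]).
#' @param scheme "quartile" (4 bins) or "fine" (25 bins, 24 used).
#' @param nBins optional override of the bin count.
#' @return data.frame: session_id, trial_id, rt_ms, pct_rank, bin,
#'   excluded.
#' @export
rankAndBinRTs <- function(trials, scheme = c("quartile", "fine"),
                          nBins = NULL) {
  if (is(trials, "SessionRecording")) trials <- trialTable(trials)
  scheme <- match.arg(scheme)
  if (is.null(nBins)) nBins <- if (scheme == "quartile") 4L else 25L
  tt <- trials[trials$correct & !is.na(trials$rt_ms), , drop = FALSE]
  out <- lapply(split(tt, tt$session_id), function(ss) {
    n <- nrow(ss)
    if (n < nBins)
      stop(sprintf("session %s has %d correct trials; need >= %d for %d bins",
                   ss$session_id[1L], n, nBins, nBins))
    rk <- rank(ss$rt_ms, ties.method = "first")
    pct <- rk / n
    bin <- pmin(nBins, ceiling(pct * nBins))
    data.frame(session_id = ss$session_id, trial_id = ss$trial_id,
               rt_ms = ss$rt_ms, pct_rank = pct, bin = as.integer(bin),
               excluded = scheme == "fine" & bin == nBins,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-session accuracy and reaction-time summary
#'
#' @param trials a trial table (or [SessionRecording-class]).
#' @return data.frame per session: nTrials, accuracyPct, meanRtMs,
#'   medianRtMs (RT over correct trials).
#' @export
accuracySummary <- function(trials) {
  if (is(trials, "SessionRecording")) trials <- trialTable(trials)
  stopifnot(nrow(trials) >= 1L)
  out <- lapply(split(trials, trials$session_id), function(ss) {
    ok <- ss$correct
    data.frame(session_id = ss$session_id[1L], nTrials = nrow(ss),
               accuracyPct = 100 * mean(ok),
               meanRtMs = if (any(ok)) mean(ss$rt_ms[ok]) else NA_real_,
               medianRtMs = if (any(ok)) stats::median(ss$rt_ms[ok])
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Label trials by priming state
#'
#' The first trial after a target-feature switch is "not_primed"; trials
#' at or beyond the k-th repetition within a block are "primed"; trials
#' in between are "excluded". A pure function of trial_in_block.
#'
#' @param trials a trial table (or [SessionRecording-class]).
#' @param k repetition threshold for "primed" (default 3).
#' @return character vector of labels, one per trial.
#' @export
labelPriming <- function(trials, k = 3L) {
  if (is(trials, "SessionRecording")) trials <- trialTable(trials)
  if (is.null(trials$trial_in_block) || anyNA(trials$trial_in_block))
    stop("trial table lacks block structure (trial_in_block)")
  ifelse(trials$trial_in_block == 1L, "not_primed",
         ifelse(trials$trial_in_block >= k, "primed", "excluded"))
}

#' Priming modulation of baseline activity in feature columns
#'
#' For each color-selective column, computes the difference in raw
#' (not baseline-corrected) pre-stimulus population spiking between
#' trials whose target color matches the column's preference and trials
#' whose target color does not -- separately for primed and not-primed
#' trials -- then compares primed vs not-primed differences across
#' columns with a paired two-sided t test.
#'
#' @param sessions list of raw [SessionRecording-class] objects (one
#'   per column); do not z-score first, the tonic shift is the signal.
#' @param prefs character vector of preferred colors, one per column
#'   ("red"/"green").
#' @param alignments optional [LaminarAlignment-class] list restricting
#'   channels to cortex.
#' @param k priming repetition threshold (see [labelPriming()]).
#' @param baselineMs pre-stimulus window (ms).
#' @return list: `perColumn` data.frame (column, diffPrimed,
#'   diffNotPrimed), `statistic`, `p.value`.
#' @export
primingBaselineEffect <- function(sessions, prefs, alignments = NULL,
                                  k = 3L, baselineMs = 100) {
  if (is(sessions, "SessionRecording")) sessions <- list(sessions)
  if (is(alignments, "LaminarAlignment")) alignments <- list(alignments)
  if (is.null(prefs) || length(prefs) != length(sessions))
    stop("need one color-preference label per column")
  nRed <- sum(prefs == "red"); nGreen <- sum(prefs == "green")
  if (nRed < 1L || nGreen < 1L)
    stop("need at least one red- and one green-preferring column")
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    ch <- if (!is.null(alignments))
      which(compartments(alignments[[i]]) != "outside")
    else seq_len(dim(mua(s))[1L])
    timeMs <- timeAxis(s)
    bIdx <- which(timeMs >= -baselineMs & timeMs < 0)
    base <- apply(mua(s)[ch, bIdx, , drop = FALSE], 3L, mean)
    tt <- trialTable(s)
    lab <- labelPriming(tt, k)
    pref <- tt$target_color == prefs[i]
    d <- function(state) {
      a <- base[lab == state & pref]; b <- base[lab == state & !pref]
      if (!length(a) || !length(b)) return(NA_real_)
      mean(a) - mean(b)
    }
    data.frame(column = i, pref = prefs[i],
               diffPrimed = d("primed"), diffNotPrimed = d("not_primed"))
  })
  perColumn <- do.call(rbind, rows)
  ok <- stats::complete.cases(perColumn[, c("diffPrimed",
                                            "diffNotPrimed")])
  tt <- stats::t.test(perColumn$diffPrimed[ok],
                      perColumn$diffNotPrimed[ok], paired = TRUE)
  list(perColumn = perColumn, statistic = unname(tt$statistic),
       p.value = tt$p.value)
}

#' Refit the power model on not-primed trials only
#'
#' Reduces the data to trials immediately following a target-feature
#' switch and rebuilds the RT regression table and power fit, to check
#' that the feedforward RT relationship does not require priming. When
#' a session has too few not-primed trials for the fine scheme, fewer
#' bins are used (merged), with a message.
#'
#' @param sessions z-scored [SessionRecording-class] (list).
#' @param alignments optional [LaminarAlignment-class] list.
#' @param popSize,nSimsPerBin,windowMs,seed as for
#'   [buildRegressionTable()].
#' @param minPerBin minimum correct not-primed trials per bin before
#'   bins are merged.
#' @param ... forwarded to [fitPowerModel()].
#' @return a [PowerFitResult-class].
#' @export
notPrimedModelCheck <- function(sessions, alignments = NULL,
                                popSize = 250L, nSimsPerBin = 500L,
                                windowMs = c(58, 78), seed = NULL,
                                minPerBin = 4L, ...) {
  if (is(sessions, "SessionRecording")) sessions <- list(sessions)
  allTrials <- do.call(rbind, lapply(sessions, trialTable))
  lab <- labelPriming(allTrials)
  sub <- allTrials[lab == "not_primed", , drop = FALSE]
  if (!nrow(sub)) stop("no not-primed trials in the data")
  nOk <- min(table(sub$session_id[sub$correct]))
  nBins <- min(25L, max(2L, floor(nOk / minPerBin)))
  if (nBins < 25L)
    message(sprintf(
      "not-primed subset supports only %d RT bins; merging bins", nBins))
  binning <- rankAndBinRTs(sub, "fine", nBins = nBins)
  tab <- buildRegressionTable(sessions, alignments, binning,
                              popSize = popSize,
                              nSimsPerBin = nSimsPerBin,
                              windowMs = windowMs, seed = seed)
  fitPowerModel(tab, ...)
}
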