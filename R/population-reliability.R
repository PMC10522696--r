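#' Assemble trial-level response pools from sessions
#'
#' Builds the pseudo-population response pools the reliability analysis
#' samples from. Each pool row is one trial-level multiunit response
#' (one in-cortex channel on one qualifying trial), so pooling across
#' sessions yields the across-session pseudo-population.
#'
#' @param sessions a [SessionRecording-class] or list of them; `mua`
#'   should already be baseline z-scored (see [baselineNormalize()])
#'   unless raw baselines are wanted.
#' @param alignments optional [LaminarAlignment-class] (or list, matched
#'   to sessions) used to restrict channels to cortex; if missing, all
#'   channels are used.
#' @param channels optional explicit channel indices overriding
#'   alignments.
#' @param correctOnly keep only correct trials (default TRUE).
#' @param geometry optional filter on distractor geometry
#'   ("adjacent", "opposite", "other").
#' @return list with matrices `oddball` and `distractor`
#'   (rows = unit-trials, columns = timepoints), the time axis `timeMs`,
#'   and bookkeeping counts.
#' @export
buildResponsePools <- function(sessions, alignments = NULL,
                               channels = NULL, correctOnly = TRUE,
                               geometry = NULL) {
  if (is(sessions, "SessionRecording")) sessions <- list(sessions)
  if (is(alignments, "LaminarAlignment")) alignments <- list(alignments)
  odd <- list(); dist <- list(); timeMs <- NULL
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    tt <- trialTable(s)
    ch <- channels
    if (is.null(ch)) {
      ch <- if (!is.null(alignments))
        which(compartments(alignments[[i]]) != "outside")
      else seq_len(dim(mua(s))[1L])
    }
    keep <- if (correctOnly) tt$correct else rep(TRUE, nrow(tt))
    oddTr <- which(keep & tt$rf_item == "target")
    distTr <- which(keep & tt$rf_item == "distractor")
    if (!is.null(geometry))
      distTr <- intersect(distTr, which(tt$rf_geometry == geometry))
    odd[[i]] <- flattenPool(mua(s), ch, oddTr)
    dist[[i]] <- flattenPool(mua(s), ch, distTr)
    timeMs <- timeAxis(s)
  }
  list(oddball = do.call(rbind, odd), distractor = do.call(rbind, dist),
       timeMs = timeMs)
}

# channel x time x trial -> (channel * trial) x time matrix
flattenPool <- function(arr, channels, trials) {
  if (!length(trials) || !length(channels))
    return(matrix(numeric(0), 0L, dim(arr)[2L]))
  sub <- arr[channels, , trials, drop = FALSE]
  d <- dim(sub)
  matrix(aperm(sub, c(1L, 3L, 2L)), d[1L] * d[3L], d[2L])
}

# Sum popSize trial-level time courses drawn with replacement, once per
# simulation (the same drawn trials are used at every timepoint, so each
# simulated population keeps whole time courses). Returns nSims x nT.
# Small pools go through a multinomial-count matrix product (BLAS);
# large pools through index sampling + rowsum, chunked to bound memory.
drawSums <- function(pool, popSize, nSims) {
  nPool <- nrow(pool); nT <- ncol(pool)
  if (nPool <= 4096L) {
    counts <- stats::rmultinom(nSims, popSize, rep(1 / nPool, nPool))
    return(crossprod(counts, pool))
  }
  out <- matrix(NA_real_, nSims, nT)
  chunk <- max(1L, floor(2e6 / (popSize * max(1L, nT) / 64)))
  s <- 1L
  while (s <= nSims) {
    e <- min(nSims, s + chunk - 1L)
    nc <- e - s + 1L
    idx <- sample.int(nPool, popSize * nc, replace = TRUE)
    out[s:e, ] <- rowsum(pool[idx, , drop = FALSE],
                         group = rep(seq_len(nc), each = popSize),
                         reorder = FALSE)
    s <- e + 1L
  }
  out
}

#' Monte-Carlo winner-take-all selection frequency
#'
#' The population reliability analysis. For each simulation and each of
#' `nItems` alternatives, `popSize` trial-level responses are drawn with
#' replacement from that alternative's pool and summed; at every
#' timepoint the alternative with the largest summed response wins (ties
#' broken uniformly at random). The oddball's win percentage over
#' `nSims` simulations, per timepoint and population size, is the
#' selection-accuracy surface. One oddball pool plus one distractor pool
#' (reused for the remaining alternatives) is the standard design; a
#' full per-alternative pool list may be supplied for conditioned
#' variants.
#'
#' @param pools list with `oddball` and `distractor` matrices
#'   (rows = trial-level responses, columns = timepoints) and optional
#'   `timeMs`; alternatively a list `alternatives` of `nItems` pool
#'   matrices, oddball first.
#' @param nItems number of search alternatives (chance = 100 / nItems).
#' @param popSizes population sizes to simulate.
#' @param nSims Monte-Carlo simulations per cell.
#' @param seed optional RNG seed.
#' @param timeMs time axis for the pool columns (ms re: stimulus onset).
#' @return a [SelectionResult-class].
#' @export
simulateSelection <- function(pools, nItems = 6L,
                              popSizes = c(1L, 9L, 49L, 131L, 225L, 250L),
                              nSims = 1000L, seed = NULL, timeMs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alts <- poolAlternatives(pools, nItems)
  nT <- ncol(alts[[1L]])
  if (is.null(timeMs)) timeMs <- pools$timeMs
  if (is.null(timeMs)) timeMs <- seq_len(nT)
  popSizes <- as.integer(popSizes)
  nSims <- as.integer(nSims)

  freqAll <- array(NA_real_, dim = c(nT, length(popSizes), nItems))
  for (pi in seq_along(popSizes)) {
    p <- popSizes[pi]
    big <- matrix(NA_real_, nSims * nT, nItems)
    for (a in seq_len(nItems)) {
      pool <- alts[[a]]
      if (p > nrow(pool))
        message(sprintf(
          "population size %d exceeds pool size %d (alternative %d); sampling with replacement",
          p, nrow(pool), a))
      big[, a] <- as.vector(drawSums(pool, p, nSims))   # nSims x nT
    }
    w <- max.col(big, ties.method = "random")
    for (a in seq_len(nItems))
      freqAll[, pi, a] <- 100 * colMeans(matrix(w == a, nSims, nT))
  }
  dimnames(freqAll) <- list(NULL, as.character(popSizes), NULL)
  freq <- freqAll[, , 1L, drop = FALSE]
  dim(freq) <- c(nT, length(popSizes))
  colnames(freq) <- as.character(popSizes)

  new("SelectionResult", freq = freq, freqAll = freqAll,
      timeMs = as.numeric(timeMs), popSizes = popSizes,
      nSims = nSims, nItems = as.integer(nItems),
      chance = 100 / nItems,
      chanceWindow = c(NA_real_, NA_real_),
      selectionTimeMs = stats::setNames(rep(NA_real_, length(popSizes)),
                                        as.character(popSizes)))
}

poolAlternatives <- function(pools, nItems) {
  if (!is.null(pools$alternatives)) {
    alts <- pools$alternatives
    if (length(alts) != nItems)
      stop(sprintf("need %d alternative pools, got %d", nItems,
                   length(alts)))
  } else {
    if (is.null(pools$oddball) || is.null(pools$distractor))
      stop("pools must contain 'oddball' and 'distractor' matrices")
    alts <- c(list(pools$oddball),
              rep(list(pools$distractor), nItems - 1L))
  }
  for (a in alts) {
    if (!nrow(a)) stop("empty response pool")
  }
  nT <- unique(vapply(alts, ncol, 1L))
  if (length(nT) != 1L) stop("all pools must share the time axis")
  alts
}

#' Empirical chance window from the pre-stimulus baseline
#'
#' Runs the reliability analysis on baseline (pre-stimulus) timepoints
#' only and returns the 0.5th and 99.5th percentiles of the pooled
#' selection frequencies across all timepoints and population sizes --
#' the 99% interval of selection accuracy expected in the absence of
#' visual stimulation.
#'
#' @param pools as for [simulateSelection()]; `timeMs` required to
#'   locate the baseline.
#' @param baselineMs length of the pre-stimulus epoch to use (ms).
#' @param nItems,popSizes,nSims,seed as for [simulateSelection()].
#' @return numeric `c(lo, hi)` in percent.
#' @export
estimateChanceWindow <- function(pools, baselineMs = 100, nItems = 6L,
                                 popSizes = c(1L, 9L, 49L, 131L, 225L,
                                              250L),
                                 nSims = 1000L, seed = NULL) {
  timeMs <- pools$timeMs
  if (is.null(timeMs)) stop("pools must carry timeMs to locate baseline")
  idx <- which(timeMs >= -baselineMs & timeMs < 0)
  if (length(idx) < 10L)
    stop("baseline shorter than 10 samples")
  base <- restrictPools(pools, idx)
  res <- simulateSelection(base, nItems = nItems, popSizes = popSizes,
                           nSims = nSims, seed = seed,
                           timeMs = timeMs[idx])
  stats::quantile(as.vector(selectionFreq(res)), c(0.005, 0.995),
                  names = FALSE)
}

restrictPools <- function(pools, idx) {
  out <- pools
  if (!is.null(out$alternatives))
    out$alternatives <- lapply(out$alternatives,
                               function(m) m[, idx, drop = FALSE])
  if (!is.null(out$oddball)) out$oddball <- out$oddball[, idx, drop = FALSE]
  if (!is.null(out$distractor))
    out$distractor <- out$distractor[, idx, drop = FALSE]
  if (!is.null(out$timeMs)) out$timeMs <- out$timeMs[idx]
  out
}

#' Attach a chance window and derive selection times
#'
#' Stores the empirical chance window on a [SelectionResult-class] and
#' computes, per population size, the first post-stimulus time at which
#' the oddball selection frequency exceeds the upper bound sustained for
#' at least `sustainMs` consecutive milliseconds (single-sample
#' Monte-Carlo blips do not count). NA where never crossed.
#'
#' @param result a [SelectionResult-class].
#' @param window numeric `c(lo, hi)` from [estimateChanceWindow()].
#' @param sustainMs minimum suprathreshold duration (ms).
#' @return the updated [SelectionResult-class].
#' @export
applyChanceWindow <- function(result, window, sustainMs = 5) {
  stopifnot(is(result, "SelectionResult"), length(window) == 2L)
  result@chanceWindow <- as.numeric(window)
  result@selectionTimeMs <- computeSelectionTimes(result, sustainMs)
  validObject(result)
  result
}

#' First sustained suprathreshold selection time per population size
#'
#' @param result a [SelectionResult-class] with its chance window set
#'   (see [applyChanceWindow()]), or pass `hi` explicitly.
#' @param sustainMs minimum suprathreshold duration (ms).
#' @param hi upper chance bound (percent); defaults to the stored one.
#' @return named numeric vector (ms re: stimulus onset), NA = no
#'   reliable crossing.
#' @export
computeSelectionTimes <- function(result, sustainMs = 5, hi = NULL) {
  stopifnot(is(result, "SelectionResult"))
  if (is.null(hi)) hi <- result@chanceWindow[2L]
  if (is.na(hi)) stop("chance window not set")
  timeMs <- result@timeMs
  post <- which(timeMs >= 0)
  msPerSample <- if (length(timeMs) > 1L) diff(timeMs[1:2]) else 1
  sustainN <- max(1L, ceiling(sustainMs / msPerSample))
  out <- stats::setNames(rep(NA_real_, length(result@popSizes)),
                         as.character(result@popSizes))
  for (pi in seq_along(result@popSizes)) {
    above <- result@freq[post, pi] > hi
    r <- rle(above)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= sustainN)
    if (length(hit)) {
      start <- ends[hit[1L]] - r$lengths[hit[1L]] + 1L
      out[pi] <- timeMs[post[start]]
    }
  }
  out
}

#' Depth-resolved selection profiles
#'
#' Restricts the response pools to each of `nDepths` aligned cortical
#' depths (spanning the upper, middle and deep compartments relative to
#' the granular marker) and runs the reliability analysis per depth.
#'
#' @param sessions list of z-scored [SessionRecording-class] objects.
#' @param alignments matching list of [LaminarAlignment-class] objects.
#' @param nDepths number of aligned depths (default 15: 5 upper, 5
#'   middle, 5 deep).
#' @param popSize population size (default 250).
#' @param nItems,nSims,seed as for [simulateSelection()].
#' @return named list of [SelectionResult-class], one per depth
#'   (superficial first); depths with no units are NULL.
#' @export
depthResolvedSelection <- function(sessions, alignments, nDepths = 15L,
                                   popSize = 250L, nItems = 6L,
                                   nSims = 1000L, seed = NULL) {
  if (is(sessions, "SessionRecording")) sessions <- list(sessions)
  if (is(alignments, "LaminarAlignment")) alignments <- list(alignments)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nDepths)
  names(out) <- sprintf("depth_%02d", seq_len(nDepths))
  for (d in seq_len(nDepths)) {
    odd <- list(); dist <- list(); timeMs <- NULL
    for (i in seq_along(sessions)) {
      s <- sessions[[i]]
      marker <- markerChannel(alignments[[i]])
      ch <- marker - 10L + d          # depth 1 = top of upper compartment
      if (ch < 1L || ch > dim(mua(s))[1L]) next
      tt <- trialTable(s)
      odd[[length(odd) + 1L]] <-
        flattenPool(mua(s), ch, which(tt$correct & tt$rf_item == "target"))
      dist[[length(dist) + 1L]] <-
        flattenPool(mua(s), ch,
                    which(tt$correct & tt$rf_item == "distractor"))
      timeMs <- timeAxis(s)
    }
    if (!length(odd)) next                      # depth with no units
    pools <- list(oddball = do.call(rbind, odd),
                  distractor = do.call(rbind, dist), timeMs = timeMs)
    out[[d]] <- simulateSelection(pools, nItems = nItems,
                                  popSizes = popSize, nSims = nSims)
  }
  out
}

#' Within-trial (structure-preserving) selection
#'
#' Variant in which each sampled population is the set of simultaneously
#' recorded multiunits of a single cortical column on a single trial,
#' preserving within-trial correlation structure. Implemented by
#' collapsing each trial to its across-channel population sum and
#' running the reliability analysis with population size 1 over those
#' column-trial responses.
#'
#' @param sessions list of z-scored [SessionRecording-class] objects.
#' @param alignments matching list of [LaminarAlignment-class] (or NULL
#'   to use all channels).
#' @param nItems,nSims,seed as for [simulateSelection()].
#' @return a [SelectionResult-class].
#' @export
withinTrialSelection <- function(sessions, alignments = NULL,
                                 nItems = 6L, nSims = 1000L,
                                 seed = NULL) {
  if (is(sessions, "SessionRecording")) sessions <- list(sessions)
  if (is(alignments, "LaminarAlignment")) alignments <- list(alignments)
  odd <- list(); dist <- list(); timeMs <- NULL
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    ch <- if (!is.null(alignments))
      which(compartments(alignments[[i]]) != "outside")
    else seq_len(dim(mua(s))[1L])
    colsum <- apply(mua(s)[ch, , , drop = FALSE], c(2L, 3L), sum)
    tt <- trialTable(s)
    odd[[i]] <- t(colsum[, tt$correct & tt$rf_item == "target",
                         drop = FALSE])
    dist[[i]] <- t(colsum[, tt$correct & tt$rf_item == "distractor",
                          drop = FALSE])
    timeMs <- timeAxis(s)
  }
  pools <- list(oddball = do.call(rbind, odd),
                distractor = do.call(rbind, dist), timeMs = timeMs)
  simulateSelection(pools, nItems = nItems, popSizes = 1L,
                    nSims = nSims, seed = seed)
}

#' Selection on error trials (signed relative to chance)
#'
#' Builds pools from incorrect trials -- the oddball pool from trials
#' where the target sat in the RF, and a "chosen distractor" pool from
#' trials where the errantly fixated distractor sat in the RF -- and runs
#' the reliability analysis with the chosen distractor as one of the
#' alternatives. The signed metric (oddball frequency minus chance) goes
#' negative when the chosen distractor systematically wins.
#'
#' @param sessions list of z-scored [SessionRecording-class] objects.
#' @param alignments optional matching [LaminarAlignment-class] list.
#' @param nItems,popSizes,nSims,seed as for [simulateSelection()].
#' @param minTrials warn below this many error trials per condition.
#' @return list with `result` (a [SelectionResult-class]) and `signed`
#'   (matrix time x popSize, oddball frequency minus chance, percent).
#' @export
errorTrialSelection <- function(sessions, alignments = NULL, nItems = 6L,
                                popSizes = c(1L, 49L, 250L),
                                nSims = 1000L, seed = NULL,
                                minTrials = 50L) {
  if (is(sessions, "SessionRecording")) sessions <- list(sessions)
  if (is(alignments, "LaminarAlignment")) alignments <- list(alignments)
  odd <- list(); chosen <- list(); dist <- list(); timeMs <- NULL
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    ch <- if (!is.null(alignments))
      which(compartments(alignments[[i]]) != "outside")
    else seq_len(dim(mua(s))[1L])
    tt <- trialTable(s)
    err <- !tt$correct
    odd[[i]] <- flattenPool(mua(s), ch,
                            which(err & tt$rf_item == "target"))
    chosen[[i]] <- flattenPool(mua(s), ch,
                               which(err & tt$rf_item == "distractor" &
                                       tt$chosen_position ==
                                         tt$rf_position))
    dist[[i]] <- flattenPool(mua(s), ch,
                             which(err & tt$rf_item == "distractor" &
                                     tt$chosen_position !=
                                       tt$rf_position))
    timeMs <- timeAxis(s)
  }
  oddM <- do.call(rbind, odd); choM <- do.call(rbind, chosen)
  disM <- do.call(rbind, dist)
  for (nm in c("oddball", "chosen distractor", "other distractor")) {
    n <- nrow(switch(nm, oddball = oddM, `chosen distractor` = choM,
                     `other distractor` = disM))
    if (n < minTrials)
      warning(sprintf(
        "only %d error-trial responses in the %s pool; Monte-Carlo error will be wide",
        n, nm))
  }
  pools <- list(alternatives = c(list(oddM), list(choM),
                                 rep(list(disM), nItems - 2L)),
                timeMs = timeMs)
  res <- simulateSelection(pools, nItems = nItems, popSizes = popSizes,
                           nSims = nSims, seed = seed, timeMs = timeMs)
  list(result = res, signed = selectionFreq(res) - res@chance)
}

#' Baseline selection bias between two trial groups
#'
#' Computes, for each Monte-Carlo simulation, the fraction of baseline
#' (pre-stimulus) timepoints at which the oddball alternative won, for
#' two groups of pools, and compares the two distributions with a
#' two-sample pooled-variance t test.
#'
#' @param poolsA,poolsB pool lists as for [simulateSelection()]
#'   (each with `timeMs`).
#' @param windowMs pre-stimulus window length (ms), default 50.
#' @param nItems,popSize,nSims,seed as for [simulateSelection()].
#' @return list with per-sim baseline frequencies `groupA`, `groupB`
#'   (percent), and `statistic`, `p.value` of the t test.
#' @export
baselineBias <- function(poolsA, poolsB, windowMs = 50, nItems = 6L,
                         popSize = 250L, nSims = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- perSimBaselineFreq(poolsA, windowMs, nItems, popSize, nSims)
  b <- perSimBaselineFreq(poolsB, windowMs, nItems, popSize, nSims)
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 simulations per group")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(groupA = a, groupB = b,
       statistic = unname(tt$statistic), p.value = tt$p.value)
}

perSimBaselineFreq <- function(pools, windowMs, nItems, popSize, nSims) {
  timeMs <- pools$timeMs
  if (is.null(timeMs)) stop("pools must carry timeMs")
  idx <- which(timeMs >= -windowMs & timeMs < 0)
  if (!length(idx)) stop("no baseline samples in the requested window")
  alts <- poolAlternatives(restrictPools(pools, idx), nItems)
  nT <- length(idx)
  big <- matrix(NA_real_, nSims * nT, nItems)
  for (a in seq_len(nItems))
    big[, a] <- as.vector(drawSums(alts[[a]], popSize, nSims))
  w <- max.col(big, ties.method = "random")
  100 * rowMeans(matrix(w == 1L, nSims, nT))
}

#' Per-unit feature (red vs green) selectivity
#'
#' Two-alternative reliability analysis at the single-unit level: sample
#' `nDraw` red and `nDraw` green trial responses, compare the sums, and
#' repeat `nSims` times. Returns the percent of simulations in which red
#' evoked the larger sum; 50% means unselective.
#'
#' @param redResponses,greenResponses per-unit response values -- either
#'   numeric vectors (one unit) or lists of vectors (one per unit). Use
#'   the mean response 60-160 ms post-display per trial.
#' @param nDraw responses sampled per color (default 100). Pools at
#'   least this large are sampled without replacement; smaller pools are
#'   sampled with replacement (with a message).
#' @param nSims simulations (default 1000).
#' @param seed optional RNG seed.
#' @return numeric vector, percent red preference per unit.
#' @export
featureSelectivity <- function(redResponses, greenResponses,
                               nDraw = 100L, nSims = 1000L, seed = NULL) {
  if (!is.list(redResponses)) redResponses <- list(redResponses)
  if (!is.list(greenResponses)) greenResponses <- list(greenResponses)
  stopifnot(length(redResponses) == length(greenResponses))
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_along(redResponses), function(u) {
    red <- redResponses[[u]]; green <- greenResponses[[u]]
    sumDraws <- function(v) {
      if (length(v) >= nDraw) {
        colSums(matrix(v[vapply(seq_len(nSims),
                                function(i) sample.int(length(v), nDraw),
                                integer(nDraw))], nDraw, nSims))
      } else {
        message(sprintf(
          "pool of %d < %d responses; sampling with replacement",
          length(v), nDraw))
        colSums(matrix(sample(v, nDraw * nSims, replace = TRUE),
                       nDraw, nSims))
      }
    }
    rs <- sumDraws(red); gs <- sumDraws(green)
    wins <- rs > gs
    ties <- rs == gs
    if (any(ties)) wins[ties] <- stats::runif(sum(ties)) < 0.5
    100 * mean(wins)
  }, numeric(1))
}

#' Selection conditioned on distractor geometry
#'
#' Re-runs the reliability analysis using only trials where the
#' RF distractor sat adjacent to (ring distance 1) or opposite
#' (ring distance 3 in a 6-item array) the target.
#'
#' @param sessions list of z-scored [SessionRecording-class] objects.
#' @param alignments optional matching [LaminarAlignment-class] list.
#' @param geometries which distractor geometries to analyse.
#' @param nItems,popSizes,nSims,seed as for [simulateSelection()].
#' @return named list of [SelectionResult-class] per geometry.
#' @export
adjacencyConditionedSelection <- function(sessions, alignments = NULL,
                                          geometries = c("adjacent",
                                                         "opposite"),
                                          nItems = 6L,
                                          popSizes = c(1L, 49L, 250L),
                                          nSims = 1000L, seed = NULL) {
  if (is(sessions, "SessionRecording")) sessions <- list(sessions)
  tt1 <- trialTable(sessions[[1L]])
  if (is.null(tt1$rf_geometry) || all(is.na(tt1$rf_geometry)))
    stop("trial table lacks rf_geometry labels")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(geometries, function(g) {
    pools <- buildResponsePools(sessions, alignments, geometry = g)
    simulateSelection(pools, nItems = nItems, popSizes = popSizes,
                      nSims = nSims)
  })
  names(out) <- geometries
  out
}
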