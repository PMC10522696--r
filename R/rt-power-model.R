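#' Locate the feedforward sensory response window
#'
#' The feedforward window is the 20 ms that follows the time at which
#' the mean population response first reaches 50% of its post-stimulus
#' maximum. Scale-invariant in amplitude and shift-equivariant in time.
#'
#' @param meanResponse numeric vector, mean population response.
#' @param timeMs matching time axis (ms re: stimulus onset).
#' @param windowLengthMs window length after the latency (default 20).
#' @return list with `latencyMs` and `windowMs = c(latency, latency+20)`.
#' @export
findFeedforwardWindow <- function(meanResponse, timeMs,
                                  windowLengthMs = 20) {
  stopifnot(length(meanResponse) == length(timeMs))
  post <- which(timeMs >= 0)
  if (!length(post)) stop("no post-stimulus samples")
  resp <- meanResponse[post]
  if (max(resp) - min(resp) <= .Machine$double.eps * 100)
    stop("flat response: no feedforward latency defined")
  peak <- max(resp)
  cross <- which(resp >= 0.5 * peak)[1L]
  latency <- timeMs[post[cross]]
  list(latencyMs = latency,
       windowMs = c(latency, latency + windowLengthMs))
}

#' Build the RT-vs-population-response regression table
#'
#' For each fine RT bin, simulates `nSimsPerBin` population responses:
#' each draws `popSize` unit-trial oddball responses (with replacement)
#' from that bin, sums their feedforward-window averages to give SPK_i,
#' and takes the mean reaction time of the sampled trials as RT_i.
#'
#' @param sessions a z-scored [SessionRecording-class] or list of them.
#' @param alignments optional [LaminarAlignment-class] (list) used to
#'   restrict channels to cortex.
#' @param binning optional result of [rankAndBinRTs()]; computed with
#'   the fine scheme when missing.
#' @param popSize population size per simulated trial (default 250).
#' @param nSimsPerBin simulated trials per bin (default 1000).
#' @param windowMs feedforward window (ms post-stimulus).
#' @param seed optional RNG seed.
#' @return data.frame with columns bin, sim, spk, rt (one row per
#'   simulated trial; spk in summed z-units, rt in ms).
#' @export
buildRegressionTable <- function(sessions, alignments = NULL,
                                 binning = NULL, popSize = 250L,
                                 nSimsPerBin = 1000L,
                                 windowMs = c(58, 78), seed = NULL) {
  if (is(sessions, "SessionRecording")) sessions <- list(sessions)
  if (is(alignments, "LaminarAlignment")) alignments <- list(alignments)
  if (!is.null(seed)) set.seed(seed)
  allTrials <- do.call(rbind, lapply(sessions, trialTable))
  if (is.null(binning)) binning <- rankAndBinRTs(allTrials, "fine")

  resp <- numeric(0); rtv <- numeric(0); binv <- integer(0)
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    ch <- if (!is.null(alignments))
      which(compartments(alignments[[i]]) != "outside")
    else seq_len(dim(mua(s))[1L])
    timeMs <- timeAxis(s)
    widx <- which(timeMs >= windowMs[1L] & timeMs <= windowMs[2L])
    if (!length(widx)) stop("feedforward window outside the recording")
    tt <- trialTable(s)
    oddTr <- which(tt$correct & tt$rf_item == "target")
    if (!length(oddTr)) next
    winMean <- apply(mua(s)[ch, widx, oddTr, drop = FALSE],
                     c(1L, 3L), mean)              # channel x trial
    key <- paste(tt$session_id[oddTr], tt$trial_id[oddTr])
    bkey <- paste(binning$session_id, binning$trial_id)
    b <- binning$bin[match(key, bkey)]
    keep <- !is.na(b) & !binning$excluded[match(key, bkey)]
    if (!any(keep)) next
    nC <- length(ch)
    resp <- c(resp, as.vector(winMean[, keep, drop = FALSE]))
    rtv <- c(rtv, rep(tt$rt_ms[oddTr][keep], each = nC))
    binv <- c(binv, rep(b[keep], each = nC))
  }

  usedBins <- sort(unique(binv))
  out <- vector("list", length(usedBins))
  for (k in seq_along(usedBins)) {
    b <- usedBins[k]
    sel <- binv == b
    if (!any(sel)) stop(sprintf("empty RT bin %d", b))
    rb <- resp[sel]; tb <- rtv[sel]
    idx <- matrix(sample.int(length(rb), popSize * nSimsPerBin,
                             replace = TRUE), popSize, nSimsPerBin)
    out[[k]] <- data.frame(
      bin = b, sim = seq_len(nSimsPerBin),
      spk = colSums(matrix(rb[idx], popSize, nSimsPerBin)),
      rt = colMeans(matrix(tb[idx], popSize, nSimsPerBin)))
  }
  do.call(rbind, out)
}

## ---- posterior sampling ------------------------------------------------

# The sampler works in a centered parametrization that removes most of
# the posterior correlation between alpha, beta and r:
#   psi = (A, log B, log r, log sigma), with
#   mu_i = A + B * (spk_i^r - mean(spk^r)) / sd(spk^r)
# so A is essentially the mean response and B the standardized slope.
# The map back to the model's parameters is beta = B / s_r and
# alpha = A - B m_r / s_r (m_r, s_r the regressor mean/SD), with
# log-Jacobian log B - log s_r + log r + log sigma. Priors are those of
# the model: alpha ~ LogNormal(0, 0.5), beta ~ LogNormal(1, 0.5),
# r ~ Gamma(1, 3), sigma_e ~ Gamma(0.5, 5) (shape-rate).

# builds a memoizing evaluator. The regressor z = (spk^r - mean) / sd
# only changes when r moves, so its sufficient statistics are cached;
# with z standardized, the Gaussian log-likelihood reduces to
#   -n log sigma - [S_rr - 2(A S_r + B S_rz) + n A^2 + (n-1) B^2] /
#   (2 sigma^2) + const,
# making updates of A, B and sigma O(1) in the sample size.
makePowerLogPost <- function(rt, logSpk, sign) {
  n <- length(rt)
  Sr <- sum(rt); Srr <- sum(rt * rt)
  const <- -n / 2 * log(2 * pi)
  lastR <- NA_real_; mR <- NA_real_; sR <- NA_real_; Srz <- NA_real_
  function(psi) {
    A <- psi[1L]; B <- exp(psi[2L]); r <- exp(psi[3L])
    sigma <- exp(psi[4L])
    if (!identical(r, lastR)) {
      u <- exp(sign * r * logSpk)
      mR <<- mean(u); sR <<- stats::sd(u)
      if (is.finite(sR) && sR > 0)
        Srz <<- sum(rt * (u - mR)) / sR
      lastR <<- r
    }
    if (!is.finite(sR) || sR <= 0) return(-Inf)
    beta <- B / sR
    alpha <- A - B * mR / sR
    if (alpha <= 0) return(-Inf)
    sse <- Srr - 2 * (A * Sr + B * Srz) + n * A^2 + (n - 1) * B^2
    ll <- const - n * log(sigma) - sse / (2 * sigma^2)
    lp <- stats::dlnorm(alpha, 0, 0.5, log = TRUE) +
      stats::dlnorm(beta, 1, 0.5, log = TRUE) +
      stats::dgamma(r, shape = 1, rate = 3, log = TRUE) +
      stats::dgamma(sigma, shape = 0.5, rate = 5, log = TRUE) +
      psi[2L] - log(sR) + psi[3L] + psi[4L]      # Jacobian
    ll + lp
  }
}

# natural-scale (alpha, beta, r, sigma_e) from a matrix of psi draws
psiToNatural <- function(m, logSpk, sign) {
  out <- matrix(NA_real_, nrow(m), 4L,
                dimnames = list(NULL, c("alpha", "beta", "r", "sigma_e")))
  for (i in seq_len(nrow(m))) {
    r <- exp(m[i, 3L])
    u <- exp(sign * r * logSpk)
    sR <- stats::sd(u)
    B <- exp(m[i, 2L])
    out[i, ] <- c(m[i, 1L] - B * mean(u) / sR, B / sR, sign * r,
                  exp(m[i, 4L]))
  }
  out
}

# posterior mode and Laplace factor in psi space, used to seed and
# precondition the slice chains
powerLaplace <- function(lpfun, rt) {
  d <- 4L
  nll <- function(p) { v <- lpfun(p); if (is.finite(v)) -v else 1e10 }
  starts <- list(c(mean(rt), log(max(stats::sd(rt), 1e-3)), log(1 / 3),
                   log(max(stats::sd(rt) / 4, 1e-4))),
                 c(mean(rt), 0, -1, -1),
                 c(mean(rt), -1, 0, 0))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(stats::optim(s, nll, method = "BFGS",
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  fallback <- diag(c(max(stats::sd(rt) / 10, 1e-3), 0.2, 0.2, 0.2))
  if (is.null(best)) return(list(mode = starts[[1L]], chol = fallback))
  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  cholS <- tryCatch({
    S <- solve(H)
    S <- (S + t(S)) / 2
    t(chol(S + diag(d) * 1e-12))
  }, error = function(e) fallback)
  list(mode = best$par, chol = cholS)
}

# One chain of coordinate-wise slice sampling (Neal 2003, stepping-out
# + shrinkage) in the Laplace-whitened space psi = mode + L v, where L
# is the Cholesky factor of the inverse Hessian at the mode. Whitening
# makes unit step widths appropriate in every coordinate; slice
# sampling then needs no further tuning.
sliceChain <- function(lpfun, warmup, keepIter, thin,
                       mode, L, v0, w = 1.5, maxStep = 30L) {
  d <- 4L
  lpv <- function(v) lpfun(mode + as.vector(L %*% v))
  v <- v0
  lp <- lpv(v)
  if (!is.finite(lp)) { v <- rep(0, d); lp <- lpv(v) }
  nKeep <- floor(keepIter / thin)
  draws <- matrix(NA_real_, nKeep, d)
  kept <- 0L
  total <- warmup + keepIter
  for (it in seq_len(total)) {
    for (j in seq_len(d)) {
      y <- lp - stats::rexp(1)
      lo <- v[j] - w * stats::runif(1)
      hi <- lo + w
      steps <- maxStep
      vj <- v
      while (steps > 0L) { vj[j] <- lo
        if (lpv(vj) <= y) break
        lo <- lo - w; steps <- steps - 1L }
      steps <- maxStep
      while (steps > 0L) { vj[j] <- hi
        if (lpv(vj) <= y) break
        hi <- hi + w; steps <- steps - 1L }
      repeat {
        prop <- lo + stats::runif(1) * (hi - lo)
        vj[j] <- prop
        lpP <- lpv(vj)
        if (is.finite(lpP) && lpP > y) { v[j] <- prop; lp <- lpP; break }
        if (prop < v[j]) lo <- prop else hi <- prop
        if (hi - lo < 1e-12) { vj[j] <- v[j]; break }
      }
    }
    if (it > warmup) {
      k <- it - warmup
      if (k %% thin == 0L && kept < nKeep) {
        kept <- kept + 1L
        draws[kept, ] <- mode + as.vector(L %*% v)
      }
    }
  }
  draws[seq_len(kept), , drop = FALSE]
}

#' Fit the Bayesian power-function model of reaction time
#'
#' Samples the posterior of RT_i ~ N(alpha + beta * SPK_i^r, sigma_e)
#' under minimally informative priors alpha ~ LogNormal(0, 0.5),
#' beta ~ LogNormal(1, 0.5), r ~ Gamma(1, 3), sigma_e ~ Gamma(0.5, 5)
#' (Gamma in shape-rate convention) using coordinate-wise slice
#' sampling in a Laplace-preconditioned, centered parametrization (see
#' the package vignette). Because the stated priors put
#' positive support on the exponent, a signed variant is available:
#' `exponentSign = -1` fits r' = -r so decreasing relationships can be
#' recovered; reported draws are on the signed scale.
#'
#' @param table data.frame with columns `spk` (> 0) and `rt` (> 0), as
#'   from [buildRegressionTable()].
#' @param mcmcConfig list with chains, warmup, totalSamples (per chain,
#'   warmup included), thin.
#' @param exponentSign +1 (stated prior) or -1 (signed variant).
#' @param standardize divide SPK by its median and convert RT from ms
#'   to seconds before fitting, so the LogNormal(0, 0.5) prior on alpha
#'   is sensible; reported coefficients are then on the standardized
#'   scale (recorded in the `scaling` slot).
#' @param seed optional RNG seed.
#' @return a [PowerFitResult-class].
#' @export
fitPowerModel <- function(table,
                          mcmcConfig = list(chains = 4L, warmup = 2000L,
                                            totalSamples = 5000L,
                                            thin = 2L),
                          exponentSign = c(1, -1), standardize = FALSE,
                          seed = NULL) {
  exponentSign <- match.arg(as.character(exponentSign[1L]),
                            c("1", "-1"))
  sign <- as.numeric(exponentSign)
  if (!is.null(seed)) set.seed(seed)
  spk <- table$spk; rt <- table$rt
  scaling <- list(spkDivisor = 1, rtDivisor = 1)
  if (standardize) {
    scaling <- list(spkDivisor = stats::median(spk), rtDivisor = 1000)
    spk <- spk / scaling$spkDivisor
    rt <- rt / scaling$rtDivisor
  }
  if (any(spk <= 0)) stop("SPK must be positive to take a power")
  if (any(rt <= 0)) stop("RT must be positive")
  logSpk <- log(spk)

  chains <- mcmcConfig$chains
  warmup <- mcmcConfig$warmup
  keepIter <- mcmcConfig$totalSamples - warmup
  thin <- mcmcConfig$thin
  stopifnot(chains >= 1L, keepIter > 0L, thin >= 1L)

  lpfun <- makePowerLogPost(rt, logSpk, sign)
  lap <- powerLaplace(lpfun, rt)
  chainList <- vector("list", chains)
  for (c in seq_len(chains)) {
    v0 <- stats::rnorm(4L, sd = 1)   # overdispersed whitened start
    chainList[[c]] <- sliceChain(lpfun, warmup, keepIter, thin,
                                 lap$mode, lap$chol, v0)
  }

  natural <- lapply(chainList, psiToNatural, logSpk = logSpk,
                    sign = sign)
  draws <- do.call(rbind, natural)

  mcl <- coda::mcmc.list(lapply(natural, coda::mcmc))
  rhat <- tryCatch({
    if (chains >= 2L)
      coda::gelman.diag(mcl, autoburnin = FALSE,
                        multivariate = FALSE)$psrf[, 1L]
    else stats::setNames(rep(NA_real_, 4L), colnames(draws))
  }, error = function(e) stats::setNames(rep(Inf, 4L), colnames(draws)))
  neff <- tryCatch(coda::effectiveSize(mcl),
                   error = function(e) rep(NA_real_, 4L))
  # with several chains a non-computable R-hat (constant or divergent
  # chains, e.g. a constant predictor leaving r unidentified) is itself
  # a failure, so only finite values at or below 1.01 count as reliable
  reliable <- if (chains >= 2L)
    all(is.finite(rhat)) && all(rhat <= 1.01) else NA

  med <- apply(draws, 2L, stats::median)
  ci <- apply(draws, 2L, stats::quantile, probs = c(0.055, 0.945))
  rownames(ci) <- c("5.5%", "94.5%")
  r2 <- bayesR2FromDraws(draws, rt, logSpk)

  new("PowerFitResult", draws = draws, medians = med, ci89 = ci,
      r2 = r2,
      mcmcConfig = mcmcConfig,
      diagnostics = list(rhat = rhat, neff = neff,
                         reliable = reliable),
      exponentSign = sign, scaling = scaling)
}

# Bayesian R2: var(fit) / (var(fit) + sigma_e^2) per draw, median over
# draws (Gelman-style, using the model's residual variance)
bayesR2FromDraws <- function(draws, rt, logSpk, maxDraws = 400L) {
  idx <- if (nrow(draws) > maxDraws)
    round(seq(1L, nrow(draws), length.out = maxDraws)) else
      seq_len(nrow(draws))
  vals <- vapply(idx, function(i) {
    mu <- draws[i, "alpha"] + draws[i, "beta"] *
      exp(draws[i, "r"] * logSpk)
    vf <- stats::var(mu)
    vf / (vf + draws[i, "sigma_e"]^2)
  }, numeric(1))
  stats::median(vals)
}

#' Fit sensitivity across response-window settings
#'
#' Refits the power model using population responses averaged over
#' windows of different widths and different onsets, reporting fit
#' quality and the exponent per setting.
#'
#' @param sessions,alignments,binning as for [buildRegressionTable()].
#' @param binWidthsMs window widths to scan (each starting at
#'   `baseOnsetMs`).
#' @param offsetsMs window onsets to scan (each of width 20 ms).
#' @param baseOnsetMs onset used for the width scan (default 58).
#' @param popSize,nSimsPerBin table-construction settings (kept small
#'   by default; this is a scan, not the headline fit).
#' @param mcmcConfig,exponentSign,standardize,seed forwarded to
#'   [fitPowerModel()].
#' @return data.frame with columns setting, widthMs, onsetMs, r2,
#'   rMedian; out-of-range windows are skipped with a message.
#' @export
binScan <- function(sessions, alignments = NULL, binning = NULL,
                    binWidthsMs = c(5, 10, 20, 40),
                    offsetsMs = c(-50, 0, 58, 100), baseOnsetMs = 58,
                    popSize = 100L, nSimsPerBin = 100L,
                    mcmcConfig = list(chains = 2L, warmup = 400L,
                                      totalSamples = 1400L, thin = 2L),
                    exponentSign = -1, standardize = TRUE,
                    seed = NULL) {
  if (is(sessions, "SessionRecording")) sessions <- list(sessions)
  if (!is.null(seed)) set.seed(seed)
  timeMs <- timeAxis(sessions[[1L]])
  settings <- rbind(
    data.frame(widthMs = binWidthsMs, onsetMs = baseOnsetMs),
    data.frame(widthMs = 20, onsetMs = offsetsMs))
  settings <- unique(settings)
  rows <- list()
  for (i in seq_len(nrow(settings))) {
    w <- c(settings$onsetMs[i], settings$onsetMs[i] + settings$widthMs[i])
    if (w[1L] < min(timeMs) || w[2L] > max(timeMs)) {
      message(sprintf("window [%g, %g] ms outside recording; skipped",
                      w[1L], w[2L]))
      next
    }
    tab <- buildRegressionTable(sessions, alignments, binning,
                                popSize = popSize,
                                nSimsPerBin = nSimsPerBin, windowMs = w)
    fit <- tryCatch(
      fitPowerModel(tab, mcmcConfig, exponentSign, standardize),
      error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      widthMs = settings$widthMs[i], onsetMs = settings$onsetMs[i],
      r2 = if (is.null(fit)) NA_real_ else bayesR2(fit),
      rMedian = if (is.null(fit)) NA_real_ else
        posteriorMedians(fit)[["r"]])
  }
  do.call(rbind, rows)
}

#' Regression table from granular sink magnitudes
#'
#' Counterpart of [buildRegressionTable()] for the synaptic-current
#' pathway: per RT bin, each simulated trial draws `popSize` trials,
#' sums their granular sink magnitudes (SPK analogue) and averages
#' their reaction times.
#'
#' @param magnitudes per-trial sink magnitudes
#'   (see [granularSinkMagnitude()]); larger = stronger sink.
#' @param rtMs matching reaction times (ms).
#' @param bins matching fine-bin labels (excluded trials NA).
#' @param popSize,nSimsPerBin,seed as for [buildRegressionTable()].
#' @return data.frame with columns bin, sim, spk, rt.
#' @export
buildCsdRegressionTable <- function(magnitudes, rtMs, bins,
                                    popSize = 250L, nSimsPerBin = 1000L,
                                    seed = NULL) {
  stopifnot(length(magnitudes) == length(rtMs),
            length(bins) == length(rtMs))
  if (!is.null(seed)) set.seed(seed)
  usedBins <- sort(unique(bins[!is.na(bins)]))
  out <- vector("list", length(usedBins))
  for (k in seq_along(usedBins)) {
    sel <- which(bins == usedBins[k])
    if (!length(sel)) stop(sprintf("empty RT bin %d", usedBins[k]))
    idx <- matrix(sample(sel, popSize * nSimsPerBin, replace = TRUE),
                  popSize, nSimsPerBin)
    out[[k]] <- data.frame(
      bin = usedBins[k], sim = seq_len(nSimsPerBin),
      spk = colSums(matrix(magnitudes[idx], popSize, nSimsPerBin)),
      rt = colMeans(matrix(rtMs[idx], popSize, nSimsPerBin)))
  }
  do.call(rbind, out)
}

#' Fit the power model with granular sink magnitude as the predictor
#'
#' Identical contract to [fitPowerModel()] with population spiking
#' replaced by the granular input sink magnitude.
#'
#' @param table data.frame with `spk` (summed sink magnitudes, > 0) and
#'   `rt`, as from [buildCsdRegressionTable()].
#' @param ... forwarded to [fitPowerModel()].
#' @return a [PowerFitResult-class].
#' @export
fitCsdModel <- function(table, ...) fitPowerModel(table, ...)
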