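# FRET calibration, blinking detection and transition-window selection.

#' Construct a FRET calibration
#'
#' @param bgD,bgA background photon rates (photons/s).
#' @param betaDA donor-to-acceptor crosstalk fraction.
#' @param gamma detection/quantum-yield correction factor.
#' @param EBMean mean bound-state transfer efficiency.
#' @return a [FretCalibration-class] (the unbound-state efficiency is 0 by
#'   construction).
#' @export
fretCalibration <- function(bgD = 0, bgA = 0, betaDA = 0, gamma = 1,
                            EBMean = NA_real_) {
  new("FretCalibration", bgD = bgD, bgA = bgA, betaDA = betaDA,
      gamma = gamma, EU = 0, EBMean = EBMean)
}

#' Background-correct measured photon count rates
#'
#' `n' = n - bg` per channel; negative corrected rates are clamped to zero
#' and flagged.
#'
#' @param rates numeric length-2 `(nD, nA)` measured rates (photons/s).
#' @param bg numeric length-2 `(bgD, bgA)` background rates.
#' @return numeric length-2 corrected rates with attribute `clamped`
#'   (logical length-2).
#' @export
backgroundCorrect <- function(rates, bg) {
  stopifnot(length(rates) == 2, length(bg) == 2, all(bg >= 0))
  corrected <- rates - bg
  clamped <- corrected < 0
  if (any(clamped))
    warning("background exceeds measured rate; corrected rate clamped to 0")
  corrected <- pmax(corrected, 0)
  attr(corrected, "clamped") <- clamped
  corrected
}

#' Estimate the donor-to-acceptor crosstalk fraction
#'
#' In the unbound state the true transfer efficiency is zero, so any
#' background-corrected acceptor signal is donor emission leaking into the
#' acceptor channel: `betaDA = nA'^U / nD'^U`.
#'
#' @param unboundRates numeric length-2 `(nD'U, nA'U)` background-corrected
#'   unbound-state rates.
#' @return scalar crosstalk fraction.
#' @export
estimateCrosstalkBeta <- function(unboundRates) {
  if (unboundRates[1] <= 0) stop("unbound donor rate must be positive")
  unname(unboundRates[2] / unboundRates[1])
}

#' Estimate the gamma correction factor
#'
#' After gamma correction the total corrected signal must be equal in the
#' bound and unbound states:
#' `gamma = (nA'^B - betaDA * nD'^B) / (nD'^U - nD'^B)`.
#'
#' @param unboundRates,boundRates numeric length-2 `(nD', nA')`
#'   background-corrected rates of the unbound and bound states.
#' @param betaDA crosstalk fraction (see [estimateCrosstalkBeta()]).
#' @return scalar gamma.
#' @export
estimateGamma <- function(unboundRates, boundRates, betaDA) {
  den <- unboundRates[1] - boundRates[1]
  if (den <= 0) stop("no FRET contrast: unbound donor rate must exceed bound donor rate")
  unname((boundRates[2] - betaDA * boundRates[1]) / den)
}

#' Corrected FRET transfer efficiency
#'
#' `E = (nA' - beta nD') / (nA' - beta nD' + gamma nD')`.
#'
#' @param rates numeric length-2 `(nD', nA')` background-corrected rates.
#' @param calib a [FretCalibration-class] (or list with `betaDA`, `gamma`).
#' @return scalar transfer efficiency.
#' @export
transferEfficiency <- function(rates, calib) {
  beta <- if (is(calib, "FretCalibration")) calib@betaDA else calib$betaDA
  gam <- if (is(calib, "FretCalibration")) calib@gamma else calib$gamma
  if (all(rates == 0)) stop("transfer efficiency undefined for all-zero rates")
  acc <- rates[2] - beta * rates[1]
  unname(acc / (acc + gam * rates[1]))
}

#' Calibrate a transition window
#'
#' Derives crosstalk, gamma and the mean bound-state efficiency from a
#' window's (background-corrected) pre- and post-transition rates.
#'
#' @param window a [TransitionWindow-class].
#' @param bg numeric length-2 background rates (photons/s).
#' @return a [FretCalibration-class].
#' @export
calibrateWindow <- function(window, bg = c(0, 0)) {
  pre <- backgroundCorrect(window@preRates, bg)
  post <- backgroundCorrect(window@postRates, bg)
  beta <- estimateCrosstalkBeta(pre)
  gam <- estimateGamma(pre, post, beta)
  cal <- fretCalibration(bgD = bg[1], bgA = bg[2], betaDA = beta, gamma = gam)
  cal@EBMean <- transferEfficiency(post, cal)
  validObject(cal)
  cal
}

#' Detect fluorophore blinking events in a photon stream segment
#'
#' For each detection channel within each state segment, inter-photon gaps
#' are tested against the exponential inter-photon time law implied by the
#' observed mean rate.  With the family-wise (default) correction the
#' flagged probability is `P = 1 - (1 - exp(-n dt))^N`, the probability that
#' any of the `N` gaps exceeds `dt`; with `familywise = FALSE` the raw tail
#' `exp(-n dt)` is used.
#'
#' @param times photon arrival times (s) of the segment.
#' @param channels per-photon channel (0/1 or labels).
#' @param state label attached to the reported events.
#' @param threshold flag gaps with probability below this (default 0.01).
#' @param familywise logical, apply the multiplicity correction.
#' @return data.frame with columns `gapStart`, `gapEnd`, `channel`,
#'   `state`, `probability` (zero rows when nothing is flagged).
#' @export
detectBlinking <- function(times, channels, state = "U", threshold = 0.01,
                           familywise = TRUE) {
  if (is.character(channels)) channels <- as.integer(channels == "acceptor")
  out <- list()
  for (ch in 0:1) {
    tc <- times[channels == ch]
    if (length(tc) < 2) {
      if (length(tc) == 1)
        warning(sprintf("fewer than 2 %s photons in segment; channel skipped",
                        c("donor", "acceptor")[ch + 1]))
      next
    }
    gaps <- diff(tc)
    N <- length(gaps)
    rate <- N / (tc[N + 1] - tc[1])
    tailP <- exp(-rate * gaps)
    p <- if (familywise) 1 - (1 - tailP)^N else tailP
    hit <- which(p < threshold)
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(
        gapStart = tc[hit], gapEnd = tc[hit + 1],
        channel = c("donor", "acceptor")[ch + 1], state = state,
        probability = p[hit])
  }
  if (!length(out))
    return(data.frame(gapStart = numeric(), gapEnd = numeric(),
                      channel = character(), state = character(),
                      probability = numeric()))
  do.call(rbind, out)
}

#' Maximum-likelihood changepoint of the channel composition
#'
#' Locates the most likely single switch between two Bernoulli regimes of
#' the photon channel sequence (the unbound and bound states share the same
#' total count rate here, so the transition shows up in the donor/acceptor
#' composition, not the total rate).
#'
#' @param times photon arrival times (s).
#' @param channels per-photon channel (0/1 or labels).
#' @return list with `time` (midpoint between the flanking photons),
#'   `index` (last photon of the first regime) and `logLikGain` relative to
#'   the single-regime model.
#' @export
channelChangepoint <- function(times, channels) {
  if (is.character(channels)) channels <- as.integer(channels == "acceptor")
  N <- length(channels)
  stopifnot(N >= 2)
  csum <- cumsum(channels)
  tot <- csum[N]
  k <- seq_len(N - 1)
  a1 <- csum[k]; n1 <- k
  a2 <- tot - a1; n2 <- N - k
  bll <- function(a, n) {
    p <- a / n
    ifelse(a > 0, a * log(p), 0) + ifelse(n - a > 0, (n - a) * log(1 - p), 0)
  }
  ll <- bll(a1, n1) + bll(a2, n2)
  i <- which.max(ll)
  list(time = (times[i] + times[i + 1]) / 2, index = i,
       logLikGain = ll[i] - bll(tot, N))
}

#' Select an analysis window around a binding transition
#'
#' Centers the largest possible window on the transition subject to the
#' selection rules: at least 1 ms long and 1000 photons, exactly one
#' transition, no blinking event inside the window, and no blinking event
#' within 1 ms of the transition (which rejects the trace).  Pre/post state
#' rates are estimated from the photons outside a guard band around the
#' transition.
#'
#' @param trace a [PhotonTrace-class] containing one unbound-to-bound
#'   transition.
#' @param transitionGuess approximate switch time (s); `NULL` to locate it
#'   automatically with [channelChangepoint()].
#' @param guardBand half-width (s) of the interval around the transition
#'   excluded from rate estimation (default 250 us).
#' @param blinkThreshold probability threshold for [detectBlinking()].
#' @param secondTransitionLogLik changepoint log-likelihood gain above which
#'   a flank is considered to contain another transition.
#' @return a [TransitionWindow-class], or a rejection object (class
#'   `tpfretWindowRejection`) whose `reason` is one of
#'   `"too_few_photons"`, `"blink_proximity"`, `"second_transition"`,
#'   `"too_short"`; see [rejectionReason()].
#' @export
selectWindow <- function(trace, transitionGuess = NULL, guardBand = 250e-6,
                         blinkThreshold = 0.01, secondTransitionLogLik = 15) {
  t <- trace@arrivalTimes
  ch <- trace@channels
  rejectWith <- function(reason)
    structure(list(reason = reason), class = "tpfretWindowRejection")
  if (length(t) < 2) return(rejectWith("too_few_photons"))
  cp <- channelChangepoint(t, ch)
  tc <- if (is.null(transitionGuess)) cp$time else {
    if (transitionGuess < 0 || transitionGuess > trace@duration)
      stop("transitionGuess outside trace")
    # refine the guess to the ML changepoint within +-0.5 ms
    near <- which(t > transitionGuess - 5e-4 & t < transitionGuess + 5e-4)
    if (length(near) >= 2)
      channelChangepoint(t[near], ch[near])$time + 0
    else transitionGuess
  }
  # blinking on each side (state-wise)
  pre <- t < tc - guardBand
  post <- t > tc + guardBand
  blinks <- rbind(detectBlinking(t[pre], ch[pre], "U", blinkThreshold),
                  detectBlinking(t[post], ch[post], "B", blinkThreshold))
  if (nrow(blinks)) {
    if (any(pmin(abs(blinks$gapStart - tc), abs(blinks$gapEnd - tc)) < 1e-3))
      return(rejectWith("blink_proximity"))
    # shrink the window to exclude all blinking events
    lo <- max(c(0, blinks$gapEnd[blinks$gapEnd < tc]))
    hi <- min(c(trace@duration, blinks$gapStart[blinks$gapStart > tc]))
  } else {
    lo <- 0
    hi <- trace@duration
  }
  half <- min(tc - lo, hi - tc)
  lo <- tc - half
  hi <- tc + half
  inWin <- t >= lo & t <= hi
  # check each flank for a second composition change
  preIdx <- which(t >= lo & t < tc - guardBand)
  postIdx <- which(t > tc + guardBand & t <= hi)
  for (idx in list(preIdx, postIdx)) {
    if (length(idx) >= 20) {
      cp2 <- channelChangepoint(t[idx], ch[idx])
      if (cp2$logLikGain > secondTransitionLogLik)
        return(rejectWith("second_transition"))
    }
  }
  if (hi - lo < 1e-3) return(rejectWith("too_short"))
  if (sum(inWin) < 1000) return(rejectWith("too_few_photons"))
  span <- function(idx) if (length(idx) > 1) t[idx[length(idx)]] - t[idx[1]] else NA
  rateOf <- function(idx) {
    s <- span(idx)
    if (!is.finite(s) || s <= 0) return(c(0, 0))
    c(sum(ch[idx] == 0L), sum(ch[idx] == 1L)) / s
  }
  w <- photonTrace(t[inWin] - lo, ch[inWin],
                   traceId = paste0(trace@traceId, ":win"),
                   duration = hi - lo,
                   metadata = c(trace@metadata, list(windowStart = lo)))
  new("TransitionWindow", photons = w, transitionGuess = tc - lo,
      preRates = rateOf(preIdx), postRates = rateOf(postIdx),
      windowLength = hi - lo)
}

#' Rejection reason of a window-selection result
#'
#' @param x result of [selectWindow()].
#' @return the rejection reason, or `NA_character_` if `x` is a valid
#'   window.
#' @export
rejectionReason <- function(x) {
  if (inherits(x, "tpfretWindowRejection")) x$reason else NA_character_
}

#' Assemble a transition window directly from known pieces
#'
#' Lower-level constructor used by the simulators and tests: wraps a photon
#' stream (already window-referenced) with its transition location and
#' per-side state rates without running the selection rules on a parent
#' trace.
#'
#' @param photons a [PhotonTrace-class] (times relative to window start).
#' @param transitionGuess switch time in the window frame (s).
#' @param preRates,postRates numeric `(nD, nA)` photon rates (photons/s).
#' @return a [TransitionWindow-class].
#' @export
transitionWindow <- function(photons, transitionGuess, preRates, postRates) {
  new("TransitionWindow", photons = photons,
      transitionGuess = transitionGuess,
      preRates = as.numeric(preRates), postRates = as.numeric(postRates),
      windowLength = photons@duration)
}
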