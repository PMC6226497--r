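# Histogramming of per-transition lifetime estimates and comparison with
# candidate barrier shapes: chi-square distance, k-sample Anderson-Darling
# test, diffusion-coefficient calibration, and the shape scan.

#' Default histogram bin edges for per-transition lifetime estimates
#'
#' 24 log-spaced bins from 0.5 ns to 3 ms, covering the resolved peak and
#' the sub-microsecond artifact peaks from unresolvable transitions.
#'
#' @param n number of bins.
#' @param from,to edge limits (s).
#' @return numeric vector of `n + 1` edges.
#' @export
defaultTauEdges <- function(n = 24, from = 0.5e-9, to = 3e-3)
  exp(seq(log(from), log(to), length.out = n + 1))

#' Histogram per-transition lifetime estimates
#'
#' Transitions lacking an interior likelihood maximum are collected in the
#' shortest bin regardless of their nominal value.
#'
#' @param values per-transition lifetime estimates (s).
#' @param hasMaximum logical flags (same length).
#' @param edges bin edges (see [defaultTauEdges()]).
#' @return a [TauHistogram-class].
#' @export
tauHistogram <- function(values, hasMaximum = rep(TRUE, length(values)),
                         edges = defaultTauEdges()) {
  stopifnot(length(values) == length(hasMaximum))
  if (length(values) &&
      (any(values[hasMaximum] < edges[1]) ||
       any(values[hasMaximum] > edges[length(edges)])))
    stop("lifetime estimate outside histogram edges")
  counts <- if (length(values)) {
    v <- values[hasMaximum]
    h <- hist(v, breaks = edges, plot = FALSE)$counts
    h[1] <- h[1] + sum(!hasMaximum)
    h
  } else rep(0, length(edges) - 1)
  new("TauHistogram", edges = edges, counts = as.numeric(counts),
      nNoMaximum = sum(!hasMaximum), values = as.numeric(values),
      hasMaximum = as.logical(hasMaximum))
}

#' Chi-square distance between two histograms
#'
#' `sum_i (Hm_i - Hs_i)^2 / (Hm_i + Hs_i)`, skipping bins where both
#' histograms are empty.
#'
#' @param Hm,Hs numeric count vectors (or [TauHistogram-class]) on the same
#'   binning.
#' @return scalar distance (>= 0).
#' @export
chi2Distance <- function(Hm, Hs) {
  if (is(Hm, "TauHistogram")) Hm <- Hm@counts
  if (is(Hs, "TauHistogram")) Hs <- Hs@counts
  if (length(Hm) != length(Hs)) stop("histograms must share one binning")
  s <- Hm + Hs
  keep <- s > 0
  sum((Hm[keep] - Hs[keep])^2 / s[keep])
}

#' k-sample Anderson-Darling test
#'
#' Rank-based k-sample test of the hypothesis that all samples come from
#' one (unspecified) continuous distribution, in the midrank version that
#' tolerates ties.  The statistic is standardized as
#' `tm = (A2 - (k-1)) / sigma` and the p-value is interpolated from the
#' published critical-value approximation (clipped to the range
#' 0.001-0.25).
#'
#' @param samples list of numeric vectors (each of length >= 2).
#' @return list with `statistic` (A2akN), `tm` (standardized), `p`.
#' @export
adKSample <- function(samples) {
  k <- length(samples)
  stopifnot(k >= 2)
  n <- vapply(samples, length, 0L)
  if (any(n < 2)) stop("each sample must contain at least 2 observations")
  Z <- sort(unlist(samples, use.names = FALSE))
  N <- length(Z)
  Zstar <- unique(Z)
  if (length(Zstar) < 2) stop("all observations are identical")
  left <- findInterval(Zstar, Z, left.open = TRUE)       # count of Z < Zstar_j
  right <- findInterval(Zstar, Z)                        # count of Z <= Zstar_j
  lj <- right - left
  Bj <- left + lj / 2
  A2 <- 0
  for (i in seq_len(k)) {
    s <- sort(samples[[i]])
    sl <- findInterval(Zstar, s, left.open = TRUE)
    sr <- findInterval(Zstar, s)
    Mij <- sr - (sr - sl) / 2
    inner <- lj / N * (N * Mij - Bj * n[i])^2 / (Bj * (N - Bj) - N * lj / 4)
    A2 <- A2 + sum(inner) / n[i]
  }
  A2 <- A2 * (N - 1) / N
  # variance of the statistic under the null
  H <- sum(1 / n)
  hh <- sum(1 / seq_len(N - 1))
  ch <- c(0, cumsum(1 / seq_len(N - 1)))                 # ch[i+1] = sum_{j<=i} 1/j
  i <- seq_len(N - 2)
  g <- sum((ch[N] - ch[i + 1]) / (N - i))
  a <- (4 * g - 6) * (k - 1) + (10 - 6 * g) * H
  b <- (2 * g - 4) * k^2 + 8 * hh * k + (2 * g - 14 * hh - 4) * H - 8 * hh + 4 * g - 6
  cc <- (6 * hh + 2 * g - 2) * k^2 + (4 * hh - 4 * g + 6) * k + (2 * hh - 6) * H + 4 * hh
  d <- (2 * hh + 6) * k^2 - 4 * hh * k
  sigsq <- (a * N^3 + b * N^2 + cc * N + d) / ((N - 1) * (N - 2) * (N - 3))
  m <- k - 1
  tm <- (A2 - m) / sqrt(sigsq)
  # critical-value approximation and log-p interpolation
  b0 <- c(0.675, 1.281, 1.645, 1.960, 2.326, 2.573, 3.085)
  b1 <- c(-0.245, 0.250, 0.678, 1.149, 1.822, 2.364, 3.615)
  b2 <- c(-0.105, -0.305, -0.362, -0.391, -0.396, -0.345, -0.154)
  crit <- b0 + b1 / sqrt(m) + b2 / m
  sig <- c(0.25, 0.10, 0.05, 0.025, 0.01, 0.005, 0.001)
  # interpolate log(p) inside the tabulated range; clamp outside it
  p <- if (tm < min(crit)) 0.25
  else if (tm > max(crit)) 0.001
  else {
    fit <- stats::lm.fit(cbind(1, crit, crit^2), log(sig))
    min(max(exp(sum(fit$coefficients * c(1, tm, tm^2))), 0.001), 0.25)
  }
  list(statistic = A2, tm = tm, p = p)
}

#' Pooled lifetime estimate of a cohort at fixed efficiency
#'
#' Sums the per-window lifetime profiles `DeltalnL_j(tau)` at the fixed
#' efficiency and locates the (parabolically refined) maximum.
#'
#' @param windows list of [TransitionWindow-class].
#' @param eHat fixed intermediate transfer efficiency.
#' @param calibs list of [FretCalibration-class] (recycled if length 1);
#'   `NULL` to calibrate each window from its own rates.
#' @param tauGrid lifetime grid.
#' @param slowRates see [defaultSlowRates()].
#' @return list with `tauHat` (s), `profiles` (matrix tau x windows),
#'   `fits` (data.frame from [perTransitionMLE()] rows).
#' @export
cohortTauAnalysis <- function(windows, eHat, calibs = NULL,
                              tauGrid = defaultTauGrid(),
                              slowRates = defaultSlowRates()) {
  J <- length(windows)
  prof <- matrix(0, length(tauGrid), J)
  fits <- vector("list", J)
  for (j in seq_len(J)) {
    w <- windows[[j]]
    cal <- if (is.null(calibs)) calibrateWindow(w)
           else if (length(calibs) == 1) calibs[[1]] else calibs[[j]]
    s <- deltaLnLSurface(w, cal, tauGrid = tauGrid, eGrid = eHat,
                         slowRates = slowRates)
    prof[, j] <- s@deltaLnL[, 1]
    fits[[j]] <- data.frame(traceId = w@photons@traceId,
                            tauHatJ = if (s@hasMaximum) s@tauHat else tauGrid[1],
                            deltaLnLAtMax = max(s@deltaLnL),
                            hasMaximum = s@hasMaximum)
  }
  pooled <- rowSums(prof)
  i <- which.max(pooled)
  interior <- i > 1 && pooled[i] > 0
  tauHat <- if (interior) exp(.parabolicPeak(log(tauGrid), pooled, i))
            else tauGrid[i]
  list(tauHat = tauHat, profiles = prof, fits = do.call(rbind, fits),
       hasMaximum = interior)
}

#' Calibrate the diffusion coefficient of a candidate barrier shape
#'
#' Scans mean transition-path times from 90% to 130% of the measured value
#' in 5% steps (scaling the candidate's solved distribution; means scale as
#' 1/D).  For each grid point, `nRep` photon cohorts are simulated from the
#' scaled distribution and analyzed like measured data; the point whose
#' average recovered pooled lifetime is closest to the target is selected
#' (ties toward the smaller index).
#'
#' @param dist the candidate's solved [TPTDistribution-class].
#' @param targetMean measured mean transition-path time (s), from the
#'   pooled likelihood analysis.
#' @param config cohort [simulationConfig()] describing window lengths and
#'   rates (its `tptLaw` is replaced per grid point).
#' @param eHat fixed intermediate efficiency for the analysis.
#' @param nRep replicate simulations per grid point.
#' @param scaleGrid mean-scaling factors.
#' @param tauGrid analysis lifetime grid.
#' @param edges histogram edges.
#' @return list with `D` (calibrated diffusion coefficient), `scale`,
#'   `dist` (rescaled distribution), `meanRecovered` (per grid point),
#'   `replicates`: for the selected point, a list with per-replicate
#'   `tauHat`, `values`, `hasMaximum`, `counts` (histograms).
#' @export
calibrateDiffusion <- function(dist, targetMean, config, eHat, nRep = 27,
                               scaleGrid = seq(0.9, 1.3, by = 0.05),
                               tauGrid = defaultTauGrid(),
                               edges = defaultTauEdges()) {
  nG <- length(scaleGrid)
  recovered <- numeric(nG)
  repsAll <- vector("list", nG)
  for (g in seq_len(nG)) {
    dg <- rescaleTPT(dist, scaleGrid[g] * targetMean)
    reps <- vector("list", nRep)
    for (r in seq_len(nRep)) {
      ci <- config
      ci$tptLaw <- dg
      ci$EI <- eHat   # intermediate efficiency as measured
      coh <- simulateTransitionCohort(ci, idPrefix = sprintf("c%02d_%02d_", g, r))
      an <- cohortTauAnalysis(coh$windows, eHat, tauGrid = tauGrid)
      reps[[r]] <- list(tauHat = an$tauHat, values = an$fits$tauHatJ,
                        hasMaximum = an$fits$hasMaximum,
                        counts = tauHistogram(an$fits$tauHatJ,
                                              an$fits$hasMaximum,
                                              edges)@counts)
    }
    recovered[g] <- mean(vapply(reps, function(x) x$tauHat, 0))
    repsAll[[g]] <- reps
  }
  err <- abs(recovered - targetMean)
  if (min(err) > 0.5 * targetMean)
    stop("no calibration grid point within 50% of the target mean")
  gSel <- which.min(err)
  sel <- rescaleTPT(dist, scaleGrid[gSel] * targetMean)
  list(D = sel@diffusionD, scale = scaleGrid[gSel], dist = sel,
       meanRecovered = recovered, replicates = repsAll[[gSel]])
}

#' Scan candidate barrier shapes against a measured lifetime histogram
#'
#' For every candidate potential: solve its transition-path-time density,
#' calibrate the diffusion coefficient against the measured mean, simulate
#' replicate photon cohorts mirroring the measured cohort, analyze them
#' identically, and compare the resulting lifetime histograms to the
#' measured one by the chi-square distance (mean and SE over replicates)
#' and a two-sample Anderson-Darling test.  The candidate with the
#' smallest mean chi-square is reported as the best match.
#'
#' @param measured list with `hist` (a [TauHistogram-class]), `tTP`
#'   (pooled mean transition-path time, s), `eHat`.
#' @param candidates named list; each element a list with `potential` (a
#'   [BarrierPotential-class]) and optionally `D0` (starting diffusion
#'   coefficient for the solve, default 1).
#' @param config cohort [simulationConfig()] mirroring the measured cohort.
#' @param nRep replicates per calibration point (27 reproduces the
#'   published protocol; smaller values give a fast mode).
#' @param scaleGrid,tauGrid,settings solver/analysis settings.
#' @return a [ShapeScanResult-class].
#' @export
barrierShapeScan <- function(measured, candidates, config, nRep = 27,
                             scaleGrid = seq(0.9, 1.3, by = 0.05),
                             tauGrid = defaultTauGrid(),
                             settings = solverSettings()) {
  edges <- measured$hist@edges
  nM <- sum(measured$hist@counts)
  rows <- list()
  details <- list()
  for (nm in names(candidates)) {
    cand <- candidates[[nm]]
    dist <- try(tptDistribution(cand$potential, D = cand$D0 %||% 1,
                                settings = settings), silent = TRUE)
    if (inherits(dist, "try-error")) {
      warning(sprintf("candidate '%s' skipped: %s", nm,
                      attr(dist, "condition")$message))
      next
    }
    cal <- calibrateDiffusion(dist, measured$tTP, config, measured$eHat,
                              nRep = nRep, scaleGrid = scaleGrid,
                              tauGrid = tauGrid, edges = edges)
    chi2 <- vapply(cal$replicates, function(rep) {
      Hs <- rep$counts * nM / max(sum(rep$counts), 1)
      chi2Distance(measured$hist@counts, Hs)
    }, 0)
    simTau <- unlist(lapply(cal$replicates, function(rep) rep$values))
    ad <- adKSample(list(measured$hist@values, simTau))
    rows[[nm]] <- data.frame(candidate = nm, kind = cand$potential@kind,
                             deltaV = cand$potential@deltaV, D = cal$D,
                             chi2Mean = mean(chi2),
                             chi2SE = sd(chi2) / sqrt(length(chi2)),
                             adStat = ad$statistic, adP = ad$p)
    details[[nm]] <- list(chi2 = chi2, scale = cal$scale,
                          meanRecovered = cal$meanRecovered)
  }
  if (!length(rows)) stop("no candidate could be evaluated")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("ShapeScanResult", table = tab,
      bestCandidate = tab$candidate[which.min(tab$chi2Mean)],
      details = details)
}

#' Default candidate barrier-shape library
#'
#' Parabolic barriers of 1-4 kT, a flat barrier, and intermediates of
#' depth 1-5 kT.
#'
#' @param x1 boundary half-width for the symmetric analytic shapes.
#' @return named list of candidates for [barrierShapeScan()].
#' @export
defaultCandidates <- function(x1 = 1) {
  out <- list()
  for (dv in 1:4)
    out[[sprintf("parabolic_%dkT", dv)]] <-
      list(potential = makePotential("parabolic", deltaV = dv, x1 = x1))
  out[["flat"]] <- list(potential = makePotential("flat", x1 = x1))
  for (dv in 1:5)
    out[[sprintf("intermediate_%dkT", dv)]] <-
      list(potential = makePotential("quartic_intermediate", deltaV = -dv,
                                     x1 = x1))
  out
}
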