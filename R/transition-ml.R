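# Two-state versus three-state log-likelihood difference surfaces over the
# intermediate lifetime and transfer efficiency; pooled and per-transition
# maximum-likelihood estimates, bootstrap errors, deletion control.

#' Default intermediate-lifetime grid
#'
#' 61 log-spaced points from 1 ns to 3 ms, bracketing all resolvable
#' transition-path times at typical count rates.
#'
#' @param n number of points.
#' @param from,to grid limits (s).
#' @return numeric vector (s).
#' @export
defaultTauGrid <- function(n = 61, from = 1e-9, to = 3e-3)
  exp(seq(log(from), log(to), length.out = n))

#' Default intermediate-efficiency grid
#'
#' 0.05 to 0.95 in steps of 0.01.
#'
#' @param from,to,by grid spec.
#' @return numeric vector.
#' @export
defaultEGrid <- function(from = 0.05, to = 0.95, by = 0.01)
  seq(from, to, by = by)

#' Fixed slow rates of the nested transition models
#'
#' The association/dissociation rates of the two-state reference model and
#' the entry rates into the intermediate of the three-state model are fixed
#' at values slow compared to any analysis window, so that random photon-rate
#' fluctuations are not misread as transitions; only the intermediate
#' lifetime and efficiency are varied.
#'
#' @return list with `slow2` (0.1 s^-1) and `slow3` (0.2 s^-1).
#' @export
defaultSlowRates <- function() list(slow2 = 0.1, slow3 = 0.2)

# parabolic refinement of a grid maximum; x on the given scale
.parabolicPeak <- function(x, y, i) {
  if (i <= 1 || i >= length(x)) return(x[i])
  d1 <- y[i - 1]; d2 <- y[i]; d3 <- y[i + 1]
  den <- d1 - 2 * d2 + d3
  if (den >= 0) return(x[i])
  s <- 0.5 * (d1 - d3) / den
  s <- max(min(s, 1), -1)
  # local (possibly non-uniform) spacing
  x[i] + s * (if (s > 0) x[i + 1] - x[i] else x[i] - x[i - 1])
}

.surfaceFromDelta <- function(delta, tauGrid, eGrid, nPooled = 1L) {
  i <- which(delta == max(delta), arr.ind = TRUE)
  # ties broken toward smaller tau (conservative, shorter transition paths)
  i <- i[order(i[, 1], i[, 2]), , drop = FALSE][1, ]
  it <- i[1]; ie <- i[2]
  interior <- it > 1 && max(delta) > 0
  tauH <- if (interior)
    exp(.parabolicPeak(log(tauGrid), delta[, ie], it)) else tauGrid[it]
  eH <- if (interior && length(eGrid) > 1)
    .parabolicPeak(eGrid, delta[it, ], ie) else eGrid[ie]
  new("LikelihoodSurface", tauGrid = tauGrid, eGrid = eGrid,
      deltaLnL = delta, argmaxIdx = as.integer(c(it, ie)),
      tauHat = tauH, eHat = eH, hasMaximum = interior,
      nPooled = as.integer(nPooled))
}

#' Log-likelihood difference surface of one transition window
#'
#' For every grid point, the photon stream of the window is evaluated under
#' the three-state model (unbound / intermediate / bound, entry rates fixed
#' slow, intermediate exit rate `kI = 1/(2 tauI)`, intermediate photon rates
#' interpolated at `EI` between the window's own unbound and bound rates)
#' and under the two-state instantaneous-transition reference; the surface
#' is `DeltalnL(tauI, EI) = lnL3(tauI, EI) - lnL2`.  Boundary vectors select
#' traces that start unbound and end bound.
#'
#' @param window a [TransitionWindow-class].
#' @param calib a [FretCalibration-class]; its `EBMean` scales the
#'   intermediate-rate interpolation.
#' @param tauGrid,eGrid grids (see [defaultTauGrid()], [defaultEGrid()]).
#' @param slowRates list with `slow2`, `slow3` (see [defaultSlowRates()]).
#' @return a [LikelihoodSurface-class].
#' @export
deltaLnLSurface <- function(window, calib, tauGrid = defaultTauGrid(),
                            eGrid = defaultEGrid(),
                            slowRates = defaultSlowRates()) {
  # NB: no validObject() here -- deletion controls legitimately produce
  # windows below the selection thresholds
  stopifnot(is(window, "TransitionWindow"))
  EB <- if (is(calib, "FretCalibration")) calib@EBMean else calib$EBMean
  if (!is.finite(EB) || EB <= 0)
    stop("calibration must provide a positive mean bound-state efficiency")
  t <- window@photons@arrivalTimes
  tau <- c(0, diff(t))
  tail <- window@photons@duration - t[length(t)]
  rates <- c(window@preRates, window@postRates)
  res <- cpp_delta_surface(tau, window@photons@channels, tail, rates, EB,
                           tauGrid, eGrid, slowRates$slow2, slowRates$slow3)
  .surfaceFromDelta(res$delta, tauGrid, eGrid)
}

#' Pool log-likelihood difference surfaces across transitions
#'
#' Surfaces on a common grid are summed elementwise; the argmax of the
#' pooled surface yields the mean transition-path time and the intermediate
#' transfer efficiency.
#'
#' @param surfaces list of [LikelihoodSurface-class] objects on one grid.
#' @return a pooled [LikelihoodSurface-class].
#' @export
poolSurfaces <- function(surfaces) {
  stopifnot(length(surfaces) >= 1)
  g1 <- surfaces[[1]]
  for (s in surfaces)
    if (!isTRUE(all.equal(s@tauGrid, g1@tauGrid)) ||
        !isTRUE(all.equal(s@eGrid, g1@eGrid)))
      stop("surfaces must share a common grid")
  delta <- Reduce(`+`, lapply(surfaces, function(s) s@deltaLnL))
  .surfaceFromDelta(delta, g1@tauGrid, g1@eGrid,
                    nPooled = sum(vapply(surfaces, function(s) s@nPooled, 1L)))
}

#' Per-transition maximum-likelihood lifetime at fixed efficiency
#'
#' Maximizes the window's log-likelihood difference over the lifetime grid
#' at the pooled efficiency estimate.  Windows lacking an interior maximum
#' (argmax at the smallest grid point, or no positive difference anywhere)
#' are assigned the smallest grid value and flagged.
#'
#' @param window a [TransitionWindow-class].
#' @param eHat fixed intermediate transfer efficiency.
#' @param calib a [FretCalibration-class].
#' @param tauGrid lifetime grid (s).
#' @param slowRates see [defaultSlowRates()].
#' @return data.frame with one row: `traceId`, `tauHatJ` (s),
#'   `deltaLnLAtMax`, `hasMaximum`.
#' @export
perTransitionMLE <- function(window, eHat, calib,
                             tauGrid = defaultTauGrid(),
                             slowRates = defaultSlowRates()) {
  s <- deltaLnLSurface(window, calib, tauGrid = tauGrid, eGrid = eHat,
                       slowRates = slowRates)
  data.frame(traceId = window@photons@traceId,
             tauHatJ = if (s@hasMaximum) s@tauHat else tauGrid[1],
             deltaLnLAtMax = max(s@deltaLnL),
             hasMaximum = s@hasMaximum)
}

#' Bootstrap standard errors of the pooled estimates
#'
#' Resamples transitions with replacement, re-pools their surfaces and
#' re-locates the maximum.
#'
#' @param surfaces list of per-transition [LikelihoodSurface-class] objects
#'   on one grid.
#' @param nTrials number of bootstrap trials (>= 2).
#' @param seed integer RNG seed (deterministic output for a given seed).
#' @return list with `seTau` (s), `seE`, and the per-trial estimates in
#'   `trials` (data.frame `tauHat`, `eHat`).
#' @export
bootstrapSE <- function(surfaces, nTrials = 1000, seed = 1) {
  J <- length(surfaces)
  if (J < 2) stop("bootstrap standard errors require at least two transitions")
  stopifnot(nTrials >= 2)
  g <- surfaces[[1]]
  nt <- length(g@tauGrid); ne <- length(g@eGrid)
  S <- vapply(surfaces, function(s) as.numeric(s@deltaLnL), numeric(nt * ne))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  counts <- vapply(seq_len(nTrials), function(i)
    tabulate(sample.int(J, J, replace = TRUE), nbins = J), numeric(J))
  P <- S %*% counts  # (nt*ne) x nTrials pooled surfaces
  est <- apply(P, 2, function(v) {
    s <- .surfaceFromDelta(matrix(v, nt, ne), g@tauGrid, g@eGrid)
    c(s@tauHat, s@eHat)
  })
  trials <- data.frame(tauHat = est[1, ], eHat = est[2, ])
  list(seTau = sd(trials$tauHat), seE = sd(trials$eHat), trials = trials)
}

.Random.seed_save <- function()
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Deletion control around the transition
#'
#' Removes a centered segment of each requested length from the window
#' (photons inside the segment are dropped; later photon times shift
#' leftward by the deleted duration) and recomputes the likelihood surface.
#' A likelihood peak that survives deletions comparable to the transition
#' path time but vanishes for much longer deletions demonstrates that the
#' peak is caused by the transition, not by photon-rate fluctuations.
#'
#' @param window a [TransitionWindow-class].
#' @param deleteLengths numeric, segment lengths to delete (s); 0 is the
#'   identity.
#' @param calib,tauGrid,eGrid,slowRates as in [deltaLnLSurface()].
#' @return named list of [LikelihoodSurface-class], one per length.
#' @export
deletionControl <- function(window, deleteLengths, calib,
                            tauGrid = defaultTauGrid(),
                            eGrid = defaultEGrid(),
                            slowRates = defaultSlowRates()) {
  out <- vector("list", length(deleteLengths))
  names(out) <- signif(deleteLengths, 6)
  for (i in seq_along(deleteLengths)) {
    L <- deleteLengths[i]
    if (L < 0 || L >= window@windowLength)
      stop("deletion length must be in [0, windowLength)")
    out[[i]] <- deltaLnLSurface(deleteWindowSegment(window, L), calib,
                                tauGrid = tauGrid, eGrid = eGrid,
                                slowRates = slowRates)
  }
  out
}

#' Delete a centered segment from a transition window
#'
#' @param window a [TransitionWindow-class].
#' @param length segment length to delete (s), centered on the transition.
#' @return a new [TransitionWindow-class] (validity relaxed: the deleted
#'   window may fall below the selection thresholds).
#' @export
deleteWindowSegment <- function(window, length) {
  if (length == 0) return(window)
  tc <- window@transitionGuess
  lo <- tc - length / 2
  hi <- tc + length / 2
  t <- window@photons@arrivalTimes
  ch <- window@photons@channels
  keep <- t < lo | t > hi
  t2 <- ifelse(t[keep] > hi, t[keep] - length, t[keep])
  ch <- ch[keep]
  ok <- c(TRUE, diff(t2) > 0)    # guard against ties across the splice
  t2 <- t2[ok]; ch2 <- ch[ok]
  ph <- photonTrace(t2, ch2,
                    traceId = paste0(window@photons@traceId, ":del"),
                    duration = window@photons@duration - length,
                    metadata = window@photons@metadata)
  out <- window
  out@photons <- ph
  out@windowLength <- window@windowLength - length
  out@transitionGuess <- max(min(tc, out@windowLength), 0)
  out
}
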