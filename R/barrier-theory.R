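# One-dimensional free-energy surfaces, Smoluchowski transition-path-time
# densities via spectral expansion, and Kramers barrier arithmetic.
#
# Energies are in kT (beta = 1); the reaction coordinate is dimensionless
# and the diffusion coefficient D (coordinate^2/s) sets the timescale.

.bdBase <- function(r) 80 * ((1.1 * (r - 1))^4 - (1.1 * (r - 1))^2)
.bdBase1 <- function(r) 80 * (4 * 1.1^4 * (r - 1)^3 - 2 * 1.1^2 * (r - 1))
.bdBase2 <- function(r) 80 * (12 * 1.1^4 * (r - 1)^2 - 2 * 1.1^2)

#' Construct a barrier potential
#'
#' Analytic families:
#' \describe{
#'   \item{parabolic}{`V(x) = -deltaV x^2 / x1^2` (inverted harmonic
#'     barrier; simple transition state).}
#'   \item{flat}{`V(x) = 0`.}
#'   \item{quartic_intermediate}{`V(x) = -2 deltaV x^2/x1^2 +
#'     deltaV x^4/x1^4`; with negative `deltaV` this has a well of depth
#'     `|deltaV|` at the center (a metastable intermediate) flanked by
#'     barriers.}
#'   \item{bd_quartic / bd_flat_top / bd_intermediate}{the fixed
#'     double-well-derived shapes used for Brownian-dynamics validation on
#'     `[0.8, 1.2]`: a quartic barrier, the same with a Gaussian dimple
#'     flattening its top, and the same with a deeper Gaussian producing a
#'     central intermediate.}
#'   \item{custom}{user-supplied `V` (derivatives by finite differences if
#'     not given).}
#' }
#' For the symmetric analytic families `x1 = -x0` and the sign convention
#' is `deltaV = V(0) - V(x1)` (negative values are intermediate wells).
#'
#' @param kind character, one of the kinds above.
#' @param deltaV signed barrier height / well depth (kT); ignored for
#'   `flat` and the fixed `bd_*` shapes.
#' @param x0,x1 absorbing boundaries.
#' @param V,dV,d2V functions for `kind = "custom"`.
#' @return a [BarrierPotential-class].
#' @export
#' @examples
#' p <- makePotential("parabolic", deltaV = 3, x1 = 1)
#' evalPotential(p, 0.5)  # -0.75
makePotential <- function(kind = c("parabolic", "flat",
                                   "quartic_intermediate", "bd_quartic",
                                   "bd_flat_top", "bd_intermediate",
                                   "custom"),
                          deltaV = NA_real_, x0 = NULL, x1 = NULL,
                          V = NULL, dV = NULL, d2V = NULL) {
  kind <- match.arg(kind)
  if (startsWith(kind, "bd_")) {
    if (is.null(x0)) x0 <- 0.8
    if (is.null(x1)) x1 <- 1.2
  } else {
    if (is.null(x1)) x1 <- 1
    if (is.null(x0)) x0 <- -x1
  }
  f <- switch(kind,
    parabolic = {
      a <- -deltaV / x1^2
      list(V = function(r) a * r^2, dV = function(r) 2 * a * r,
           d2V = function(r) rep(2 * a, length(r)))
    },
    flat = list(V = function(r) rep(0, length(r)),
                dV = function(r) rep(0, length(r)),
                d2V = function(r) rep(0, length(r))),
    quartic_intermediate = {
      a <- -2 * deltaV / x1^2; b <- deltaV / x1^4
      list(V = function(r) a * r^2 + b * r^4,
           dV = function(r) 2 * a * r + 4 * b * r^3,
           d2V = function(r) 2 * a + 12 * b * r^2)
    },
    bd_quartic = list(V = .bdBase, dV = .bdBase1, d2V = .bdBase2),
    bd_flat_top = {
      g <- function(r) -6 * exp(-2 * (20 / 7)^2 * (r - 1)^2)
      c2 <- 2 * (20 / 7)^2
      list(V = function(r) .bdBase(r) + g(r),
           dV = function(r) .bdBase1(r) + g(r) * (-2 * c2 * (r - 1)),
           d2V = function(r) .bdBase2(r) +
             g(r) * ((2 * c2 * (r - 1))^2 - 2 * c2))
    },
    bd_intermediate = {
      g <- function(r) -(44 / 5) * exp(-2 * 5^2 * (r - 1)^2)
      c2 <- 2 * 5^2
      list(V = function(r) .bdBase(r) + g(r),
           dV = function(r) .bdBase1(r) + g(r) * (-2 * c2 * (r - 1)),
           d2V = function(r) .bdBase2(r) +
             g(r) * ((2 * c2 * (r - 1))^2 - 2 * c2))
    },
    custom = {
      if (is.null(V)) stop("custom potential requires V")
      h <- (x1 - x0) * 1e-6
      if (is.null(dV)) dV <- function(r) (V(r + h) - V(r - h)) / (2 * h)
      if (is.null(d2V)) d2V <- function(r) (V(r + h) - 2 * V(r) + V(r - h)) / h^2
      list(V = V, dV = dV, d2V = d2V)
    })
  center <- (x0 + x1) / 2
  dv <- if (kind %in% c("parabolic", "quartic_intermediate")) deltaV
        else f$V(center) - f$V(x1)
  obj <- new("BarrierPotential", kind = kind, deltaV = dv, x0 = x0, x1 = x1,
             roughAmplitude = 0, roughPeriod = NA_real_,
             V = f$V, dV = f$dV, d2V = f$d2V)
  if (kind %in% c("parabolic", "quartic_intermediate") &&
      abs((f$V(center) - f$V(x1)) - deltaV) > 1e-12 * max(1, abs(deltaV)))
    stop("potential does not satisfy deltaV = V(0) - V(x1)")
  obj
}

#' Add sinusoidal roughness to a potential
#'
#' `V_rough(x) = V(x) + amplitude * sin(2 pi x / period)`.  Roughness slows
#' diffusive transport (longer mean transition-path times at fixed D) while
#' leaving the shape of the rescaled transition-path-time distribution
#' essentially unchanged.
#'
#' @param potential a [BarrierPotential-class].
#' @param amplitude roughness amplitude (kT, >= 0).
#' @param period roughness period (coordinate units, != 0).
#' @return a new [BarrierPotential-class]; the base potential is unchanged.
#' @export
addSinusoidalRoughness <- function(potential, amplitude, period) {
  stopifnot(is(potential, "BarrierPotential"), amplitude >= 0)
  if (period == 0) stop("roughness period must be non-zero")
  if (amplitude == 0) return(potential)
  V0 <- potential@V; dV0 <- potential@dV; d2V0 <- potential@d2V
  w <- 2 * pi / period
  out <- potential
  out@roughAmplitude <- amplitude
  out@roughPeriod <- period
  out@V <- function(r) V0(r) + amplitude * sin(w * r)
  out@dV <- function(r) dV0(r) + amplitude * w * cos(w * r)
  out@d2V <- function(r) d2V0(r) - amplitude * w^2 * sin(w * r)
  out
}

#' Solver settings for the spectral transition-path-time solver
#'
#' @param basisSize number of particle-in-a-box basis functions (>= 16).
#' @param epsilon launch offset from the left boundary as a fraction of
#'   `(x1 - x0)`; the solver evaluates at `epsilon` and `epsilon/2` and
#'   Richardson-extrapolates to 0.
#' @param nTime number of points of the reported time grid.
#' @param tMinFrac,tMaxFrac time-grid limits as fractions of the diffusive
#'   time `(x1 - x0)^2 / D`.
#' @param nQuad quadrature points for the potential matrix elements.
#' @param check logical: verify convergence by doubling the basis (error if
#'   the mean shifts by more than 0.5%).
#' @return list of settings.
#' @export
solverSettings <- function(basisSize = 256, epsilon = 1e-3, nTime = 400,
                           tMinFrac = 1e-4, tMaxFrac = 50, nQuad = 4096,
                           check = TRUE) {
  stopifnot(basisSize >= 16, epsilon > 0, epsilon < 0.1)
  list(basisSize = basisSize, epsilon = epsilon, nTime = nTime,
       tMinFrac = tMinFrac, tMaxFrac = tMaxFrac, nQuad = nQuad,
       check = check)
}

# Spectral solve: decay rates and raw flux amplitudes c_k for a source at
# x0 + eps, J(x1, t) prop sum_k c_k exp(-lam_k t).  The amplitude series is
# not absolutely convergent (delta-source truncation), so normalization and
# moments are taken by quadrature at t > 0 where the exponential damping
# makes the sum converge.
.spectralModes <- function(potential, D, eps, basisSize, nQuad) {
  x0 <- potential@x0; x1 <- potential@x1
  L <- x1 - x0
  M <- basisSize
  # Schroedinger transform: U_eff = D [ (V'/2)^2 - V''/2 ]  (beta = 1)
  xq <- seq(x0, x1, length.out = nQuad)
  Ueff <- D * ((potential@dV(xq) / 2)^2 - potential@d2V(xq) / 2)
  n <- seq_len(M)
  Phi <- sqrt(2 / L) * sin(outer(xq - x0, n * pi / L))  # nQuad x M
  wq <- rep(L / (nQuad - 1), nQuad)
  wq[c(1, nQuad)] <- wq[c(1, nQuad)] / 2  # trapezoid
  H <- crossprod(Phi * (Ueff * wq), Phi)
  H <- (H + t(H)) / 2
  diag(H) <- diag(H) + D * (n * pi / L)^2
  eg <- eigen(H, symmetric = TRUE)
  lam <- rev(eg$values)              # ascending decay rates
  A <- eg$vectors[, rev(seq_len(M)), drop = FALSE]
  # flux amplitude at x1 and source amplitude at x0 + eps
  dphi1 <- sqrt(2 / L) * (n * pi / L) * (-1)^n
  phiEps <- sqrt(2 / L) * sin(n * pi * eps / L)   # eps in coordinate units
  ck <- as.numeric(crossprod(A, dphi1)) * as.numeric(crossprod(A, phiEps))
  if (any(lam <= 0))
    stop("spectral solver produced non-positive decay rates (potential too steep for the basis)")
  list(rates = lam, amplitudes = ck)
}

#' Transition-path-time distribution on a 1D free-energy surface
#'
#' Solves the Smoluchowski equation with absorbing boundaries at `x0` and
#' `x1` by spectral expansion (mapping to a Schroedinger operator
#' diagonalized in a particle-in-a-box basis).  The density is the
#' transmitted flux at `x1` for a source started at `x0 + eps`, normalized
#' by the total transmitted flux, Richardson-extrapolated over two launch
#' offsets toward `eps -> 0`.
#'
#' @param potential a [BarrierPotential-class].
#' @param D diffusion coefficient (coordinate^2/s, > 0).
#' @param settings see [solverSettings()].
#' @return a [TPTDistribution-class].
#' @export
#' @examples
#' flat <- makePotential("flat", x0 = -1, x1 = 1)
#' d <- tptDistribution(flat, D = 1)
#' meanTPT(d)  # close to L^2/(6 D) = 2/3
tptDistribution <- function(potential, D, settings = solverSettings()) {
  stopifnot(is(potential, "BarrierPotential"), D > 0)
  L <- potential@x1 - potential@x0
  eps1 <- settings$epsilon * L
  T0 <- L^2 / D
  solve1 <- function(basis) {
    mA <- .spectralModes(potential, D, eps1, basis, settings$nQuad)
    mB <- .spectralModes(potential, D, eps1 / 2, basis, settings$nQuad)
    # Richardson toward eps -> 0: f(0) ~ 2 f(eps/2) - f(eps) after putting
    # both solves on the same (linear-in-eps) scale
    amp <- 2 * (2 * mB$amplitudes) - mA$amplitudes
    rates <- mA$rates
    # time grid covering both the diffusive scale and the slowest decay
    tMax <- max(settings$tMaxFrac * T0, 25 / min(rates))
    tg <- exp(seq(log(settings$tMinFrac * T0), log(tMax),
                  length.out = settings$nTime))
    modes <- list(rates = rates, amplitudes = amp)
    dens <- .mixtureDensity(modes, tg)
    # constant prefactors of the flux (including -D and the half-potential
    # boundary factors) were dropped from the amplitudes; normalizing by the
    # signed flux integral restores both scale and sign
    Z <- .trapz(tg, dens)
    if (Z == 0) stop("spectral solver produced a vanishing flux integral")
    modes$amplitudes <- amp / Z
    dens <- dens / Z
    mean <- .trapz(tg, tg * dens)
    list(modes = modes, tGrid = tg, density = dens, mean = mean)
  }
  sol <- solve1(settings$basisSize)
  if (isTRUE(settings$check)) {
    sol2 <- solve1(settings$basisSize * 2)
    if (abs(sol2$mean - sol$mean) > 5e-3 * abs(sol2$mean))
      stop(sprintf(
        "spectral solver not converged: mean changes by %.2f%% on doubling the basis (%d -> %d)",
        100 * abs(sol2$mean - sol$mean) / abs(sol2$mean),
        settings$basisSize, 2 * settings$basisSize))
  }
  dens <- pmax(sol$density, 0)   # truncation ripple at very small t
  normRes <- abs(1 - .trapz(sol$tGrid, dens))
  new("TPTDistribution", tGrid = sol$tGrid, density = dens,
      mean = sol$mean, diffusionD = D,
      rates = sol$modes$rates, weights = sol$modes$amplitudes,
      diagnostics = list(basisSize = settings$basisSize,
                         normResidual = normRes,
                         epsilon = c(eps1, eps1 / 2)))
}

# p(t) = sum_k a_k exp(-r_k t); vectorized over t in blocks to bound memory
.mixtureDensity <- function(modes, t) {
  out <- numeric(length(t))
  for (i in seq_along(t))
    out[i] <- sum(modes$amplitudes * exp(-modes$rates * t[i]))
  out
}

# survival S(t) = int_t^inf p = sum_k (a_k / r_k) exp(-r_k t); accurate for
# t away from 0 (exponential damping regularizes the truncated series)
.mixtureSurvival <- function(modes, t) {
  out <- numeric(length(t))
  for (i in seq_along(t))
    out[i] <- sum(modes$amplitudes / modes$rates * exp(-modes$rates * t[i]))
  out
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Mean transition-path time of a solved distribution
#'
#' First moment; analytic for the spectral exponential-mixture
#' representation, by quadrature for tabulated densities.
#'
#' @param dist a [TPTDistribution-class], or a list with `tGrid` and
#'   `density`.
#' @return mean time (s).
#' @export
meanTptQuadrature <- function(dist) {
  if (is(dist, "TPTDistribution"))
    return(.trapz(dist@tGrid, dist@tGrid * dist@density) /
             .trapz(dist@tGrid, dist@density))
  .trapz(dist$tGrid, dist$tGrid * dist$density) / .trapz(dist$tGrid, dist$density)
}

#' Rescale a solved distribution to a target mean
#'
#' Scaling the mean by `f` is equivalent to scaling the diffusion
#' coefficient by `1/f`; the shape is unchanged.
#'
#' @param dist a [TPTDistribution-class].
#' @param targetMean desired mean (s).
#' @return a rescaled [TPTDistribution-class].
#' @export
rescaleTPT <- function(dist, targetMean) {
  f <- targetMean / dist@mean
  out <- dist
  out@tGrid <- dist@tGrid * f
  out@density <- dist@density / f
  out@mean <- targetMean
  out@rates <- dist@rates / f
  out@weights <- dist@weights / f
  out@diffusionD <- dist@diffusionD / f
  out
}

#' Kramers estimate of a barrier height from an escape time
#'
#' With preexponential time `tau0` (estimated as `2 pi tau_r` from the
#' chain reconfiguration time `tau_r`), the barrier is
#' `ln(2 escapeTime / tau0)` kT when the intermediate can escape over two
#' symmetric barriers (the measured lifetime is half the single-barrier
#' escape time) and `ln(escapeTime / tau0)` for a single exit.
#'
#' @param escapeTime observed escape time (s).
#' @param tau0 preexponential time (s).
#' @param symmetricExit logical: two equal barriers share the escape flux.
#' @return barrier height (kT).
#' @export
#' @examples
#' kramersBarrierHeight(80e-6, 0.5e-6)          # ~5.8 kT
#' kramersBarrierHeight(80e-6, 0.5e-6, FALSE)   # ~5 kT
kramersBarrierHeight <- function(escapeTime, tau0, symmetricExit = TRUE) {
  if (escapeTime <= 0 || tau0 <= 0) stop("times must be positive")
  if (symmetricExit) log(2 * escapeTime / tau0) else log(escapeTime / tau0)
}

#' Preexponential time from the chain reconfiguration time
#'
#' @param tauR reconfiguration time (s).
#' @return `2 pi tauR` (s).
#' @export
kramersPrefactor <- function(tauR) 2 * pi * tauR

#' Activation barrier from a rate ratio
#'
#' `ln(kRef / k)` kT: e.g. the association barrier from the ratio of the
#' observed association rate to the diffusion-limited collision rate.
#'
#' @param k observed rate.
#' @param kRef reference (barrierless) rate, same units.
#' @return barrier height (kT).
#' @export
barrierFromRateRatio <- function(k, kRef) {
  if (k <= 0 || kRef <= 0) stop("rates must be positive")
  log(kRef / k)
}

#' Splitting probability of the intermediate toward the bound state
#'
#' `kIB / (kIU + kIB)`; with symmetric exits this is 1/2, which is why the
#' two-state rates are half the three-state entry rates.
#'
#' @param kIU,kIB exit rates from the intermediate to the unbound and bound
#'   states (>= 0, not both 0).
#' @return probability of exiting to the bound state.
#' @export
splittingProbability <- function(kIU, kIB) {
  stopifnot(kIU >= 0, kIB >= 0)
  if (kIU + kIB == 0) stop("at least one exit rate must be positive")
  kIB / (kIU + kIB)
}
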