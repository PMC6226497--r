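# Central S4 containers.  Internal time unit is seconds throughout; photon
# rates are photons/s; kinetic rates s^-1.  Reporting layers convert to
# microseconds / ms^-1 where that is the conventional scale.

setClassUnion("listOrNULL", c("list", "NULL"))

#' PhotonTrace: a timestamped, channel-tagged photon stream
#'
#' @slot arrivalTimes numeric, photon arrival times in seconds, strictly
#'   increasing.
#' @slot channels integer, per-photon channel: 0 = donor, 1 = acceptor.
#' @slot traceId character scalar, opaque identifier.
#' @slot duration numeric scalar, trace duration in seconds
#'   (\code{>=} last arrival time).
#' @slot metadata list of per-trace annotations (excitation regime, known
#'   per-state count rates for simulated traces, background rates,
#'   simulation truth).
#' @exportClass PhotonTrace
setClass("PhotonTrace",
  representation(arrivalTimes = "numeric", channels = "integer",
                 traceId = "character", duration = "numeric",
                 metadata = "list"))

setValidity("PhotonTrace", function(object) {
  t <- object@arrivalTimes
  msg <- character()
  if (length(object@channels) != length(t))
    msg <- c(msg, "channels must have the same length as arrivalTimes")
  if (length(t) && any(diff(t) <= 0))
    msg <- c(msg, "arrivalTimes must be strictly increasing")
  if (length(t) && t[1] < 0)
    msg <- c(msg, "arrivalTimes must be non-negative")
  if (length(object@duration) != 1 || is.na(object@duration) ||
      (length(t) && object@duration < t[length(t)]))
    msg <- c(msg, "duration must be a scalar >= the last arrival time")
  if (length(object@channels) && !all(object@channels %in% c(0L, 1L)))
    msg <- c(msg, "channels must be 0 (donor) or 1 (acceptor)")
  if (length(msg)) msg else TRUE
})

#' KineticModel: CTMC generator plus per-state photon emission rates
#'
#' The generator convention is \code{dp/dt = K p} (columns sum to zero).
#'
#' @slot stateNames character, ordered state labels.
#' @slot K square numeric rate matrix (s^-1), columns summing to zero.
#' @slot nD,nA numeric, per-state donor/acceptor photon rates (photons/s).
#' @slot pIni numeric, initial state distribution.
#' @slot pFin numeric, final selection/summation vector.
#' @exportClass KineticModel
setClass("KineticModel",
  representation(stateNames = "character", K = "matrix",
                 nD = "numeric", nA = "numeric",
                 pIni = "numeric", pFin = "numeric"))

setValidity("KineticModel", function(object) {
  K <- object@K
  n <- nrow(K)
  msg <- character()
  if (ncol(K) != n) msg <- c(msg, "K must be square")
  if (length(object@stateNames) != n)
    msg <- c(msg, "stateNames length must match dim(K)")
  off <- K; diag(off) <- 0
  if (any(off < 0)) msg <- c(msg, "off-diagonal entries of K must be >= 0")
  if (any(abs(colSums(K)) > 1e-12 * max(1, max(abs(K)))))
    msg <- c(msg, "columns of K must sum to zero (generator convention)")
  for (s in c("nD", "nA", "pIni", "pFin"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("%s length must match dim(K)", s))
  if (any(object@nD < 0) || any(object@nA < 0))
    msg <- c(msg, "photon rates must be >= 0")
  if (any(object@pIni < 0) || abs(sum(object@pIni) - 1) > 1e-9)
    msg <- c(msg, "pIni must be a probability vector")
  if (!(all(object@pFin %in% c(0, 1))))
    msg <- c(msg, "pFin entries must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' RateEstimates: fitted association/dissociation and blinking kinetics
#'
#' @slot kbarOn pseudo-first-order association rate (s^-1),
#'   \code{kOn * cSolution}.
#' @slot kOff dissociation rate (s^-1).
#' @slot kPlusB,kMinusB blinking entry/exit rates (s^-1).
#' @slot perTraceRates data.frame with one row per trace and columns
#'   \code{traceId, nDU, nAU, nDB, nAB} (photons/s).
#' @slot cSolution molar concentration of the labeled binding partner.
#' @slot logLik achieved total log-likelihood.
#' @slot boundaryFlags character, names of rates that hit the zero boundary.
#' @exportClass RateEstimates
setClass("RateEstimates",
  representation(kbarOn = "numeric", kOff = "numeric", kPlusB = "numeric",
                 kMinusB = "numeric", perTraceRates = "data.frame",
                 cSolution = "numeric", logLik = "numeric",
                 boundaryFlags = "character"))

setValidity("RateEstimates", function(object) {
  msg <- character()
  if (any(c(object@kbarOn, object@kOff, object@kPlusB, object@kMinusB) < 0))
    msg <- c(msg, "all rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' StatePath: a decoded piecewise-constant state trajectory
#'
#' @slot boundaries numeric, segment boundaries in seconds (tiling
#'   \code{[0, duration]}).
#' @slot states integer, state index of each segment.
#' @slot traceId character, source trace.
#' @exportClass StatePath
setClass("StatePath",
  representation(boundaries = "numeric", states = "integer",
                 traceId = "character"))

setValidity("StatePath", function(object) {
  msg <- character()
  if (length(object@boundaries) != length(object@states) + 1)
    msg <- c(msg, "boundaries must have length(states) + 1")
  if (any(diff(object@boundaries) < 0))
    msg <- c(msg, "boundaries must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' FretCalibration: background, crosstalk and gamma corrections
#'
#' @slot bgD,bgA background photon rates (photons/s).
#' @slot betaDA donor-to-acceptor crosstalk fraction.
#' @slot gamma detection-efficiency/quantum-yield correction factor.
#' @slot EU transfer efficiency of the unbound state (0 by construction).
#' @slot EBMean mean bound-state transfer efficiency.
#' @exportClass FretCalibration
setClass("FretCalibration",
  representation(bgD = "numeric", bgA = "numeric", betaDA = "numeric",
                 gamma = "numeric", EU = "numeric", EBMean = "numeric"))

setValidity("FretCalibration", function(object) {
  msg <- character()
  if (object@bgD < 0 || object@bgA < 0) msg <- c(msg, "backgrounds must be >= 0")
  if (object@betaDA < 0) msg <- c(msg, "betaDA must be >= 0")
  if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
  if (!is.na(object@EBMean) && (object@EBMean < 0 || object@EBMean > 1))
    msg <- c(msg, "EBMean must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' TransitionWindow: a photon-stream segment around one binding transition
#'
#' @slot photons [PhotonTrace] with times re-referenced to the window start.
#' @slot transitionGuess numeric, approximate switch time (s, window frame).
#' @slot preRates,postRates numeric length-2 \code{(nD, nA)} photon rates
#'   (photons/s) of the unbound and bound sides.
#' @slot windowLength numeric, window duration (s).
#' @exportClass TransitionWindow
setClass("TransitionWindow",
  representation(photons = "PhotonTrace", transitionGuess = "numeric",
                 preRates = "numeric", postRates = "numeric",
                 windowLength = "numeric"))

setValidity("TransitionWindow", function(object) {
  msg <- character()
  if (object@windowLength < 1e-3)
    msg <- c(msg, "window must be at least 1 ms long")
  if (length(object@photons@arrivalTimes) < 1000)
    msg <- c(msg, "window must contain at least 1000 photons")
  if (object@transitionGuess < 0 || object@transitionGuess > object@windowLength)
    msg <- c(msg, "transitionGuess must lie inside the window")
  if (length(object@preRates) != 2 || length(object@postRates) != 2 ||
      any(c(object@preRates, object@postRates) < 0))
    msg <- c(msg, "preRates/postRates must be non-negative (nD, nA) pairs")
  if (length(msg)) msg else TRUE
})

#' LikelihoodSurface: Delta lnL over an (intermediate lifetime, efficiency) grid
#'
#' @slot tauGrid numeric, intermediate lifetimes (s), log-spaced.
#' @slot eGrid numeric, intermediate transfer efficiencies.
#' @slot deltaLnL numeric matrix \code{[tau, E]}, three-state minus two-state
#'   log likelihood.
#' @slot argmaxIdx integer length-2, grid indices of the maximum.
#' @slot tauHat,eHat numeric, location of the maximum (parabolically refined
#'   when the maximum is interior; equal to the grid argmax otherwise).
#' @slot hasMaximum logical, TRUE when an interior maximum exists.
#' @slot nPooled integer, number of transitions pooled into this surface.
#' @exportClass LikelihoodSurface
setClass("LikelihoodSurface",
  representation(tauGrid = "numeric", eGrid = "numeric",
                 deltaLnL = "matrix", argmaxIdx = "integer",
                 tauHat = "numeric", eHat = "numeric",
                 hasMaximum = "logical", nPooled = "integer"))

setValidity("LikelihoodSurface", function(object) {
  msg <- character()
  if (!all(dim(object@deltaLnL) ==
           c(length(object@tauGrid), length(object@eGrid))))
    msg <- c(msg, "deltaLnL must be a [tauGrid x eGrid] matrix")
  if (length(object@tauGrid) > 1 && any(diff(object@tauGrid) <= 0))
    msg <- c(msg, "tauGrid must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' BarrierPotential: a 1D free-energy surface between absorbing boundaries
#'
#' Energies are in units of kT.  The sign convention for the barrier
#' height/intermediate depth is \code{deltaV = V(center) - V(x1)}: positive
#' for a barrier above the boundaries, negative for an intermediate well.
#'
#' @slot kind one of \code{"parabolic"}, \code{"flat"},
#'   \code{"quartic_intermediate"}, \code{"bd_quartic"},
#'   \code{"bd_flat_top"}, \code{"bd_intermediate"}, \code{"custom"}.
#' @slot deltaV numeric, signed height/depth (kT).
#' @slot x0,x1 numeric, absorbing boundaries of the reaction coordinate.
#' @slot roughAmplitude,roughPeriod numeric, sinusoidal roughness
#'   (amplitude in kT; 0 amplitude disables it).
#' @slot V,dV,d2V functions of x returning the potential and its first two
#'   derivatives (roughness included).
#' @exportClass BarrierPotential
setClass("BarrierPotential",
  representation(kind = "character", deltaV = "numeric",
                 x0 = "numeric", x1 = "numeric",
                 roughAmplitude = "numeric", roughPeriod = "numeric",
                 V = "function", dV = "function", d2V = "function"))

setValidity("BarrierPotential", function(object) {
  msg <- character()
  if (object@x1 <= object@x0) msg <- c(msg, "x1 must exceed x0")
  if (object@roughAmplitude < 0) msg <- c(msg, "roughness amplitude must be >= 0")
  if (length(msg)) msg else TRUE
})

#' TPTDistribution: a numerically solved transition-path-time density
#'
#' The density is a finite spectral sum \code{p(t) = sum_k a_k exp(-r_k t)}
#' (amplitudes may be negative for a truncated expansion; the exponential
#' damping regularizes the series for \code{t > 0}), normalized by
#' quadrature on the time grid.
#'
#' @slot tGrid numeric, time grid (s).
#' @slot density numeric, probability density on \code{tGrid} (1/s).
#' @slot mean numeric, mean transition-path time (s).
#' @slot diffusionD numeric, diffusion coefficient (coordinate^2/s).
#' @slot rates numeric, spectral decay rates r_k (1/s).
#' @slot weights numeric, spectral amplitudes a_k (1/s).
#' @slot diagnostics list: basis size, normalization residual,
#'   Richardson offsets.
#' @exportClass TPTDistribution
setClass("TPTDistribution",
  representation(tGrid = "numeric", density = "numeric", mean = "numeric",
                 diffusionD = "numeric", rates = "numeric",
                 weights = "numeric", diagnostics = "list"))

setValidity("TPTDistribution", function(object) {
  msg <- character()
  if (length(object@tGrid) != length(object@density))
    msg <- c(msg, "tGrid and density must have the same length")
  if (any(object@density < -1e-8 * max(abs(object@density))))
    msg <- c(msg, "density must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TauHistogram: histogram of per-transition lifetime estimates
#'
#' @slot edges numeric, log-spaced bin edges (s).
#' @slot counts numeric, per-bin counts.
#' @slot nNoMaximum integer, number of transitions lacking an interior
#'   likelihood maximum (forced into the shortest bin).
#' @slot values numeric, the underlying per-transition estimates (s).
#' @slot hasMaximum logical, per-transition interior-maximum flags.
#' @exportClass TauHistogram
setClass("TauHistogram",
  representation(edges = "numeric", counts = "numeric",
                 nNoMaximum = "integer", values = "numeric",
                 hasMaximum = "logical"))

setValidity("TauHistogram", function(object) {
  msg <- character()
  if (length(object@counts) != length(object@edges) - 1)
    msg <- c(msg, "counts must have length(edges) - 1")
  if (any(diff(object@edges) <= 0))
    msg <- c(msg, "edges must be strictly increasing")
  if (abs(sum(object@counts) - length(object@values)) > 1e-9)
    msg <- c(msg, "counts must sum to the number of transitions")
  if (length(msg)) msg else TRUE
})

#' ShapeScanResult: chi-square / Anderson-Darling scan over barrier shapes
#'
#' @slot table data.frame with one row per candidate: \code{candidate},
#'   \code{kind}, \code{deltaV}, \code{D} (calibrated diffusion
#'   coefficient), \code{chi2Mean}, \code{chi2SE}, \code{adStat},
#'   \code{adP}.
#' @slot bestCandidate character, id of the chi-square-minimizing candidate.
#' @slot details list of per-candidate replicate diagnostics.
#' @exportClass ShapeScanResult
setClass("ShapeScanResult",
  representation(table = "data.frame", bestCandidate = "character",
                 details = "list"))
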