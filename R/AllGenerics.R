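# Generics and simple accessors.

#' @export
setGeneric("arrivalTimes", function(x) standardGeneric("arrivalTimes"))
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @export
setGeneric("traceId", function(x) standardGeneric("traceId"))
#' @export
setGeneric("traceDuration", function(x) standardGeneric("traceDuration"))
#' @export
setGeneric("nPhotons", function(x) standardGeneric("nPhotons"))
#' @export
setGeneric("traceMetadata", function(x) standardGeneric("traceMetadata"))
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))
#' @export
setGeneric("tauHat", function(x) standardGeneric("tauHat"))
#' @export
setGeneric("eHat", function(x) standardGeneric("eHat"))
#' @export
setGeneric("hasMaximum", function(x) standardGeneric("hasMaximum"))
#' @export
setGeneric("deltaLnL", function(x) standardGeneric("deltaLnL"))
#' @export
setGeneric("meanTPT", function(x) standardGeneric("meanTPT"))
#' @export
setGeneric("evalPotential", function(x, r) standardGeneric("evalPotential"))

#' Accessors for photon traces and derived objects
#'
#' @param x a [PhotonTrace], [TransitionWindow], [LikelihoodSurface],
#'   [TPTDistribution] or [BarrierPotential].
#' @param r numeric, reaction-coordinate values (for `evalPotential`).
#' @return the requested component; times are seconds, energies kT.
#' @name accessors
#' @aliases arrivalTimes channels traceId traceDuration nPhotons
#'   traceMetadata rateMatrix tauHat eHat hasMaximum deltaLnL meanTPT
#'   evalPotential
NULL

#' @rdname accessors
#' @export
setMethod("arrivalTimes", "PhotonTrace", function(x) x@arrivalTimes)
#' @rdname accessors
#' @export
setMethod("channels", "PhotonTrace",
          function(x) c("donor", "acceptor")[x@channels + 1L])
#' @rdname accessors
#' @export
setMethod("traceId", "PhotonTrace", function(x) x@traceId)
#' @rdname accessors
#' @export
setMethod("traceDuration", "PhotonTrace", function(x) x@duration)
#' @rdname accessors
#' @export
setMethod("nPhotons", "PhotonTrace", function(x) length(x@arrivalTimes))
#' @rdname accessors
#' @export
setMethod("traceMetadata", "PhotonTrace", function(x) x@metadata)
#' @rdname accessors
#' @export
setMethod("arrivalTimes", "TransitionWindow", function(x) x@photons@arrivalTimes)
#' @rdname accessors
#' @export
setMethod("channels", "TransitionWindow", function(x) channels(x@photons))
#' @rdname accessors
#' @export
setMethod("nPhotons", "TransitionWindow", function(x) length(x@photons@arrivalTimes))
#' @rdname accessors
#' @export
setMethod("rateMatrix", "KineticModel", function(x) x@K)
#' @rdname accessors
#' @export
setMethod("tauHat", "LikelihoodSurface", function(x) x@tauHat)
#' @rdname accessors
#' @export
setMethod("eHat", "LikelihoodSurface", function(x) x@eHat)
#' @rdname accessors
#' @export
setMethod("hasMaximum", "LikelihoodSurface", function(x) x@hasMaximum)
#' @rdname accessors
#' @export
setMethod("deltaLnL", "LikelihoodSurface", function(x) x@deltaLnL)
#' @rdname accessors
#' @export
setMethod("meanTPT", "TPTDistribution", function(x) x@mean)
#' @rdname accessors
#' @export
setMethod("evalPotential", "BarrierPotential", function(x, r) x@V(r))

setMethod("show", "PhotonTrace", function(object) {
  cat(sprintf("PhotonTrace '%s': %d photons over %.4g s (%.3g photons/ms)\n",
              object@traceId, length(object@arrivalTimes), object@duration,
              if (object@duration > 0)
                length(object@arrivalTimes) / object@duration / 1e3 else NA))
  if (length(object@arrivalTimes)) {
    fA <- mean(object@channels == 1L)
    cat(sprintf("  acceptor fraction: %.3f\n", fA))
  }
  invisible(NULL)
})

setMethod("show", "KineticModel", function(object) {
  cat(sprintf("KineticModel with %d states: %s\n", nrow(object@K),
              paste(object@stateNames, collapse = ", ")))
  cat("  rate matrix (s^-1):\n")
  m <- object@K
  dimnames(m) <- list(object@stateNames, object@stateNames)
  print(signif(m, 4))
  invisible(NULL)
})

setMethod("show", "LikelihoodSurface", function(object) {
  cat(sprintf(
    "LikelihoodSurface (%d tau x %d E grid, %d transition%s pooled)\n",
    length(object@tauGrid), length(object@eGrid), object@nPooled,
    if (object@nPooled == 1) "" else "s"))
  cat(sprintf("  max Delta lnL = %.3f at tau = %.3g us, E = %.3f%s\n",
              max(object@deltaLnL), object@tauHat * 1e6, object@eHat,
              if (object@hasMaximum) "" else " (no interior maximum)"))
  invisible(NULL)
})

setMethod("show", "BarrierPotential", function(object) {
  cat(sprintf("BarrierPotential '%s' on [%.3g, %.3g]", object@kind,
              object@x0, object@x1))
  if (is.finite(object@deltaV)) cat(sprintf(", deltaV = %.3g kT", object@deltaV))
  if (object@roughAmplitude > 0)
    cat(sprintf(", sinusoidal roughness %.3g kT / period %.3g",
                object@roughAmplitude, object@roughPeriod))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "TPTDistribution", function(object) {
  cat(sprintf(
    "TPTDistribution: mean t_TP = %.4g us (D = %.4g, basis %d, |1 - int p| = %.2g)\n",
    object@mean * 1e6, object@diffusionD,
    object@diagnostics$basisSize %||% NA_integer_,
    object@diagnostics$normResidual %||% NA_real_))
  invisible(NULL)
})

setMethod("show", "TauHistogram", function(object) {
  cat(sprintf("TauHistogram: %d transitions in %d log-spaced bins (%.3g ns - %.3g ms), %d without interior maximum\n",
              length(object@values), length(object@counts),
              object@edges[1] * 1e9, object@edges[length(object@edges)] * 1e3,
              object@nNoMaximum))
  invisible(NULL)
})

setMethod("show", "ShapeScanResult", function(object) {
  cat("ShapeScanResult\n")
  print(object@table, digits = 4)
  cat(sprintf("  best candidate (min chi^2): %s\n", object@bestCandidate))
  invisible(NULL)
})

setMethod("show", "RateEstimates", function(object) {
  cat(sprintf(
    "RateEstimates: kbar_on = %.4g s^-1, k_off = %.4g s^-1, k_+b = %.4g, k_-b = %.4g s^-1\n",
    object@kbarOn, object@kOff, object@kPlusB, object@kMinusB))
  if (length(object@cSolution) && is.finite(object@cSolution))
    cat(sprintf("  c = %.3g M  =>  k_on = %.4g M^-1 s^-1\n",
                object@cSolution, object@kbarOn / object@cSolution))
  if (length(object@boundaryFlags))
    cat("  at boundary:", paste(object@boundaryFlags, collapse = ", "), "\n")
  invisible(NULL)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
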