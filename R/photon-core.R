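# Photon-trace data model and the matrix-exponential likelihood engine.

#' Construct a photon trace
#'
#' @param arrivalTimes numeric, photon arrival times in seconds (strictly
#'   increasing).
#' @param channels per-photon channel labels: `"donor"`/`"acceptor"`, or
#'   0/1 integers.
#' @param traceId character identifier.
#' @param duration trace duration in seconds; defaults to the last arrival
#'   time.
#' @param metadata list of per-trace annotations.
#' @return a [PhotonTrace-class] object.
#' @export
#' @examples
#' tr <- photonTrace(c(1e-4, 3e-4, 7e-4), c("donor", "acceptor", "donor"))
#' nPhotons(tr)
photonTrace <- function(arrivalTimes, channels, traceId = "trace",
                        duration = NULL, metadata = list()) {
  if (is.character(channels)) {
    ok <- channels %in% c("donor", "acceptor")
    if (!all(ok)) stop("channels must be 'donor' or 'acceptor'")
    channels <- as.integer(channels == "acceptor")
  }
  if (is.null(duration))
    duration <- if (length(arrivalTimes)) arrivalTimes[length(arrivalTimes)] else 0
  new("PhotonTrace", arrivalTimes = as.numeric(arrivalTimes),
      channels = as.integer(channels), traceId = as.character(traceId),
      duration = as.numeric(duration), metadata = metadata)
}

#' Construct a kinetic model
#'
#' @param K square generator matrix (s^-1), columns summing to zero
#'   (`dp/dt = K p`).
#' @param nD,nA per-state donor/acceptor photon rates (photons/s).
#' @param pIni initial state distribution; defaults to the equilibrium
#'   distribution of `K`.
#' @param pFin final selection vector; defaults to all ones (summation).
#' @param stateNames optional state labels.
#' @return a [KineticModel-class] object.
#' @export
kineticModel <- function(K, nD, nA, pIni = NULL, pFin = NULL,
                         stateNames = NULL) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (is.null(stateNames))
    stateNames <- rownames(K) %||% paste0("S", seq_len(n))
  if (is.null(pFin)) pFin <- rep(1, n)
  if (is.null(pIni)) pIni <- equilibriumPopulations(unname(K))
  new("KineticModel", stateNames = stateNames, K = unname(K),
      nD = as.numeric(nD), nA = as.numeric(nA),
      pIni = as.numeric(pIni), pFin = as.numeric(pFin))
}

#' Two-state binding model (unbound/bound)
#'
#' @param kbarOn pseudo-first-order association rate (s^-1).
#' @param kOff dissociation rate (s^-1).
#' @param rates numeric length-4 `(nDU, nAU, nDB, nAB)` photon rates
#'   (photons/s).
#' @param pIni,pFin optional boundary vectors (see [kineticModel()]).
#' @return a [KineticModel-class] with states U, B.
#' @export
bindingModel2 <- function(kbarOn, kOff, rates, pIni = NULL, pFin = NULL) {
  K <- matrix(c(-kbarOn, kbarOn, kOff, -kOff), 2, 2)
  kineticModel(K, nD = rates[c(1, 3)], nA = rates[c(2, 4)],
               pIni = pIni, pFin = pFin, stateNames = c("U", "B"))
}

#' Three-state transition-path model (unbound/intermediate/bound)
#'
#' The transition path is represented by a virtual intermediate state I with
#' mean lifetime `tauI = 1/(2 kI)` between the unbound and bound states; the
#' two exit rates from I are set equal.
#'
#' @param kOnPrime,kOffPrime slow entry rates into I from U and B (s^-1).
#' @param tauI intermediate lifetime (s).
#' @param rates numeric length-4 `(nDU, nAU, nDB, nAB)` photon rates.
#' @param EI intermediate transfer efficiency.
#' @param EB mean bound-state transfer efficiency used for the rate
#'   interpolation (with the unbound efficiency fixed at 0).
#' @param pIni,pFin optional boundary vectors.
#' @return a [KineticModel-class] with states U, I, B.
#' @export
bindingModel3 <- function(kOnPrime, kOffPrime, tauI, rates, EI, EB,
                          pIni = NULL, pFin = NULL) {
  kI <- 1 / (2 * tauI)
  K <- matrix(c(-kOnPrime, kOnPrime, 0,
                kI, -2 * kI, kI,
                0, kOffPrime, -kOffPrime), 3, 3)
  nI <- intermediateRates(rates, EI, EB)
  kineticModel(K, nD = c(rates[1], nI[1], rates[3]),
               nA = c(rates[2], nI[2], rates[4]),
               pIni = pIni, pFin = pFin, stateNames = c("U", "I", "B"))
}

#' Photon rates of the intermediate state
#'
#' Linear interpolation between the unbound and bound rates on the
#' transfer-efficiency scale: `n_c^I = n_c^U + (EI - EU)/(EB - EU) *
#' (n_c^B - n_c^U)` with `EU = 0`.
#'
#' @param rates numeric length-4 `(nDU, nAU, nDB, nAB)`.
#' @param EI intermediate transfer efficiency.
#' @param EB mean bound-state transfer efficiency.
#' @return numeric length-2 `(nDI, nAI)`.
#' @export
intermediateRates <- function(rates, EI, EB) {
  if (EB <= 0) stop("EB must be positive to interpolate intermediate rates")
  frac <- EI / EB
  pmax(c(rates[1] + frac * (rates[3] - rates[1]),
         rates[2] + frac * (rates[4] - rates[2])), 0)
}

#' Three-state association/dissociation model with a dark (blinking) state
#'
#' Blinking is modeled in the low-FRET unbound state with entry/exit rates
#' `kPlusB`/`kMinusB`.  The dark state's acceptor rate is constrained to the
#' unbound acceptor rate (acceptor background) and its donor rate to the
#' bound donor rate.
#'
#' @param kbarOn,kOff association/dissociation rates (s^-1).
#' @param kPlusB,kMinusB dark-state entry/exit rates (s^-1).
#' @param rates numeric length-4 `(nDU, nAU, nDB, nAB)` photon rates.
#' @param pIni optional initial distribution (defaults to equilibrium).
#' @return a [KineticModel-class] with states U, B, dark.
#' @export
blinkingModel <- function(kbarOn, kOff, kPlusB, kMinusB, rates, pIni = NULL) {
  K <- matrix(c(-(kbarOn + kPlusB), kbarOn, kPlusB,
                kOff, -kOff, 0,
                kMinusB, 0, -kMinusB), 3, 3)
  kineticModel(K, nD = c(rates[1], rates[3], rates[3]),
               nA = c(rates[2], rates[4], rates[2]),
               pIni = pIni, stateNames = c("U", "B", "dark"))
}

#' Equilibrium state populations of a kinetic model
#'
#' Solves `K p_eq = 0` with `sum(p_eq) = 1`.
#'
#' @param model a [KineticModel-class] (or a bare generator matrix).
#' @return numeric probability vector.
#' @export
#' @examples
#' m <- bindingModel2(1, 3, c(180, 20, 30, 170) * 1e3)
#' equilibriumPopulations(m)  # (0.75, 0.25)
equilibriumPopulations <- function(model) {
  K <- if (is(model, "KineticModel")) model@K else as.matrix(model)
  n <- nrow(K)
  sv <- svd(K)$d
  if (n > 1 && sv[n - 1] < 1e-10 * max(sv[1], 1))
    stop("reducible or degenerate rate matrix: stationary distribution is not unique")
  A <- rbind(K, rep(1, n))
  p <- qr.solve(A, c(rep(0, n), 1))
  if (any(p < -1e-8)) stop("rate matrix has no non-negative stationary distribution")
  p <- pmax(p, 0)
  p / sum(p)
}

#' Photon-by-photon log-likelihood of a trace under a kinetic model
#'
#' Evaluates the log of
#' `p_fin^T prod_i [ n_{c_i} exp((K - n_D - n_A) tau_i) ] p_ini`
#' with later photons applied leftmost and `tau_1 = 0`, followed by a
#' photon-free propagation over the interval between the last photon and the
#' trace duration.  The value is a dimensionful density: the log of
#' (photons/s)^N times a probability.  Numerical stability comes from
#' per-photon renormalization with an accumulated log scale.
#'
#' @param trace a [PhotonTrace-class].
#' @param model a [KineticModel-class].
#' @return scalar log-likelihood.
#' @export
traceLogLikelihood <- function(trace, model) {
  stopifnot(is(trace, "PhotonTrace"), is(model, "KineticModel"))
  t <- trace@arrivalTimes
  N <- length(t)
  if (N == 0)
    return(cpp_trace_loglik(numeric(0), integer(0), model@K, model@nD,
                            model@nA, model@pIni, model@pFin, trace@duration))
  tau <- c(0, diff(t))
  if (any(tau < 0)) stop("negative inter-photon time")
  tail <- trace@duration - t[N]
  cpp_trace_loglik(tau, trace@channels, model@K, model@nD, model@nA,
                   model@pIni, model@pFin, tail)
}

# objective helper: total negative log-likelihood of a set of
# preprocessed photon streams under the blinking model, parameters packed
# on the log scale.  The generator is built directly and the equilibrium
# distribution uses the tree-structure closed form (detailed balance):
# p_B/p_U = kbarOn/kOff, p_dark/p_U = kPlusB/kMinusB.
.kineticsNegLogLik <- function(logPar, streams) {
  J <- length(streams)
  k <- exp(logPar[1:4])
  K <- matrix(c(-(k[1] + k[3]), k[1], k[3],
                k[2], -k[2], 0,
                k[4], 0, -k[4]), 3, 3)
  peq <- c(1, k[1] / k[2], k[3] / k[4])
  peq <- peq / sum(peq)
  pfin <- c(1, 1, 1)
  nll <- 0
  for (j in seq_len(J)) {
    r <- exp(logPar[4 + 4 * (j - 1) + 1:4])
    st <- streams[[j]]
    ll <- cpp_trace_loglik(st$tau, st$chan, K,
                           c(r[1], r[3], r[3]), c(r[2], r[4], r[2]),
                           peq, pfin, st$tail)
    if (!is.finite(ll)) return(1e12)
    nll <- nll - ll
  }
  nll
}

#' Fit association/dissociation and blinking kinetics to long photon traces
#'
#' Maximizes the summed photon-by-photon log-likelihood of the three-state
#' (unbound/bound/dark) model over the shared kinetic rates and the
#' per-trace photon rates, with the dark-state rates constrained
#' (`nA^dark = nA^U`, `nD^dark = nD^B`) and the initial distribution set to
#' the equilibrium populations.
#'
#' @param traces list of [PhotonTrace-class] objects.
#' @param init a [RateEstimates-class] or a list with elements `kbarOn`,
#'   `kOff`, `kPlusB`, `kMinusB` and `rates` (length-4 photon-rate guess
#'   shared across traces, photons/s).
#' @param cSolution molar concentration of the labeled partner (for the
#'   second-order rate); `NA` to skip.
#' @param control passed to [stats::optim()] (`method = "L-BFGS-B"`).
#' @return a [RateEstimates-class].  Rates that converge to the lower
#'   boundary are listed in `boundaryFlags`.  Non-convergence raises an
#'   error of class `tpfretConvergenceError` carrying the best-so-far
#'   estimates in its `estimates` field.
#' @export
fitLongTraceKinetics <- function(traces, init, cSolution = NA_real_,
                                 control = list(maxit = 300)) {
  stopifnot(length(traces) >= 1)
  if (is(init, "RateEstimates")) {
    k0 <- c(init@kbarOn, init@kOff, init@kPlusB, init@kMinusB)
    r0 <- as.numeric(init@perTraceRates[1, c("nDU", "nAU", "nDB", "nAB")])
  } else {
    k0 <- c(init$kbarOn, init$kOff, init$kPlusB, init$kMinusB)
    r0 <- init$rates
  }
  J <- length(traces)
  streams <- lapply(traces, function(tr) {
    t <- tr@arrivalTimes
    list(tau = if (length(t)) c(0, diff(t)) else numeric(0),
         chan = tr@channels,
         tail = tr@duration - if (length(t)) t[length(t)] else 0)
  })
  floorRate <- 1e-4
  p0 <- log(pmax(c(k0, rep(r0, J)), floorRate))
  lower <- rep(log(floorRate), length(p0))
  upper <- rep(log(1e8), length(p0))
  fit <- optim(p0, .kineticsNegLogLik, streams = streams,
               method = "L-BFGS-B", lower = lower, upper = upper,
               control = control)
  kin <- exp(fit$par[1:4])
  atFloor <- kin <= 10 * floorRate   # at or near the zero boundary
  flags <- c("kbarOn", "kOff", "kPlusB", "kMinusB")[atFloor]
  prt <- do.call(rbind, lapply(seq_len(J), function(j)
    data.frame(traceId = traces[[j]]@traceId,
               t(setNames(exp(fit$par[4 + 4 * (j - 1) + 1:4]),
                          c("nDU", "nAU", "nDB", "nAB"))))))
  est <- new("RateEstimates", kbarOn = kin[1], kOff = kin[2],
             kPlusB = kin[3], kMinusB = kin[4], perTraceRates = prt,
             cSolution = cSolution, logLik = -fit$value,
             boundaryFlags = flags)
  if (fit$convergence != 0 && fit$convergence != 1) {
    cond <- structure(
      class = c("tpfretConvergenceError", "error", "condition"),
      list(message = paste0("kinetics optimizer did not converge (code ",
                            fit$convergence, "): ", fit$message),
           call = sys.call(-1), estimates = est))
    stop(cond)
  }
  if (fit$convergence == 1)
    warning("iteration limit reached in kinetics fit; estimates may be rough")
  est
}

#' Second-order association rate from a fit
#'
#' @param est a [RateEstimates-class] with `cSolution` set.
#' @return `kbarOn / cSolution` (M^-1 s^-1).
#' @export
kOn <- function(est) {
  stopifnot(is(est, "RateEstimates"), is.finite(est@cSolution))
  est@kbarOn / est@cSolution
}

#' Viterbi decoding of the state path underlying a photon trace
#'
#' Max-product analogue of the photon likelihood on its interval
#' factorization: one hidden state per inter-photon interval, with the
#' transition weight from state b to state a at photon i given by
#' `n_{c_i}(a) [exp(H tau_i)]_{ab}`.  The decoded path is piecewise constant
#' with boundaries at the midpoints between photons where the state changes.
#'
#' @param trace a [PhotonTrace-class].
#' @param model a [KineticModel-class].
#' @return a [StatePath-class].
#' @export
viterbiDecode <- function(trace, model) {
  stopifnot(is(trace, "PhotonTrace"), is(model, "KineticModel"))
  t <- trace@arrivalTimes
  N <- length(t)
  n <- nrow(model@K)
  if (N == 0)
    return(new("StatePath", boundaries = c(0, trace@duration),
               states = which.max(model@pIni), traceId = trace@traceId))
  H <- model@K - diag(model@nD + model@nA, n)
  eg <- eigen(H)
  V <- eg$vectors; Vi <- solve(V); lam <- eg$values
  tau <- c(0, diff(t))
  nmat <- rbind(model@nD, model@nA)
  chan <- trace@channels + 1L
  logDelta <- log(model@pIni + 1e-300)
  back <- matrix(0L, N, n)
  for (i in seq_len(N)) {
    P <- if (tau[i] > 0) Re(V %*% (exp(lam * tau[i]) * Vi)) else diag(n)
    P[P < 0] <- 0
    W <- log(P + 1e-300) + log(nmat[chan[i], ] + 1e-300)  # W[a,b] rows a
    cand <- W + matrix(logDelta, n, n, byrow = TRUE)
    back[i, ] <- max.col(cand, ties.method = "first")
    logDelta <- cand[cbind(seq_len(n), back[i, ])]
  }
  logDelta <- logDelta + log(model@pFin + 1e-300)
  states <- integer(N)
  states[N] <- which.max(logDelta)
  for (i in rev(seq_len(N - 1))) states[i] <- back[i + 1, states[i + 1]]
  # collapse to segments with boundaries at inter-photon midpoints
  chg <- which(diff(states) != 0)
  bounds <- c(0, (t[chg] + t[chg + 1]) / 2, trace@duration)
  segStates <- states[c(chg, N)]
  new("StatePath", boundaries = bounds, states = as.integer(segStates),
      traceId = trace@traceId)
}
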