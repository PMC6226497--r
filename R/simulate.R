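# Synthetic-data generation: photon traces from state trajectories,
# Gillespie long traces with blinking, and Brownian-dynamics transition
# paths converted to photon streams through the Foerster equation.

#' Simulation configuration for transition-window cohorts
#'
#' The defaults emulate the experimental conditions of immobilized-molecule
#' binding measurements at high excitation power: ~200 photons/ms total
#' count rate, windows of a few ms containing at least 1000 photons and a
#' single unbound-to-bound transition at the center, and transition-path
#' times drawn from an exponential law with an 80 us mean.
#'
#' @param nTransitions number of windows in a cohort.
#' @param rates numeric length-4 `(nDU, nAU, nDB, nAB)` photon rates
#'   (photons/s).
#' @param windowLength window duration (s).
#' @param tptLaw transition-path-time law: `list(type = "delta", value =)`,
#'   `list(type = "exponential", mean =)`, or a [TPTDistribution-class].
#' @param EI intermediate transfer efficiency (on the apparent-efficiency
#'   scale of the calibrated rates).
#' @param background numeric length-2 `(bgD, bgA)` background rates
#'   (photons/s), added uniformly.
#' @param cohortTable optional data.frame with per-window columns
#'   `windowLength`, `nDU`, `nAU`, `nDB`, `nAB` mimicking a measured
#'   cohort (rows recycled as needed); overrides `rates`/`windowLength`.
#' @param rateEstimation `"empirical"` (estimate window state rates from
#'   the simulated photons, as for measured data) or `"truth"`.
#' @return a list of class `tpfretSimConfig`.
#' @export
simulationConfig <- function(nTransitions = 686,
                             rates = c(180, 20, 30, 170) * 1e3,
                             windowLength = 6e-3,
                             tptLaw = list(type = "exponential", mean = 80e-6),
                             EI = 0.72, background = c(0, 0),
                             cohortTable = NULL,
                             rateEstimation = c("empirical", "truth")) {
  stopifnot(all(rates >= 0), windowLength >= 1e-3, all(background >= 0))
  structure(list(nTransitions = nTransitions, rates = rates,
                 windowLength = windowLength, tptLaw = tptLaw, EI = EI,
                 background = background, cohortTable = cohortTable,
                 rateEstimation = match.arg(rateEstimation)),
            class = "tpfretSimConfig")
}

#' Draw transition-path times from a generating law
#'
#' @param law `list(type = "delta", value =)`, `list(type = "exponential",
#'   mean =)`, or a [TPTDistribution-class] (inverse-CDF sampling from its
#'   spectral representation).
#' @param n number of draws.
#' @return numeric vector of times (s); uses the current RNG stream.
#' @export
sampleTPT <- function(law, n = 1) {
  if (is(law, "TPTDistribution")) {
    if (abs(.trapz(law@tGrid, law@density) - 1) > 5e-3)
      stop("unnormalized density")
    modes <- list(rates = law@rates, amplitudes = law@weights)
    # CDF from the damped spectral survival function, inverted on the grid
    Fg <- cummax(pmin(pmax(1 - .mixtureSurvival(modes, law@tGrid), 0), 1))
    u <- runif(n)
    out <- approx(c(0, Fg), c(0, law@tGrid), xout = pmin(u, max(Fg)),
                  ties = "ordered")$y
    return(out)
  }
  switch(law$type,
         delta = rep(law$value, n),
         exponential = rexp(n, rate = 1 / law$mean),
         stop("unknown transition-path-time law"))
}

# Photon stream over piecewise-constant emission: segments given by
# boundary times (length m+1) and per-segment (nD, nA) rates.
.poissonSegments <- function(bounds, nDseg, nAseg) {
  m <- length(bounds) - 1
  len <- diff(bounds)
  tot <- nDseg + nAseg
  counts <- rpois(m, tot * len)
  idx <- rep.int(seq_len(m), counts)
  t <- bounds[idx] + runif(sum(counts)) * len[idx]
  pA <- ifelse(tot[idx] > 0, nAseg[idx] / tot[idx], 0)
  ch <- as.integer(runif(length(t)) < pA)
  o <- order(t)
  t <- t[o]; ch <- ch[o]
  keep <- c(TRUE, diff(t) > 0)   # exact floating-point ties are dropped
  list(times = t[keep], channels = ch[keep])
}

# estimate a window's state rates and switch time the way the measurement
# pipeline does: ML changepoint of the channel composition, then per-side
# counting rates outside a guard band
.assembleWindow <- function(times, channels, windowLength, guard, truth,
                            trueRates, useTruth, traceId) {
  ph <- photonTrace(times, channels, traceId = traceId,
                    duration = windowLength, metadata = list(truth = truth))
  if (useTruth) {
    return(transitionWindow(ph, truth$switchCenter,
                            preRates = trueRates[1:2],
                            postRates = trueRates[3:4]))
  }
  cp <- channelChangepoint(times, channels)
  tc <- cp$time
  sideRate <- function(idx) {
    if (length(idx) < 2) return(NULL)
    span <- times[idx[length(idx)]] - times[idx[1]]
    if (span <= 0) return(NULL)
    c(sum(channels[idx] == 0L), sum(channels[idx] == 1L)) / span
  }
  pre <- sideRate(which(times < tc - guard))
  post <- sideRate(which(times > tc + guard))
  if (is.null(pre)) pre <- trueRates[1:2]
  if (is.null(post)) post <- trueRates[3:4]
  transitionWindow(ph, tc, preRates = pre, postRates = post)
}

#' Simulate a photon window containing one binding transition
#'
#' Generates an unbound segment, an intermediate dwell of duration drawn
#' from the configured transition-path-time law (photon rates interpolated
#' at `EI`), and a bound segment, with photons as a piecewise Poisson
#' process assigned to channels by the rate ratio.  The generating truth
#' (transition-path time, switch times) is stored in the trace metadata;
#' the window's state rates are estimated from the photons unless
#' `rateEstimation = "truth"`.
#'
#' @param config a [simulationConfig()].
#' @param windowId identifier.
#' @param guard guard band for empirical rate estimation (s).
#' @return a [TransitionWindow-class].
#' @export
simulateTransitionWindow <- function(config, windowId = "sim", guard = 250e-6) {
  stopifnot(inherits(config, "tpfretSimConfig"))
  r <- config$rates
  Lw <- config$windowLength
  tTP <- min(sampleTPT(config$tptLaw, 1), 0.5 * Lw)
  EB <- .apparentEB(r)
  nI <- intermediateRates(r, config$EI, EB)
  s1 <- Lw / 2 - tTP / 2
  bounds <- c(0, s1, s1 + tTP, Lw)
  nD <- c(r[1], nI[1], r[3]) + config$background[1]
  nA <- c(r[2], nI[2], r[4]) + config$background[2]
  ph <- .poissonSegments(bounds, nD, nA)
  truth <- list(tTP = tTP, switchStart = s1, switchEnd = s1 + tTP,
                switchCenter = Lw / 2, EI = config$EI, EB = EB, rates = r)
  .assembleWindow(ph$times, ph$channels, Lw, guard, truth, r,
                  config$rateEstimation == "truth", windowId)
}

# apparent mean bound-state efficiency implied by a background-free rate
# set, via the crosstalk/gamma calibration identities
.apparentEB <- function(rates) {
  beta <- rates[2] / rates[1]
  gam <- (rates[4] - beta * rates[3]) / (rates[1] - rates[3])
  acc <- rates[4] - beta * rates[3]
  acc / (acc + gam * rates[3])
}

#' Simulate a cohort of transition windows
#'
#' @param config a [simulationConfig()]; if it carries a `cohortTable`, the
#'   per-window lengths and rates are taken from it (rows recycled).
#' @param idPrefix window identifier prefix.
#' @return list with `windows` (list of [TransitionWindow-class]) and
#'   `truth` (data.frame of generating values).
#' @export
simulateTransitionCohort <- function(config, idPrefix = "w") {
  n <- config$nTransitions
  tab <- config$cohortTable
  windows <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- config
    if (!is.null(tab)) {
      row <- tab[((i - 1) %% nrow(tab)) + 1, ]
      ci$windowLength <- row$windowLength
      ci$rates <- as.numeric(row[c("nDU", "nAU", "nDB", "nAB")])
    }
    w <- simulateTransitionWindow(ci, windowId = sprintf("%s%04d", idPrefix, i))
    windows[[i]] <- w
    tr <- w@photons@metadata$truth
    truths[[i]] <- data.frame(id = w@photons@traceId, tTP = tr$tTP,
                              EI = tr$EI, windowLength = ci$windowLength)
  }
  list(windows = windows, truth = do.call(rbind, truths))
}

#' Simulate a long photon trace with binding and blinking kinetics
#'
#' Gillespie simulation of the state trajectory under the model's
#' generator, with photons emitted as a piecewise Poisson process at the
#' per-state donor/acceptor rates.
#'
#' @param model a [KineticModel-class] (e.g. [blinkingModel()]).
#' @param duration trace duration (s).
#' @param traceId identifier.
#' @return a [PhotonTrace-class]; the state trajectory is stored in
#'   `metadata$truth` (`boundaries`, `states`).
#' @export
simulateLongTrace <- function(model, duration, traceId = "long") {
  K <- model@K
  n <- nrow(K)
  s <- sample.int(n, 1, prob = model@pIni)
  t <- 0
  bounds <- 0
  states <- integer()
  while (t < duration) {
    exitRate <- -K[s, s]
    dwell <- if (exitRate > 0) rexp(1, exitRate) else Inf
    tEnd <- min(t + dwell, duration)
    states <- c(states, s)
    bounds <- c(bounds, tEnd)
    if (tEnd >= duration) break
    rates <- K[, s]
    rates[s] <- 0
    s <- sample.int(n, 1, prob = rates)
    t <- tEnd
  }
  ph <- .poissonSegments(bounds, model@nD[states], model@nA[states])
  photonTrace(ph$times, ph$channels, traceId = traceId, duration = duration,
              metadata = list(truth = list(boundaries = bounds,
                                           states = states)))
}

#' Brownian-dynamics transition paths on a free-energy surface
#'
#' Euler-Maruyama integration (`dx = -D V'(x) dt + sqrt(2 D dt) xi`,
#' energies in kT) launched at `x0 + eps`; only trajectories absorbed at
#' `x1` without first returning to `x0` are retained.  Within-step boundary
#' crossings are handled with the Brownian-bridge correction.
#'
#' @param potential a [BarrierPotential-class].
#' @param D diffusion coefficient (coordinate^2/s).
#' @param nPaths number of successful transition paths to collect.
#' @param dt time step (s); the default 0.1 us resolves the curvature of
#'   the shapes used here at the calibrated diffusion coefficients.
#' @param eps launch offset as a fraction of `(x1 - x0)`.
#' @param nStore store full position records for this many paths.
#' @param nGrid drift-interpolation grid size.
#' @param maxLaunch abort if this many launches do not yield `nPaths`
#'   successes (success rate guard).
#' @return list with `durations` (s), `launches`, and `paths` (list of
#'   numeric position vectors for the first `nStore` successes, time step
#'   `dt`).
#' @export
bdTransitionPaths <- function(potential, D, nPaths, dt = 1e-7, eps = 1e-3,
                              nStore = 0, nGrid = 20001, maxLaunch = NULL) {
  stopifnot(is(potential, "BarrierPotential"), D > 0, dt > 0)
  x0 <- potential@x0; x1 <- potential@x1
  xg <- seq(x0, x1, length.out = nGrid)
  drift <- -D * potential@dV(xg)
  # launches that fall back to x0 cost only a few steps, so a generous
  # cap is cheap; barrier-top shapes have success rates ~ eps * exp(-dV)
  if (is.null(maxLaunch)) maxLaunch <- max(nPaths * 2e5, 1e7)
  res <- cpp_bd_paths(xg, drift, D, dt, eps * (x1 - x0), as.integer(nPaths),
                      maxLaunch, as.integer(nStore))
  res$dt <- dt
  res
}

#' Convert a Brownian-dynamics path to a discretized efficiency-state trace
#'
#' Distances are converted to transfer efficiencies with the Foerster
#' equation `E = 1 / (1 + (r/R0)^6)` and binned into 20 states of width
#' 0.05; per-state photon rates interpolate linearly between the unbound
#' and bound rates on the efficiency scale (`n_c(E) = E (n_c^B - n_c^U) +
#' n_c^U`).
#'
#' @param positions numeric, path positions (reaction-coordinate units).
#' @param R0 Foerster radius in coordinate units.
#' @param rates optional numeric length-4 `(nDU, nAU, nDB, nAB)`; when
#'   given, per-state photon rates are attached.
#' @return list with `E` (per-step efficiency), `state` (1-based bin index,
#'   bins `[0,0.05), ..., [0.95,1]`), `stateE` (bin centers), and (when
#'   `rates` is given) `nD`, `nA` per state bin.
#' @export
pathToEfficiencyStates <- function(positions, R0 = 1, rates = NULL) {
  E <- 1 / (1 + (positions / R0)^6)
  state <- pmin(floor(E / 0.05), 19) + 1L
  stateE <- (seq_len(20) - 0.5) * 0.05
  out <- list(E = E, state = as.integer(state), stateE = stateE)
  if (!is.null(rates)) {
    out$nD <- stateE * (rates[3] - rates[1]) + rates[1]
    out$nA <- stateE * (rates[4] - rates[2]) + rates[2]
  }
  out
}

#' Simulate a transition-window cohort from Brownian-dynamics paths
#'
#' Full forward model for validation: transition paths are generated on the
#' potential, converted to 20-state efficiency trajectories (the reaction
#' coordinate enters the Foerster equation as a dye separation that
#' shrinks as binding proceeds, so efficiency rises from the unbound to
#' the bound side), embedded between unbound and bound segments in a
#' window, and read out as photons.
#'
#' @param potential a [BarrierPotential-class] (BD family on `[0.8, 1.2]`).
#' @param D diffusion coefficient (coordinate^2/s).
#' @param config a [simulationConfig()] (supplies rates, window length,
#'   cohort size).
#' @param dt BD time step (s).
#' @param R0 Foerster radius in coordinate units.
#' @param guard guard band for empirical rate estimation (s).
#' @return as [simulateTransitionCohort()].
#' @export
simulateBDCohort <- function(potential, D, config, dt = 1e-7, R0 = 1,
                             guard = 250e-6) {
  n <- config$nTransitions
  r <- config$rates
  paths <- bdTransitionPaths(potential, D, nPaths = n, dt = dt, nStore = n)
  Lw <- config$windowLength
  windows <- vector("list", n)
  truths <- vector("list", n)
  ctr <- (potential@x0 + potential@x1) / 2
  for (i in seq_len(n)) {
    pos <- paths$paths[[i]]
    # reflect: dye separation decreases as the reaction coordinate advances
    eff <- pathToEfficiencyStates(2 * ctr - pos, R0 = R0, rates = r)
    tTP <- length(pos) * dt
    tTP <- min(tTP, 0.5 * Lw)
    nsteps <- min(length(pos), floor(0.5 * Lw / dt))
    s1 <- Lw / 2 - tTP / 2
    # collapse consecutive equal states into segments
    st <- eff$state[seq_len(nsteps)]
    chg <- c(TRUE, diff(st) != 0)
    segState <- st[chg]
    segStart <- s1 + (which(chg) - 1) * dt
    bounds <- c(0, segStart, s1 + nsteps * dt, Lw)
    nD <- c(r[1], eff$nD[segState], r[3])
    nA <- c(r[2], eff$nA[segState], r[4])
    ph <- .poissonSegments(bounds, nD, nA)
    truth <- list(tTP = tTP, switchStart = s1, switchEnd = s1 + tTP,
                  switchCenter = Lw / 2, EI = NA_real_,
                  EB = .apparentEB(r), rates = r)
    windows[[i]] <- .assembleWindow(ph$times, ph$channels, Lw, guard, truth,
                                    r, config$rateEstimation == "truth",
                                    sprintf("bd%04d", i))
    truths[[i]] <- data.frame(id = sprintf("bd%04d", i), tTP = tTP,
                              EI = NA_real_, windowLength = Lw)
  }
  list(windows = windows, truth = do.call(rbind, truths))
}

#' Synthetic cohort rate table
#'
#' Loads the packaged synthetic table of per-window lengths and state
#' photon rates whose marginals mimic measured cohorts (total rates
#' 100-500 photons/ms, windows long enough for at least 1000 photons).
#' The table is a configurable stand-in for a measured cohort summary.
#'
#' @return data.frame with columns `windowLength`, `nDU`, `nAU`, `nDB`,
#'   `nAB`.
#' @export
cohortRateTable <- function() {
  f <- system.file("extdata", "cohort_rates_synthetic.csv",
                   package = "tpfret", mustWork = TRUE)
  read.table(f, header = TRUE, sep = ",")
}
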