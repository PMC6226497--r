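# Shared fixtures.  Expensive objects are built lazily once per test run
# and cached in this environment.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# canonical high-power rate set (photons/s): ~200 photons/ms total,
# unbound acceptor fraction 10% (crosstalk), bound donor fraction 15%
stdRates <- function() c(180, 20, 30, 170) * 1e3

stdCalibration <- function()
  fretCalibration(EBMean = tpfret:::.apparentEB(stdRates()))

# one clean simulated window under the standard conditions
stdWindow <- function(seed = 401, tTP = 80e-6) {
  withr::with_seed(seed, {
    cfg <- simulationConfig(nTransitions = 1,
                            tptLaw = list(type = "delta", value = tTP))
    simulateTransitionWindow(cfg)
  })
}

# a small cohort with exponential transition-path times (shared by the
# pooling / deletion / monotonicity tests)
stdCohort <- function(n = 40, seed = 402) {
  cached(sprintf("cohort_%d_%d", n, seed), withr::with_seed(seed, {
    simulateTransitionCohort(simulationConfig(nTransitions = n))
  }))
}

# matrix-exponential by scaling and squaring of the Taylor series --
# an oracle independent of the eigendecomposition used by the engine
expmSeries <- function(A) {
  nrm <- max(abs(A))
  s <- max(0, ceiling(log2(max(nrm, 1e-300))) + 4)
  B <- A / 2^s
  X <- diag(nrow(A))
  term <- X
  for (k in 1:30) {
    term <- term %*% B / k
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

# reference photon-by-photon likelihood via explicit matrix-exponential
# products (renormalized), independent of the C++ engine
refLogLik <- function(trace, model) {
  t <- trace@arrivalTimes
  H <- model@K - diag(model@nD + model@nA, nrow(model@K))
  v <- model@pIni
  acc <- 0
  tau <- if (length(t)) c(0, diff(t)) else numeric(0)
  for (i in seq_along(t)) {
    v <- as.numeric(expmSeries(H * tau[i]) %*% v)
    v <- (if (trace@channels[i] == 0L) model@nD else model@nA) * v
    s <- sum(abs(v)); acc <- acc + log(s); v <- v / s
  }
  tl <- trace@duration - if (length(t)) t[length(t)] else 0
  v <- as.numeric(expmSeries(H * tl) %*% v)
  acc + log(sum(model@pFin * v))
}

# discrete-time forward algorithm on a fine uniform grid: photons snapped
# to grid points, one fixed per-step propagator
forwardGridLogLik <- function(trace, model, dt = 1e-8) {
  t <- trace@arrivalTimes
  H <- model@K - diag(model@nD + model@nA, nrow(model@K))
  P <- expmSeries(H * dt)
  steps <- round(c(0, diff(t)) / dt)
  v <- model@pIni
  acc <- 0
  for (i in seq_along(t)) {
    for (k in seq_len(steps[i])) v <- as.numeric(P %*% v)
    v <- (if (trace@channels[i] == 0L) model@nD else model@nA) * v
    s <- sum(abs(v)); acc <- acc + log(s); v <- v / s
  }
  tl <- round((trace@duration - t[length(t)]) / dt)
  for (k in seq_len(tl)) v <- as.numeric(P %*% v)
  acc + log(sum(model@pFin * v))
}

# random valid generator with symmetric connectivity (for property tests)
randomGenerator <- function(n = 3) {
  K <- matrix(runif(n * n, 0.5, 5), n, n)
  K[lower.tri(K)] <- t(K)[lower.tri(K)] * runif(sum(lower.tri(K)), 0.5, 2)
  diag(K) <- 0
  diag(K) <- -colSums(K)
  K
}
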