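# Photon-trace data model and likelihood engine.

test_that("PhotonTrace enforces its invariants", {
  expect_s4_class(photonTrace(c(1e-4, 2e-4), c("donor", "acceptor")),
                  "PhotonTrace")
  expect_error(photonTrace(c(2e-4, 1e-4), c(0L, 1L)), "increasing")
  expect_error(photonTrace(c(1e-4, 2e-4), c(0L, 1L), duration = 1e-5),
               "duration")
  expect_error(photonTrace(1e-4, c(0L, 1L)), "length")
})

test_that("equilibrium populations solve K p = 0", {
  m <- bindingModel2(1, 3, stdRates())
  expect_equal(equilibriumPopulations(m), c(0.75, 0.25))
  m3 <- blinkingModel(1, 1, 1, 1, stdRates())
  expect_equal(equilibriumPopulations(m3), rep(1 / 3, 3))
  withr::with_seed(7, {
    for (i in 1:20) {
      K <- randomGenerator(3)
      p <- equilibriumPopulations(K)
      expect_lt(max(abs(K %*% p)), 1e-10)
      expect_equal(sum(p), 1, tolerance = 1e-10)
      expect_true(all(p >= 0))
    }
  })
  # reducible generator: two disconnected states
  expect_error(equilibriumPopulations(matrix(0, 2, 2)), "stationary")
})

test_that("single-state likelihood matches the closed form", {
  # rates in ms^-1, times in ms (the engine is unit-agnostic):
  # lnL = 2 ln(80) + ln(20) - 200
  m <- kineticModel(matrix(0, 1, 1), nD = 80, nA = 20, pIni = 1, pFin = 1)
  tr <- photonTrace(c(0, 1, 2), c(0L, 1L, 0L), duration = 2)
  expect_equal(traceLogLikelihood(tr, m), 2 * log(80) + log(20) - 200,
               tolerance = 1e-12)
})

test_that("probability is conserved when no photons are emitted", {
  withr::with_seed(11, {
    for (i in 1:10) {
      K <- randomGenerator(3)
      m <- kineticModel(K, nD = rep(0, 3), nA = rep(0, 3),
                        pFin = rep(1, 3))
      tr <- photonTrace(numeric(0), integer(0),
                        duration = runif(1, 1e-4, 10))
      expect_equal(traceLogLikelihood(tr, m), 0, tolerance = 1e-9)
    }
  })
})

test_that("empty trace uses the full-duration propagator", {
  m <- bindingModel2(2, 16, stdRates(), pIni = c(1, 0), pFin = c(1, 1))
  tr <- photonTrace(numeric(0), integer(0), duration = 2e-3)
  expect_equal(traceLogLikelihood(tr, m), refLogLik(tr, m),
               tolerance = 1e-10)
})

test_that("likelihood matches independent matrix-exponential oracles", {
  withr::with_seed(23, {
    for (i in 1:8) {
      K <- randomGenerator(3)
      nD <- runif(3, 0, 200) * 1e3
      nA <- runif(3, 0, 200) * 1e3
      m <- kineticModel(K * runif(1, 1, 100), nD, nA,
                        pIni = c(1, 0, 0), pFin = c(1, 1, 1))
      N <- sample(5:25, 1)
      t <- sort(runif(N, 0, 2e-3))
      tr <- photonTrace(t, sample(0:1, N, TRUE), duration = 2.2e-3)
      expect_equal(traceLogLikelihood(tr, m), refLogLik(tr, m),
                   tolerance = 1e-8)
    }
  })
})

test_that("likelihood matches a 10-ns discrete forward algorithm", {
  withr::with_seed(31, {
    m <- bindingModel3(0.2, 0.2, tauI = 80e-6, rates = stdRates(),
                       EI = 0.72, EB = 0.83,
                       pIni = c(1, 0, 0), pFin = c(0, 0, 1))
    N <- 20
    # photon times on the 10-ns grid so snapping is exact
    t <- sort(sample.int(2e4, N)) * 1e-8
    tr <- photonTrace(t, sample(0:1, N, TRUE), duration = 2.2e-4)
    ours <- traceLogLikelihood(tr, m)
    oracle <- forwardGridLogLik(tr, m, dt = 1e-8)
    expect_equal(ours, oracle, tolerance = 1e-6)
  })
})

test_that("likelihood is invariant under uniform time translation", {
  withr::with_seed(13, {
    m <- bindingModel2(2, 16, stdRates())
    t <- sort(runif(50, 0, 5e-3))
    ch <- sample(0:1, 50, TRUE)
    tr1 <- photonTrace(t, ch, duration = 6e-3)
    tr2 <- photonTrace(t + 0.7, ch, duration = 6e-3 + 0.7)
    expect_equal(traceLogLikelihood(tr1, m), traceLogLikelihood(tr2, m),
                 tolerance = 1e-10)
  })
})

test_that("three-state model converges to the two-state model as tauI -> 0", {
  # the residual of the nested comparison is the physical O(n_tot * tauI)
  # correction, so it must shrink linearly with the intermediate lifetime
  withr::with_seed(41, {
    worst1 <- worst2 <- 0
    for (i in 1:100) {
      N <- 30
      t <- sort(runif(N, 0, 2e-3))
      ch <- sample(0:1, N, TRUE)
      tr <- photonTrace(t, ch, duration = 2.1e-3)
      m2 <- bindingModel2(0.1, 0.1, stdRates(),
                          pIni = c(1, 0), pFin = c(0, 1))
      EI <- runif(1, 0.1, 0.9)
      l2 <- traceLogLikelihood(tr, m2)
      mk <- function(tau)
        bindingModel3(0.2, 0.2, tauI = tau, rates = stdRates(),
                      EI = EI, EB = 0.83,
                      pIni = c(1, 0, 0), pFin = c(0, 0, 1))
      worst1 <- max(worst1, abs(traceLogLikelihood(tr, mk(1e-9)) - l2))
      worst2 <- max(worst2, abs(traceLogLikelihood(tr, mk(1e-11)) - l2))
    }
    expect_lt(worst1, 1e-4)
    expect_lt(worst2, 1e-6)
    expect_lt(worst2, worst1 / 10)   # linear decay of the residual
  })
})

test_that("long-trace kinetics are recovered from simulated data", {
  withr::with_seed(21, {
    truth <- c(kbarOn = 2, kOff = 16, kPlusB = 1, kMinusB = 1)
    m <- blinkingModel(2, 16, 1, 1, c(180, 20, 30, 170))
    traces <- lapply(1:20, function(i) simulateLongTrace(m, 10, paste0("t", i)))
    fit <- fitLongTraceKinetics(
      traces, list(kbarOn = 3, kOff = 10, kPlusB = 0.5, kMinusB = 2,
                   rates = c(150, 30, 40, 150)),
      control = list(maxit = 300, factr = 1e9))
    est <- c(fit@kbarOn, fit@kOff, fit@kPlusB, fit@kMinusB)
    expect_true(all(abs(est - truth) / truth < 0.15))
    r1 <- as.numeric(fit@perTraceRates[1, c("nDU", "nAU", "nDB", "nAB")])
    expect_true(all(abs(r1 - c(180, 20, 30, 170)) / c(180, 20, 30, 170) < 0.25))
  })
})

test_that("a trace without transitions drives the association rate to the boundary", {
  withr::with_seed(22, {
    m <- blinkingModel(1e-4, 16, 1e-4, 2, c(180, 20, 30, 170))
    m@pIni <- c(1, 0, 0)  # start (and stay) unbound
    traces <- lapply(1:2, function(i) simulateLongTrace(m, 5, paste0("t", i)))
    fit <- fitLongTraceKinetics(
      traces, list(kbarOn = 0.5, kOff = 10, kPlusB = 0.5, kMinusB = 1,
                   rates = c(180, 20, 30, 170)),
      control = list(maxit = 500, factr = 1e7))
    expect_true("kbarOn" %in% fit@boundaryFlags)
  })
})

test_that("doubling the solution concentration doubles kbar_on, not k_on", {
  withr::with_seed(25, {
    rates <- c(180, 20, 30, 170)
    fitAt <- function(kbar, conc) {
      m <- blinkingModel(kbar, 16, 1, 1, rates)
      traces <- lapply(1:6, function(i) simulateLongTrace(m, 8, paste0("t", i)))
      fitLongTraceKinetics(
        traces, list(kbarOn = kbar * 1.4, kOff = 12, kPlusB = 0.6,
                     kMinusB = 1.5, rates = rates * 0.9),
        cSolution = conc, control = list(maxit = 200, factr = 1e9))
    }
    f1 <- fitAt(2, 50e-9)
    f2 <- fitAt(4, 100e-9)   # doubled concentration doubles the observed rate
    expect_equal(f2@kbarOn / f1@kbarOn, 2, tolerance = 0.5)
    expect_equal(kOn(f2) / kOn(f1), 1, tolerance = 0.5)
  })
})

test_that("Viterbi decoding matches exhaustive path enumeration", {
  m <- bindingModel2(5, 5, c(100, 5, 5, 100) * 1e3,
                     pIni = c(0.5, 0.5), pFin = c(1, 1))
  withr::with_seed(51, {
    for (rep in 1:5) {
      N <- 6
      t <- sort(runif(N, 0, 2e-3))
      ch <- sample(0:1, N, TRUE)
      tr <- photonTrace(t, ch, duration = 2e-3 + 1e-4)
      sp <- viterbiDecode(tr, m)
      # brute force over all 2^N interval labelings with the same weights
      H <- m@K - diag(m@nD + m@nA, 2)
      tau <- c(0, diff(t))
      Plist <- lapply(tau, function(x) expmSeries(H * x))
      nmat <- rbind(m@nD, m@nA)
      best <- -Inf; bestPath <- NULL
      for (code in 0:(2^N - 1)) {
        s <- as.integer(intToBits(code))[1:N] + 1L
        lp <- log(m@pIni[s[1]]) + log(nmat[ch[1] + 1, s[1]]) +
          log(Plist[[1]][s[1], s[1]])
        for (i in 2:N)
          lp <- lp + log(Plist[[i]][s[i], s[i - 1]]) +
            log(nmat[ch[i] + 1, s[i]])
        if (lp > best) { best <- lp; bestPath <- s }
      }
      # reconstruct the per-photon states from the decoded segments
      dec <- findInterval(t, sp@boundaries, rightmost.closed = TRUE)
      expect_equal(sp@states[dec], bestPath)
    }
  })
})

test_that("Viterbi finds the switch and visits the intermediate", {
  # 3 donor photons then 3 acceptor photons at well-separated rates
  m <- bindingModel2(5, 5, c(100, 5, 5, 100) * 1e3,
                     pIni = c(0.5, 0.5), pFin = c(1, 1))
  t <- c(1, 2, 3, 4, 5, 6) * 1e-4
  tr <- photonTrace(t, c(0L, 0L, 0L, 1L, 1L, 1L), duration = 7e-4)
  sp <- viterbiDecode(tr, m)
  expect_equal(sp@states, c(1L, 2L))
  expect_gt(sp@boundaries[2], t[3])
  expect_lt(sp@boundaries[2], t[4])
  # one-state model: constant path
  m1 <- kineticModel(matrix(0, 1, 1), nD = 1e5, nA = 1e5, pIni = 1, pFin = 1)
  expect_equal(viterbiDecode(tr, m1)@states, 1L)
  # window with a 200-us intermediate dwell: decoded path visits I
  withr::with_seed(53, {
    w <- stdWindow(tTP = 200e-6)
    cal <- stdCalibration()
    m3 <- bindingModel3(100, 100, tauI = 200e-6, rates = stdRates(),
                        EI = 0.72, EB = cal@EBMean,
                        pIni = c(1, 0, 0), pFin = c(0, 0, 1))
    sp3 <- viterbiDecode(w@photons, m3)
    expect_true(all(c(1L, 2L, 3L) %in% sp3@states))
    ord <- sp3@states[c(1, length(sp3@states))]
    expect_equal(ord, c(1L, 3L))  # starts unbound, ends bound
  })
})
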