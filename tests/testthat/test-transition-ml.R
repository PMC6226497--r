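# Delta lnL surfaces, pooling, per-transition estimates, bootstrap,
# deletion control.

test_that("the surface vanishes uniformly in E as tauI -> 0", {
  withr::with_seed(71, {
    for (i in 1:3) {
      w <- simulateTransitionWindow(simulationConfig(nTransitions = 1))
      s <- deltaLnLSurface(w, stdCalibration(), tauGrid = 1e-9,
                           eGrid = defaultEGrid(by = 0.1))
      expect_lt(max(abs(s@deltaLnL)), 0.01)
    }
  })
})

test_that("surface lnL values agree with the reference propagator", {
  # small synthetic window evaluated at a handful of grid points
  withr::with_seed(72, {
    t <- sort(runif(20, 0, 2e-3))
    ch <- sample(0:1, 20, TRUE)
    tau <- c(0, diff(t))
    tail <- 2.1e-3 - t[20]
    r <- stdRates()
    EB <- 0.83
    res <- tpfret:::cpp_delta_surface(tau, as.integer(ch), tail, r, EB,
                                      c(1e-6, 8e-5), c(0.3, 0.72),
                                      0.1, 0.2)
    tr <- photonTrace(t, ch, duration = 2.1e-3)
    m2 <- bindingModel2(0.1, 0.1, r, pIni = c(1, 0), pFin = c(0, 1))
    l2 <- refLogLik(tr, m2)
    expect_equal(res$lnL2, l2, tolerance = 1e-8)
    for (it in 1:2) for (ie in 1:2) {
      m3 <- bindingModel3(0.2, 0.2, tauI = c(1e-6, 8e-5)[it], rates = r,
                          EI = c(0.3, 0.72)[ie], EB = EB,
                          pIni = c(1, 0, 0), pFin = c(0, 0, 1))
      expect_lt(abs(res$delta[it, ie] - (refLogLik(tr, m3) - l2)), 1e-6)
    }
  })
})

test_that("pooling is linear and order-invariant", {
  withr::with_seed(73, {
    cfg <- simulationConfig(nTransitions = 3)
    coh <- simulateTransitionCohort(cfg)
    tg <- defaultTauGrid(n = 21)
    eg <- seq(0.4, 0.9, 0.1)
    ss <- lapply(coh$windows, function(w)
      deltaLnLSurface(w, calibrateWindow(w), tauGrid = tg, eGrid = eg))
    p1 <- poolSurfaces(ss)
    expect_equal(p1@nPooled, 3L)
    # doubling
    p2 <- poolSurfaces(list(ss[[1]], ss[[1]]))
    expect_equal(p2@deltaLnL, 2 * ss[[1]]@deltaLnL)
    expect_equal(p2@tauHat, ss[[1]]@tauHat)
    expect_equal(p2@eHat, ss[[1]]@eHat)
    # order invariance
    p3 <- poolSurfaces(rev(ss))
    expect_equal(p3@deltaLnL, p1@deltaLnL)
    expect_equal(p3@tauHat, p1@tauHat)
    # grid mismatch
    s2 <- deltaLnLSurface(coh$windows[[1]], calibrateWindow(coh$windows[[1]]),
                          tauGrid = defaultTauGrid(n = 11), eGrid = eg)
    expect_error(poolSurfaces(list(ss[[1]], s2)), "common grid")
  })
})

test_that("a well-resolved intermediate is found per transition", {
  withr::with_seed(74, {
    cfg <- simulationConfig(nTransitions = 1, windowLength = 8e-3,
                            tptLaw = list(type = "delta", value = 200e-6))
    w <- simulateTransitionWindow(cfg)
    fit <- perTransitionMLE(w, eHat = 0.72, calib = calibrateWindow(w))
    expect_true(fit$hasMaximum)
    expect_gt(fit$tauHatJ, 100e-6)
    expect_lt(fit$tauHatJ, 400e-6)
  })
})

test_that("an instantaneous transition lands in the shortest bin", {
  withr::with_seed(75, {
    # low count rate + zero-lifetime transitions: most windows cannot
    # resolve any intermediate
    cfg <- simulationConfig(nTransitions = 20, windowLength = 14e-3,
                            rates = c(81, 9, 14, 76) * 1e3,  # ~90/ms
                            tptLaw = list(type = "delta", value = 0))
    coh <- simulateTransitionCohort(cfg)
    tg <- defaultTauGrid(n = 31)
    fits <- do.call(rbind, lapply(coh$windows, function(w)
      perTransitionMLE(w, 0.72, calibrateWindow(w), tauGrid = tg)))
    expect_gt(sum(!fits$hasMaximum), 0)
    expect_true(all(fits$tauHatJ[!fits$hasMaximum] == tg[1]))
    expect_gt(mean(fits$tauHatJ < 1e-6), 0.3)   # sub-us artifact pile-up
  })
})

test_that("higher count rates suppress the sub-microsecond artifacts", {
  withr::with_seed(76, {
    frac_nomax <- function(rateScale, n = 40) {
      cfg <- simulationConfig(nTransitions = n,
                              windowLength = max(6e-3 / rateScale, 3e-3),
                              rates = stdRates() * rateScale,
                              tptLaw = list(type = "exponential",
                                            mean = 80e-6))
      coh <- simulateTransitionCohort(cfg)
      fits <- do.call(rbind, lapply(coh$windows, function(w)
        perTransitionMLE(w, 0.72, calibrateWindow(w),
                         tauGrid = defaultTauGrid(n = 31))))
      mean(fits$tauHatJ < 1e-6)   # artifact fraction below 1 us
    }
    expect_lt(frac_nomax(2), frac_nomax(0.5))
  })
})

test_that("bootstrap errors are deterministic and vanish for identical surfaces", {
  withr::with_seed(77, {
    w <- simulateTransitionWindow(simulationConfig(nTransitions = 1))
    s <- deltaLnLSurface(w, calibrateWindow(w),
                         tauGrid = defaultTauGrid(n = 21),
                         eGrid = seq(0.5, 0.9, 0.1))
    b1 <- bootstrapSE(list(s, s, s), nTrials = 50, seed = 9)
    expect_equal(b1$seTau, 0)
    expect_equal(b1$seE, 0)
    expect_error(bootstrapSE(list(s), nTrials = 10, seed = 1), "two")
    # determinism
    coh <- stdCohort(n = 6, seed = 771)
    ss <- lapply(coh$windows, function(w)
      deltaLnLSurface(w, calibrateWindow(w),
                      tauGrid = defaultTauGrid(n = 21),
                      eGrid = seq(0.5, 0.9, 0.1)))
    b2 <- bootstrapSE(ss, nTrials = 100, seed = 4)
    b3 <- bootstrapSE(ss, nTrials = 100, seed = 4)
    expect_identical(b2, b3)
    expect_gt(b2$seTau, 0)
  })
})

test_that("deletion of length zero is the identity", {
  withr::with_seed(78, {
    w <- simulateTransitionWindow(simulationConfig(nTransitions = 1))
    cal <- calibrateWindow(w)
    tg <- defaultTauGrid(n = 21)
    eg <- c(0.6, 0.72, 0.85)
    out <- deletionControl(w, c(0, 80e-6), cal, tauGrid = tg, eGrid = eg)
    s0 <- deltaLnLSurface(w, cal, tauGrid = tg, eGrid = eg)
    expect_equal(out[[1]]@deltaLnL, s0@deltaLnL)
    expect_error(deletionControl(w, w@windowLength, cal, tauGrid = tg,
                                 eGrid = eg), "deletion length")
  })
})

test_that("deleting essentially the whole window destroys the evidence", {
  withr::with_seed(79, {
    cfg <- simulationConfig(nTransitions = 6, windowLength = 6e-3,
                            tptLaw = list(type = "delta", value = 80e-6))
    coh <- simulateTransitionCohort(cfg)
    res <- lapply(coh$windows, function(w) {
      t <- arrivalTimes(w)
      keepLen <- t[length(t) - 10] - t[10]  # leave ~10 photons per side
      wDel <- deleteWindowSegment(w, keepLen * 0.999)
      deltaLnLSurface(wDel, calibrateWindow(w),
                      tauGrid = defaultTauGrid(n = 21),
                      eGrid = c(0.6, 0.72, 0.85))
    })
    full <- lapply(coh$windows, function(w)
      deltaLnLSurface(w, calibrateWindow(w),
                      tauGrid = defaultTauGrid(n = 21),
                      eGrid = c(0.6, 0.72, 0.85)))
    # after deletion, any surviving maxima are noise-level and the pooled
    # evidence collapses relative to the intact windows
    delMax <- max(poolSurfaces(res)@deltaLnL)
    expect_lt(delMax, 1)
    expect_gt(max(poolSurfaces(full)@deltaLnL), 5 * delMax)
    expect_true(all(vapply(res, function(s) max(s@deltaLnL), 0) < 1))
  })
})

test_that("pooled peak height grows with the number of pooled transitions", {
  coh <- stdCohort(n = 40, seed = 402)
  cached("mono_profiles", {
    tg <- defaultTauGrid(n = 31)
    vapply(coh$windows, function(w) {
      s <- deltaLnLSurface(w, calibrateWindow(w), tauGrid = tg,
                           eGrid = 0.72)
      s@deltaLnL[, 1]
    }, numeric(31))
  })
  prof <- cached("mono_profiles", NULL)
  peak <- function(k) max(rowSums(prof[, 1:k, drop = FALSE]))
  expect_lt(peak(10), peak(20))
  expect_lt(peak(20), peak(40))
})
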