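# FRET calibration, blinking detection and window selection.

test_that("background correction subtracts and clamps", {
  expect_equal(as.numeric(backgroundCorrect(c(200, 105), c(0, 5))),
               c(200, 100))
  expect_equal(as.numeric(backgroundCorrect(c(200, 105), c(0, 0))),
               c(200, 105))
  expect_warning(out <- backgroundCorrect(c(200, 3), c(0, 5)), "clamped")
  expect_equal(as.numeric(out), c(200, 0))
  expect_equal(attr(out, "clamped"), c(FALSE, TRUE))
})

test_that("crosstalk and gamma follow the calibration identities", {
  expect_equal(estimateCrosstalkBeta(c(100, 5)), 0.05)
  expect_equal(estimateCrosstalkBeta(c(100, 0)), 0)
  expect_error(estimateCrosstalkBeta(c(0, 100)), "positive")
  expect_equal(estimateGamma(c(100, 5), c(20, 80), 0.05), 79 / 80)
  expect_error(estimateGamma(c(100, 5), c(100, 80), 0.05), "contrast")
})

test_that("transfer efficiency reproduces the corrected-rate algebra", {
  cal <- fretCalibration(betaDA = 0.05, gamma = 79 / 80)
  expect_equal(transferEfficiency(c(20, 80), cal), 79 / 98.75)
  # unbound state with beta from its own rates gives exactly 0
  calU <- fretCalibration(betaDA = estimateCrosstalkBeta(c(100, 5)), gamma = 1)
  expect_equal(transferEfficiency(c(100, 5), calU), 0)
  cal1 <- fretCalibration(betaDA = 0, gamma = 1)
  expect_equal(transferEfficiency(c(50, 50), cal1), 0.5)
  expect_error(transferEfficiency(c(0, 0), cal1), "undefined")
})

test_that("gamma correction equalizes total corrected signal in both states", {
  withr::with_seed(61, {
    for (i in 1:20) {
      nU <- c(runif(1, 100, 400), 0)
      nU[2] <- nU[1] * runif(1, 0.02, 0.2)   # crosstalk
      gam <- runif(1, 0.5, 1.5)
      EBtrue <- runif(1, 0.6, 0.95)
      # construct bound-state rates with known gamma and efficiency
      beta <- nU[2] / nU[1]
      tot <- nU[1]                           # donor-scale total
      nDB <- tot * (1 - EBtrue)
      nAB <- gam * tot * EBtrue + beta * nDB
      beta2 <- estimateCrosstalkBeta(nU)
      g2 <- estimateGamma(nU, c(nDB, nAB), beta2)
      expect_equal(g2, gam, tolerance = 1e-10)
      totU <- nU[2] - beta2 * nU[1] + g2 * nU[1]
      totB <- nAB - beta2 * nDB + g2 * nDB
      expect_equal(totU, totB, tolerance = 1e-9)
      cal <- fretCalibration(betaDA = beta2, gamma = g2)
      expect_equal(transferEfficiency(c(nDB, nAB), cal), EBtrue,
                   tolerance = 1e-10)
    }
  })
})

test_that("windows calibrated from simulated rates recover the crosstalk", {
  withr::with_seed(62, {
    cfg <- simulationConfig(nTransitions = 1)
    w <- simulateTransitionWindow(cfg)
    cal <- calibrateWindow(w)
    beta0 <- 20 / 180
    expect_lt(abs(cal@betaDA - beta0), 0.03)     # counting error
    expect_lt(abs(cal@EBMean - tpfret:::.apparentEB(stdRates())), 0.05)
  })
})

test_that("improbably long gaps are flagged as blinking", {
  # gap of 0.1 ms at 100 photons/ms: tail e^-10 ~ 4.5e-5 < 0.01
  t <- c(seq(0, 0.5e-3, by = 1e-5), 0.61e-3 + seq(0, 0.5e-3, by = 1e-5))
  ev <- detectBlinking(t, rep(0L, length(t)), state = "U",
                       familywise = FALSE)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$channel, "donor")
  expect_lt(ev$probability, 0.01)
  # empty input
  expect_equal(nrow(detectBlinking(numeric(0), integer(0))), 0)
})

test_that("family-wise blinking threshold controls the false-flag rate", {
  withr::with_seed(63, {
    nFlagged <- 0
    nTraces <- 800
    for (i in seq_len(nTraces)) {
      t <- cumsum(rexp(400, 2e5))
      ev <- detectBlinking(t, rep(0L, 400), state = "U")
      if (nrow(ev) > 0) nFlagged <- nFlagged + 1
    }
    rate <- nFlagged / nTraces
    expect_gt(rate, 0.002)
    expect_lt(rate, 0.025)  # ~1% per trace by construction
  })
})

test_that("channel changepoint locates the composition switch", {
  withr::with_seed(64, {
    ch <- c(rbinom(500, 1, 0.1), rbinom(500, 1, 0.85))
    t <- sort(runif(1000, 0, 5e-3))
    cp <- channelChangepoint(t, as.integer(ch))
    expect_lt(abs(cp$index - 500), 20)
    expect_gt(cp$logLikGain, 100)
  })
})

test_that("clean simulated traces yield valid windows with accurate rates", {
  withr::with_seed(65, {
    cfg <- simulationConfig(nTransitions = 1, windowLength = 8e-3)
    w0 <- simulateTransitionWindow(cfg, guard = 250e-6)
    # re-run selection from the raw photon stream
    tr <- w0@photons
    sel <- selectWindow(tr, transitionGuess = w0@transitionGuess)
    expect_s4_class(sel, "TransitionWindow")
    expect_gte(nPhotons(sel), 1000)
    expect_gte(sel@windowLength, 1e-3)
    expect_lt(abs(sum(sel@preRates) - 200e3) / 200e3, 0.1)
    expect_lt(abs(sum(sel@postRates) - 200e3) / 200e3, 0.1)
    expect_lt(abs(sel@preRates[2] / sum(sel@preRates) - 0.1), 0.05)
    expect_gt(sel@postRates[2] / sum(sel@postRates), 0.75)
  })
})

test_that("blink near the transition rejects the trace", {
  withr::with_seed(66, {
    cfg <- simulationConfig(nTransitions = 1, windowLength = 8e-3)
    w0 <- simulateTransitionWindow(cfg)
    t <- arrivalTimes(w0)
    ch <- w0@photons@channels
    tc <- w0@transitionGuess
    # carve a 0.6-ms silent gap starting 0.5 ms after the transition
    keep <- !(t > tc + 5e-4 & t < tc + 11e-4)
    tr <- photonTrace(t[keep], ch[keep], duration = w0@photons@duration)
    sel <- selectWindow(tr, transitionGuess = tc)
    expect_s3_class(sel, "tpfretWindowRejection")
    expect_equal(rejectionReason(sel), "blink_proximity")
  })
})

test_that("too few photons rejects the trace", {
  withr::with_seed(67, {
    cfg <- simulationConfig(nTransitions = 1, windowLength = 6e-3)
    w0 <- simulateTransitionWindow(cfg)
    t <- arrivalTimes(w0)
    ch <- w0@photons@channels
    keep <- seq_along(t) %% 3 == 0   # thin to ~1/3 of the photons (~400)
    tr <- photonTrace(t[keep], ch[keep], duration = w0@photons@duration)
    sel <- selectWindow(tr, transitionGuess = w0@transitionGuess)
    expect_s3_class(sel, "tpfretWindowRejection")
    expect_equal(rejectionReason(sel), "too_few_photons")
  })
})

test_that("a second transition in a flank rejects the trace", {
  withr::with_seed(68, {
    cfg <- simulationConfig(nTransitions = 1, windowLength = 8e-3)
    w0 <- simulateTransitionWindow(cfg)
    t <- arrivalTimes(w0)
    ch <- w0@photons@channels
    tc <- w0@transitionGuess
    # mild composition flip (bound -> 50/50) inside the bound flank:
    # detectable as a changepoint but with no silent gap in either channel
    mid <- t > tc + 2e-3 & t < tc + 3.5e-3
    ch[mid] <- rbinom(sum(mid), 1, 0.4)
    tr <- photonTrace(t, as.integer(ch), duration = w0@photons@duration)
    sel <- selectWindow(tr, transitionGuess = tc)
    expect_s3_class(sel, "tpfretWindowRejection")
    expect_equal(rejectionReason(sel), "second_transition")
  })
})

test_that("selected windows always satisfy the type invariants", {
  withr::with_seed(69, {
    for (i in 1:10) {
      cfg <- simulationConfig(
        nTransitions = 1,
        windowLength = runif(1, 5e-3, 12e-3),
        tptLaw = list(type = "exponential", mean = runif(1, 2e-5, 3e-4)))
      w0 <- simulateTransitionWindow(cfg)
      sel <- selectWindow(w0@photons, transitionGuess = w0@transitionGuess)
      if (inherits(sel, "tpfretWindowRejection")) next
      expect_true(validObject(sel, test = TRUE) == TRUE ||
                    isTRUE(validObject(sel, test = TRUE)))
      expect_gte(nPhotons(sel), 1000)
      expect_gte(sel@windowLength, 1e-3)
      expect_true(sel@transitionGuess >= 0 &&
                    sel@transitionGuess <= sel@windowLength)
    }
  })
})
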