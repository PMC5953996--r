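test_that("Renkin-Crone forward relation evaluates and behaves", {
  rc <- renkinCroneForward(1.0)
  expect_equal(rc$k1, 1 - 0.874 * exp(-0.443), tolerance = 1e-12)
  expect_equal(rc$k1, 0.4388, tolerance = 1e-4)
  expect_equal(renkinCroneForward(3.0)$k1, 0.7377, tolerance = 1e-3)

  # E -> 1 as flow -> 0+ (everything extracted at low flow)
  expect_equal(renkinCroneForward(1e-4)$e, 1, tolerance = 1e-9)

  grid <- seq(0.05, 10, length.out = 400)
  k1s <- renkinCroneForward(grid)$k1
  es <- renkinCroneForward(grid)$e
  expect_true(all(diff(k1s) > 0)) # invertibility
  expect_true(all(diff(es) < 0)) # flow-dependent extraction
  expect_error(renkinCroneForward(0), "positive")
  expect_error(renkinCroneForward(-1), "positive")
})

test_that("Renkin-Crone inversion is the exact inverse", {
  expect_equal(renkinCroneInvert(0.4387983), 1.0, tolerance = 1e-4)
  expect_equal(renkinCroneInvert(1e-6), 0, tolerance = 1e-4)
  ms <- seq(0.2, 6, length.out = 50)
  back <- renkinCroneInvert(renkinCroneForward(ms)$k1)
  expect_true(all(abs(back - ms) < 1e-6))
  expect_error(renkinCroneInvert(2.0), "attainable maximum")
  expect_error(renkinCroneInvert(-0.1), "positive")
})

test_that("spillover estimation recovers known mixing fractions", {
  cfg <- simConfig(seed = 2)
  ca <- aifFunction(cfg)
  sched <- spectSchedule()
  blood <- makeAif(cfg, sched)
  lm <- detectBolusLandmarks(blood)
  win <- c(lm$tArrival, lm$tArrival + 90)

  # simulator ground truth, noiseless
  myo <- makeTissueTac(ca, 0.44, 0, sm = 0.3, pv = 1, sched)
  expect_equal(estimateSpillover(myo, blood, win), 0.3, tolerance = 0.02)

  # exact basis member: pure spillover, no uptake
  pure <- TimeActivityCurve(sched, 0.5 * tacValues(blood), "GLOBAL")
  expect_equal(estimateSpillover(pure, blood, win), 0.5, tolerance = 1e-9)

  # no signal at all
  zero <- TimeActivityCurve(sched, rep(0, 32), "GLOBAL")
  expect_equal(estimateSpillover(zero, blood, win), 0)

  # constant blood curve cannot separate spillover from uptake
  flat <- TimeActivityCurve(sched, rep(3, 32), "BLOOD")
  flatMyo <- TimeActivityCurve(sched, rep(1, 32), "GLOBAL")
  expect_error(estimateSpillover(flatMyo, flat, win), "degenerate")
})

test_that("retention rate reproduces the rectangle hand integral exactly", {
  fx <- rectangleRetentionFixture()
  res <- retentionRate(fx$myo, fx$blood, retentionParams(sm = 0))
  # numerator 0.6 kBq/mL, denominator 1.5 kBq/mL x min
  expect_equal(res$r, 0.4, tolerance = 1e-12)
  expect_equal(res$t0, 3)
  expect_equal(res$t3, 153)
})

test_that("pure spillover yields zero retention", {
  cfg <- simConfig()
  sched <- spectSchedule()
  blood <- makeAif(cfg, sched)
  myo <- TimeActivityCurve(sched, 0.4 * tacValues(blood), "GLOBAL")
  # the corrected tissue activity is ~0 up to rounding; a tiny negative
  # numerator is clamped with a warning
  res <- withCallingHandlers(
    retentionRate(myo, blood, retentionParams(sm = 0.4)),
    warning = function(w) {
      expect_match(conditionMessage(w), "clamping")
      invokeRestart("muffleWarning")
    }
  )
  expect_equal(res$r, 0, tolerance = 1e-10)
})

test_that("retention rate is invariant to common rescaling of both TACs", {
  cfg <- simConfig(seed = 3)
  ca <- aifFunction(cfg)
  sched <- spectSchedule()
  blood <- makeAif(cfg, sched)
  myo <- makeTissueTac(ca, 0.5, 0, sm = 0.25, pv = 1, sched)
  r1 <- retentionRate(myo, blood)$r
  scale <- 7.3
  bloodS <- TimeActivityCurve(sched, scale * tacValues(blood), "BLOOD")
  myoS <- TimeActivityCurve(sched, scale * tacValues(myo), "GLOBAL")
  r2 <- retentionRate(myoS, bloodS)$r
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("retention rate recovers simulated uptake within 2%", {
  cfg <- simConfig(seed = 4)
  ca <- aifFunction(cfg)
  sched <- spectSchedule()
  blood <- makeAif(cfg, sched)
  k1 <- 0.45
  myo <- makeTissueTac(ca, k1, 0, sm = 0.3, pv = 1, sched)
  res <- retentionRate(myo, blood)
  expect_equal(res$r, k1, tolerance = 0.02)
  expect_equal(res$sm, 0.3, tolerance = 0.02)
})

test_that("retention errors name their cause", {
  sched <- uniformSchedule(10, 10) # 100 s: too short for t3 = t0 + 150
  v <- c(0, 10, 5, rep(0.2, 7))
  blood <- TimeActivityCurve(sched, v, "BLOOD")
  myo <- TimeActivityCurve(sched, rep(1, 10), "GLOBAL")
  expect_error(retentionRate(myo, blood), "does not cover")
})

test_that("quantifySpect ties the pipeline together per region", {
  study <- simulateStudy(simConfig(seed = 6, nPatients = 1))
  pat <- study$patients[[1]]

  # stress = rest implies MFR 1 everywhere
  same <- quantifySpect(pat$spect$rest, pat$spect$rest)
  expect_equal(same$mfr, rep(1, 4))
  expect_setequal(same$region, c("GLOBAL", "LAD", "LCX", "RCA"))

  # true flows are recovered and MFR matches the simulator oracle
  q <- quantifySpect(pat$spect$rest, pat$spect$stress)
  tr <- study$truth
  for (terr in c("LAD", "LCX", "RCA")) {
    row <- q[q$region == terr, ]
    truth <- tr[tr$territory == terr, ]
    expect_equal(row$rest_mbf, truth$true_rest_mbf, tolerance = 0.02)
    expect_equal(row$mfr, truth$true_mfr, tolerance = 0.04)
  }

  expect_error(quantifySpect(pat$spect$rest, NULL), "stress")
  noBlood <- pat$spect$stress[c("global", "lad", "lcx", "rca")]
  expect_error(quantifySpect(pat$spect$rest, noBlood), "blood")
})
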