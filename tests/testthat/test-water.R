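test_that("water model prediction honors its limiting cases", {
  cfg <- simConfig()
  sched <- petSchedule()
  aif <- makeAif(cfg, sched)

  # minimal flow, no blood volume: nearly no signal
  lo <- waterModelPredict(aif, mbf = 0.1, ptf = 0.3, va = 0)
  expect_lt(max(tacValues(lo)), 0.15 * max(tacValues(aif)))

  # pure blood volume: prediction reproduces the input function
  bv <- waterModelPredict(aif, mbf = 0.1, ptf = 0, va = 1)
  expect_equal(tacValues(bv), tacValues(aif), tolerance = 0.02)

  # pointwise monotone in va wherever the input is positive
  p1 <- waterModelPredict(aif, 2, 0.8, va = 0.1)
  p2 <- waterModelPredict(aif, 2, 0.8, va = 0.3)
  pos <- tacValues(aif) > 0
  expect_true(all(tacValues(p2)[pos] >= tacValues(p1)[pos]))
})

test_that("water prediction matches the closed-form convolution", {
  lambda <- 1.2 # 1/min
  mbf <- 2.0
  p <- 0.91
  k2 <- mbf / p
  sched <- petSchedule()
  mid <- frameMidtimes(sched)
  # an exactly-known AIF: exponential in minutes, sampled as frame averages
  avg <- sapply(seq_len(nFrames(sched)), function(i) {
    a <- frameStart(sched)[i] / 60
    b <- a + frameDuration(sched)[i] / 60
    (exp(-lambda * a) - exp(-lambda * b)) / (lambda * (b - a))
  })
  aif <- TimeActivityCurve(sched, avg, "BLOOD")
  pred <- waterModelPredict(aif, mbf, ptf = 1, va = 0, p = p)
  closed <- function(t) {
    tm <- t / 60
    mbf * (exp(-lambda * tm) - exp(-k2 * tm)) / (k2 - lambda)
  }
  expected <- sapply(seq_len(nFrames(sched)), function(i) {
    a <- frameStart(sched)[i]
    b <- a + frameDuration(sched)[i]
    riemannIntegral(closed, a, b, n = 2000) * 60 / (b - a)
  })
  expect_equal(tacValues(pred), expected, tolerance = 5e-3)
})

test_that("water fit recovers model-consistent parameters to tolerance", {
  cfg <- simConfig()
  sched <- petSchedule()
  aif <- makeAif(cfg, sched)
  myo <- waterModelPredict(aif, mbf = 2.5, ptf = 0.9, va = 0.1)
  fit <- fitWaterModel(myo, aif)
  expect_true(fit$converged)
  expect_equal(fit$mbf, 2.5, tolerance = 1e-3)
  expect_equal(fit$ptf, 0.9, tolerance = 1e-3)
  expect_equal(fit$va, 0.1, tolerance = 1e-3)
  expect_lt(fit$residualRms, 1e-6)
})

test_that("water fit recovers simulated flows from the continuous truth", {
  cfg <- simConfig()
  ca <- aifFunction(cfg)
  sched <- petSchedule()
  aif <- makeAif(cfg, sched)
  myo <- makeTissueTac(ca, 2.5, 2.5 / 0.91, sm = 0.3, pv = 1, sched)
  fit <- fitWaterModel(myo, aif)
  expect_true(fit$converged)
  expect_equal(fit$mbf, 2.5, tolerance = 0.02)
})

test_that("fit residual never exceeds any multistart's residual", {
  cfg <- simConfig(seed = 8)
  sched <- petSchedule()
  aif <- makeAif(cfg, sched)
  myo <- makeTissueTac(aifFunction(cfg), 1.5, 1.5 / 0.91,
    sm = 0.2, pv = 0.9,
    schedule = sched
  )
  myo <- addNoise(myo, noiseScaleFor(myo, 0.05), seed = 21)
  params <- waterModelParams()
  fit <- fitWaterModel(myo, aif, params)
  obs <- tacValues(myo)
  for (i in 1:3) {
    st <- params@starts[i, ]
    pred <- waterModelPredict(aif, st[1], st[2], st[3], p = params@p)
    sseStart <- sum((tacValues(pred) - obs)^2)
    expect_lte(fit$residualRms^2 * length(obs), sseStart + 1e-9)
  }
})

test_that("degenerate myocardial signal pins the fit at the lower bounds", {
  cfg <- simConfig()
  sched <- petSchedule()
  aif <- makeAif(cfg, sched)
  zero <- TimeActivityCurve(sched, rep(0, 24), "GLOBAL")
  fit <- fitWaterModel(zero, aif)
  expect_true(fit$converged)
  expect_equal(fit$mbf, 0.1, tolerance = 1e-6)
  expect_equal(fit$va, 0, tolerance = 1e-6)

  zeroAif <- TimeActivityCurve(sched, rep(0, 24), "BLOOD")
  expect_error(fitWaterModel(zero, zeroAif), "degenerate")
})

test_that("quantifyPet mirrors the SPECT pipeline per region", {
  study <- simulateStudy(simConfig(seed = 9, nPatients = 1))
  pat <- study$patients[[1]]

  same <- quantifyPet(pat$pet$rest, pat$pet$rest)
  expect_equal(same$mfr, rep(1, 4))

  q <- quantifyPet(pat$pet$rest, pat$pet$stress)
  tr <- study$truth
  for (terr in c("LAD", "LCX", "RCA")) {
    row <- q[q$region == terr, ]
    truth <- tr[tr$territory == terr, ]
    expect_equal(row$mfr, truth$true_mfr, tolerance = 0.05)
  }

  broken <- pat$pet$stress
  broken$lcx <- NULL
  expect_error(quantifyPet(pat$pet$rest, broken), "lcx")
})
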