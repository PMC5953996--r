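# Shared in-code fixtures and independent oracles.

# Uniform schedule of n frames x dt seconds.
uniformSchedule <- function(n, dt) FrameSchedule(frameDuration = rep(dt, n))

# Rectangle-function retention fixture on a uniform 2-s grid (80 frames,
# 160 s): blood = 1 kBq/mL on plateau [3, 91] s (arrival midtime t0 = 3 s),
# tissue = 0.6 kBq/mL on plateau [93, 153] s. The piecewise-linear ramps at
# the plateau edges are symmetric about the frame boundaries and lie fully
# inside the integration windows, so the TAC integrals equal the hand
# integrals of the ideal rectangles exactly:
# R = 0.6 / (90 s / 60) = 0.4 / min.
rectangleRetentionFixture <- function() {
  sched <- uniformSchedule(80, 2)
  mid <- frameMidtimes(sched)
  blood <- ifelse(mid >= 3 & mid <= 91, 1, 0)
  myo <- ifelse(mid >= 93 & mid <= 153, 0.6, 0)
  list(
    blood = TimeActivityCurve(sched, blood, "BLOOD"),
    myo = TimeActivityCurve(sched, myo, "GLOBAL")
  )
}

# Mann-Whitney pairwise-concordance AUC oracle for "lower = more abnormal"
# scores: brute-force pair counting with ties counted one half.
mannWhitneyAuc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (p in pos) {
    tot <- tot + sum(p < neg) + 0.5 * sum(p == neg)
  }
  tot / (length(pos) * length(neg))
}

# Fine-grid Riemann integral of a function, in kBq/mL x min.
riemannIntegral <- function(f, a, b, n = 200000) {
  tt <- seq(a, b, length.out = n)
  y <- f(tt)
  sum(diff(tt) * (y[-1] + y[-n]) / 2) / 60
}
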