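#' Flow-dependent extraction: the Renkin-Crone relation
#'
#' For a diffusion-limited tracer such as Tc-99m-sestamibi the unidirectional
#' uptake rate K1 falls short of flow by the first-pass extraction fraction:
#' `K1 = MBF * E(MBF)` with `E(MBF) = 1 - A * exp(-B / MBF)`. With the
#' defaults A = 0.874 and B = 0.443 the relation is strictly increasing in
#' MBF on (0, 10], so it can be inverted uniquely; `renkinCroneInvert()`
#' solves `K1 = MBF * (1 - A * exp(-B / MBF))` for MBF on the bracket
#' `[1e-6, 10]` mL/min/g to absolute tolerance 1e-9.
#'
#' @param mbf myocardial blood flow, mL/min/g (> 0); vectorized.
#' @param k1 uptake rate, mL/min/g (> 0); vectorized.
#' @param A,B Renkin-Crone constants (defaults 0.874, 0.443).
#' @return `renkinCroneForward()`: list with `k1` and extraction `e`
#'   (both vectors); `renkinCroneInvert()`: numeric vector of MBF.
#' @examples
#' renkinCroneForward(1)$k1 # 0.4388
#' renkinCroneInvert(0.4388) # ~1.0
#' @export
renkinCroneForward <- function(mbf, A = 0.874, B = 0.443) {
  if (any(!is.finite(mbf)) || any(mbf <= 0)) {
    stop("mbf must be positive and finite")
  }
  e <- 1 - A * exp(-B / mbf)
  list(k1 = mbf * e, e = e)
}

#' @rdname renkinCroneForward
#' @export
renkinCroneInvert <- function(k1, A = 0.874, B = 0.443) {
  mbfMax <- 10
  k1Max <- renkinCroneForward(mbfMax, A, B)$k1
  vapply(k1, function(k) {
    if (!is.finite(k) || k <= 0) {
      stop("k1 must be positive and finite")
    }
    if (k >= k1Max) {
      stop(
        "k1 = ", signif(k, 6), " exceeds the attainable maximum ",
        signif(k1Max, 6), " mL/min/g at MBF = ", mbfMax, " mL/min/g"
      )
    }
    stats::uniroot(
      function(m) renkinCroneForward(m, A, B)$k1 - k,
      interval = c(1e-6, mbfMax), tol = 1e-9
    )$root
  }, numeric(1))
}

#' Estimate blood-to-myocardium spillover
#'
#' Fits the early (blood-pool phase) myocardial signal as a linear
#' combination of the blood curve and its running integral,
#' `P(t) ~ sm * Ca(t) + k * integral_0^t Ca`, by ordinary least squares over
#' the frames whose midtimes fall inside `window`; the coefficient on
#' `Ca(t)` is the spillover fraction, clamped to [0, 1]. During the bolus
#' the tissue compartment is still nearly empty, so the spillover term
#' dominates the fit.
#'
#' @param myo myocardial [TimeActivityCurve-class].
#' @param blood blood-pool [TimeActivityCurve-class] on the same schedule.
#' @param window numeric length-2, seconds: typically
#'   `c(tArrival, tArrival + t1Offset)`.
#' @return estimated spillover fraction `sm` in [0, 1].
#' @examples
#' cfg <- simConfig()
#' sched <- spectSchedule()
#' blood <- makeAif(cfg, sched)
#' myo <- makeTissueTac(aifFunction(cfg), 0.4, 0, sm = 0.3, pv = 1, sched)
#' lm <- detectBolusLandmarks(blood)
#' estimateSpillover(myo, blood, c(lm$tArrival, lm$tArrival + 90))
#' @export
estimateSpillover <- function(myo, blood, window) {
  stopifnot(
    is(myo, "TimeActivityCurve"), is(blood, "TimeActivityCurve"),
    length(window) == 2L, window[1] < window[2]
  )
  sched <- blood@schedule
  tEnd <- totalDuration(sched)
  if (window[1] < sched@frameStart[1L] - 1e-9 || window[2] > tEnd + 1e-9) {
    stop("spillover window must lie inside the acquisition")
  }
  mid <- frameMidtimes(sched)
  idx <- which(mid >= window[1] & mid <= window[2])
  if (length(idx) < 2L) {
    stop("spillover window covers fewer than 2 frames")
  }
  caw <- blood@values[idx]
  if (stats::sd(caw) <= 1e-10 * max(abs(caw), 1e-300)) {
    stop(
      "degenerate blood curve in the spillover window (no bolus dynamics); ",
      "supply sm manually via retentionParams(sm = ...)"
    )
  }
  cumInt <- vapply(
    mid[idx],
    function(tt) {
      if (tt <= sched@frameStart[1L]) 0 else
        integrateTac(blood, sched@frameStart[1L], tt)
    },
    numeric(1)
  )
  X <- cbind(ca = caw, cum = cumInt)
  if (qr(X)$rank < 2L) {
    stop(
      "degenerate blood curve in the spillover window; ",
      "supply sm manually via retentionParams(sm = ...)"
    )
  }
  beta <- stats::lsfit(X, myo@values[idx], intercept = FALSE)$coefficients
  min(max(beta[["ca"]], 0), 1)
}

#' Net-retention rate of a myocardial region
#'
#' The net-retention estimator for trapped tracers: the late, spillover- and
#' partial-volume-corrected tissue activity is ratioed to the integrated
#' arterial input over the bolus phase,
#' \deqn{R = \frac{\frac{1}{PV (t_3 - t_2)} \int_{t_2}^{t_3} P(t) - S_m
#'   C_a(t)\, dt}{CF \int_{0}^{t_1} C_a(t) - S_b P(t)\, dt},}
#' all times in minutes, so R has units 1/min. The upper limits are anchored
#' at the bolus (t0 = arrival or peak per `params@anchor`):
#' `t1 = t0 + t1Offset`, `t2 = t0 + t2Offset`, `t3 = t0 + t3Offset`; the
#' input integral starts at acquisition start so the bolus rising edge is
#' fully counted.
#' Under trapping kinetics R equals the uptake rate K1, and
#' `MBF = renkinCroneInvert(R)`.
#'
#' A negative numerator (possible in noisy data) clamps R to 0 with a
#' warning; a non-positive denominator (no usable bolus) is an error.
#'
#' @param myo,blood myocardial and blood-pool [TimeActivityCurve-class]
#'   objects on a shared schedule.
#' @param params a [RetentionParams-class]; if `params@sm` is `NA` the
#'   spillover is estimated from the blood-pool phase.
#' @return list: `r` (1/min), `sm` used, `t0`, `t1`, `t2`, `t3` (seconds).
#' @export
retentionRate <- function(myo, blood, params = retentionParams()) {
  stopifnot(
    is(myo, "TimeActivityCurve"), is(blood, "TimeActivityCurve"),
    is(params, "RetentionParams")
  )
  lmks <- detectBolusLandmarks(blood)
  t0 <- if (params@anchor == "arrival") lmks$tArrival else lmks$tPeak
  t1 <- t0 + params@t1Offset
  t2 <- t0 + params@t2Offset
  t3 <- t0 + params@t3Offset
  tEnd <- totalDuration(blood@schedule)
  if (t3 > tEnd + 1e-9) {
    stop(
      "acquisition (", tEnd, " s) does not cover the tissue window ending ",
      t3, " s; bolus anchor at ", t0, " s"
    )
  }
  sm <- params@sm
  if (is.na(sm)) {
    sm <- estimateSpillover(myo, blood, c(t0, t1))
  }
  # denominator: integrated arterial input over the whole bolus phase, from
  # acquisition start to t1 (the anchor shifts t1, not the lower limit, so
  # the rising edge of the bolus is fully counted), minutes
  tStart <- blood@schedule@frameStart[1L]
  den <- params@cf *
    (integrateTac(blood, tStart, t1) -
      params@sb * integrateTac(myo, tStart, t1))
  if (den <= 0) {
    stop("non-positive input integral over [", t0, ", ", t1, "] s: no usable bolus")
  }
  # numerator: mean late tissue activity, spillover- and PV-corrected
  num <- (integrateTac(myo, t2, t3) - sm * integrateTac(blood, t2, t3)) /
    (params@pv * ((t3 - t2) / 60))
  if (num < 0) {
    warning("negative spillover-corrected tissue activity; clamping R to 0")
    num <- 0
  }
  list(r = num / den, sm = sm, t0 = t0, t1 = t1, t2 = t2, t3 = t3)
}

# region keys of a TAC set as written/read by the I/O layer
.regionKeys <- c(GLOBAL = "global", LAD = "lad", LCX = "lcx", RCA = "rca")

.checkTacSet <- function(tacs, state) {
  need <- c("blood", unname(.regionKeys))
  miss <- setdiff(need, names(tacs))
  if (length(miss) > 0) {
    stop(
      "TAC set for state '", state, "' is missing region(s): ",
      paste(miss, collapse = ", ")
    )
  }
}

#' Quantify MBF and MFR from a dynamic sestamibi SPECT study
#'
#' Runs the full SPECT arm for one patient: for every region (GLOBAL, LAD,
#' LCX, RCA) and state (rest, stress), estimate spillover (unless supplied),
#' compute the net-retention rate R, identify it with the uptake rate K1,
#' invert the Renkin-Crone relation for MBF, and form MFR = stress/rest.
#'
#' @param restTacs,stressTacs named lists of [TimeActivityCurve-class]
#'   objects with elements `blood`, `global`, `lad`, `lcx`, `rca` (as
#'   returned by [readTacFile()] or [simulateStudy()]).
#' @param params a [RetentionParams-class].
#' @return data.frame with one row per region: `region`, `rest_mbf`,
#'   `stress_mbf`, `mfr`, `k1_rest`, `k1_stress`, `sm_rest`, `sm_stress`.
#' @examples
#' study <- simulateStudy(simConfig(seed = 3, nPatients = 1))
#' quantifySpect(study$patients[[1]]$spect$rest, study$patients[[1]]$spect$stress)
#' @export
quantifySpect <- function(restTacs, stressTacs, params = retentionParams()) {
  if (missing(restTacs) || is.null(restTacs)) stop("rest TAC set is missing")
  if (missing(stressTacs) || is.null(stressTacs)) {
    stop("stress TAC set is missing")
  }
  .checkTacSet(restTacs, "rest")
  .checkTacSet(stressTacs, "stress")
  states <- list(rest = restTacs, stress = stressTacs)
  out <- NULL
  for (region in names(.regionKeys)) {
    est <- lapply(names(states), function(state) {
      tacs <- states[[state]]
      res <- tryCatch(
        retentionRate(tacs[[.regionKeys[[region]]]], tacs$blood, params),
        error = function(e) {
          stop(
            "region ", region, ", state ", state, ": ",
            conditionMessage(e)
          )
        }
      )
      mbf <- if (res$r > 0) {
        renkinCroneInvert(res$r, params@renkinA, params@renkinB)
      } else {
        0
      }
      list(k1 = res$r, mbf = mbf, sm = res$sm)
    })
    names(est) <- names(states)
    out <- rbind(out, data.frame(
      region = region,
      rest_mbf = est$rest$mbf, stress_mbf = est$stress$mbf,
      mfr = est$stress$mbf / est$rest$mbf,
      k1_rest = est$rest$k1, k1_stress = est$stress$k1,
      sm_rest = est$rest$sm, sm_stress = est$stress$sm
    ))
  }
  rownames(out) <- NULL
  out
}
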