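#' @import methods
NULL

#' Temporal binning of a dynamic acquisition
#'
#' A `FrameSchedule` describes the frame grid of a dynamic emission
#' acquisition: per-frame start times and durations, in seconds. Frames must
#' be contiguous (each frame starts where the previous one ends),
#' non-overlapping, and strictly positive in duration; at least 4 frames are
#' required.
#'
#' @slot frameStart numeric, frame start times in seconds.
#' @slot frameDuration numeric, frame durations in seconds.
#'
#' @seealso [spectSchedule()], [petSchedule()], [frameMidtimes()],
#'   [totalDuration()]
#' @export
setClass("FrameSchedule",
  representation(frameStart = "numeric", frameDuration = "numeric"),
  validity = function(object) {
    s <- object@frameStart
    d <- object@frameDuration
    if (length(s) != length(d)) {
      return("frameStart and frameDuration must have equal length")
    }
    if (length(s) < 4L) {
      return("a frame schedule needs at least 4 frames")
    }
    if (anyNA(s) || anyNA(d) || any(!is.finite(s)) || any(!is.finite(d))) {
      return("frame times must be finite")
    }
    if (any(d <= 0)) {
      return("all frame durations must be > 0")
    }
    if (length(s) > 1L) {
      gap <- s[-1L] - (s[-length(s)] + d[-length(d)])
      if (any(abs(gap) > 1e-9)) {
        return("frames must be contiguous: start[i+1] = start[i] + duration[i]")
      }
    }
    TRUE
  }
)

#' Construct a frame schedule
#'
#' @param frameStart numeric vector of frame start times (seconds). If
#'   missing, starts are derived from `frameDuration` assuming the
#'   acquisition begins at `t = 0`.
#' @param frameDuration numeric vector of frame durations (seconds).
#'
#' @return A [FrameSchedule-class] object.
#' @examples
#' FrameSchedule(frameDuration = rep(5, 24))
#' @export
FrameSchedule <- function(frameStart, frameDuration) {
  frameDuration <- as.numeric(frameDuration)
  if (missing(frameStart)) {
    frameStart <- if (length(frameDuration) == 0L) {
      numeric(0)
    } else {
      cumsum(c(0, frameDuration[-length(frameDuration)]))
    }
  }
  new("FrameSchedule",
    frameStart = as.numeric(frameStart),
    frameDuration = frameDuration
  )
}

#' Printed dynamic protocols
#'
#' Named constructors for the two acquisition protocols the package targets:
#' the 32-frame dynamic CZT-SPECT rebinning (21 x 3 s, 1 x 9 s, 1 x 15 s,
#' 1 x 21 s, 1 x 27 s, 7 x 30 s; 345 s total) and the 24-frame dynamic
#' water-PET protocol (14 x 5 s, 3 x 10 s, 3 x 20 s, 4 x 30 s; 280 s total).
#'
#' @return A [FrameSchedule-class].
#' @examples
#' totalDuration(spectSchedule()) # 345
#' totalDuration(petSchedule()) # 280
#' @export
spectSchedule <- function() {
  FrameSchedule(frameDuration = c(rep(3, 21), 9, 15, 21, 27, rep(30, 7)))
}

#' @rdname spectSchedule
#' @export
petSchedule <- function() {
  FrameSchedule(frameDuration = c(rep(5, 14), rep(10, 3), rep(20, 3), rep(30, 4)))
}

#' Frame-averaged activity over time for one region
#'
#' A `TimeActivityCurve` (TAC) holds frame-averaged activity concentration
#' (kBq/mL) on a [FrameSchedule-class], for either the blood pool (the
#' arterial input function, sampled from a left-atrial ROI) or a myocardial
#' region (global left ventricle or one coronary territory). Values must be
#' finite and non-negative.
#'
#' @slot schedule a [FrameSchedule-class].
#' @slot values numeric, one activity value per frame, kBq/mL.
#' @slot label region identifier: one of `"BLOOD"`, `"GLOBAL"`, `"LAD"`,
#'   `"LCX"`, `"RCA"`.
#' @export
setClass("TimeActivityCurve",
  representation(
    schedule = "FrameSchedule",
    values = "numeric",
    label = "character"
  ),
  validity = function(object) {
    if (length(object@values) != length(object@schedule@frameDuration)) {
      return("need exactly one value per frame")
    }
    if (anyNA(object@values) || any(!is.finite(object@values))) {
      return("TAC values must be finite")
    }
    if (any(object@values < 0)) {
      return("TAC values must be >= 0 (clamp before construction)")
    }
    if (length(object@label) != 1L ||
      !(object@label %in% c("BLOOD", "GLOBAL", "LAD", "LCX", "RCA"))) {
      return("label must be one of BLOOD, GLOBAL, LAD, LCX, RCA")
    }
    TRUE
  }
)

#' Construct a time-activity curve
#'
#' @param schedule a [FrameSchedule-class].
#' @param values numeric, frame-averaged activity concentration (kBq/mL),
#'   one per frame.
#' @param label region identifier (`"BLOOD"`, `"GLOBAL"`, `"LAD"`, `"LCX"`,
#'   `"RCA"`).
#'
#' @return A [TimeActivityCurve-class].
#' @examples
#' tac <- TimeActivityCurve(petSchedule(), rep(1, 24), "BLOOD")
#' integrateTac(tac, 0, 60)
#' @export
TimeActivityCurve <- function(schedule, values, label = "GLOBAL") {
  new("TimeActivityCurve",
    schedule = schedule,
    values = as.numeric(values),
    label = as.character(label)
  )
}

#' Net-retention model parameters
#'
#' All constants of the net-retention estimator and the Renkin-Crone
#' extraction relation. The retention rate R is
#' \deqn{R = \frac{\frac{1}{PV (t_3 - t_2)} \int_{t_2}^{t_3} P(t) - S_m
#'   C_a(t)\, dt}{CF \int_{0}^{t_1} C_a(t) - S_b P(t)\, dt}}
#' with the upper integration limits anchored at the bolus (either its
#' arrival or its peak frame) and all times in minutes, so R carries units
#' 1/min.
#'
#' @slot pv partial-volume recovery factor on the tissue signal,
#'   dimensionless, in (0, 1.5]; default 1.0. Estimated MBF scales as 1/PV.
#' @slot cf myocardial density correction, fixed at 1.
#' @slot sm blood-to-myocardium spillover fraction; `NA` (the default) means
#'   estimate it from the blood-pool phase via [estimateSpillover()].
#' @slot sb myocardium-to-blood spillover, 0 by default (negligible).
#' @slot t1Offset seconds after the anchor ending the blood-pool (input)
#'   integral; default 90 (1.5 min).
#' @slot t2Offset,t3Offset seconds after the anchor bounding the tissue
#'   integral; defaults 90 and 150 (1.5 to 2.5 min).
#' @slot renkinA,renkinB Renkin-Crone constants of
#'   `K1 = MBF * (1 - A * exp(-B/MBF))`; defaults A = 0.874, B = 0.443
#'   (B in mL/min/g inside the exponent).
#' @slot anchor `"arrival"` (default) anchors t0 at bolus arrival (first
#'   frame above 10% of the blood peak); `"peak"` anchors at the peak frame.
#' @export
setClass("RetentionParams",
  representation(
    pv = "numeric", cf = "numeric", sm = "numeric", sb = "numeric",
    t1Offset = "numeric", t2Offset = "numeric", t3Offset = "numeric",
    renkinA = "numeric", renkinB = "numeric", anchor = "character"
  ),
  prototype(
    pv = 1.0, cf = 1.0, sm = NA_real_, sb = 0.0,
    t1Offset = 90, t2Offset = 90, t3Offset = 150,
    renkinA = 0.874, renkinB = 0.443, anchor = "arrival"
  ),
  validity = function(object) {
    if (object@pv <= 0 || object@pv > 1.5) {
      return("pv must lie in (0, 1.5]")
    }
    if (!is.na(object@sm) && object@sm < 0) {
      return("sm must be >= 0")
    }
    if (object@sb < 0) {
      return("sb must be >= 0")
    }
    if (!(object@t1Offset <= object@t2Offset &&
      object@t2Offset < object@t3Offset)) {
      return("offsets must satisfy t1 <= t2 < t3")
    }
    if (object@renkinA <= 0 || object@renkinA >= 1) {
      return("renkinA must lie in (0, 1)")
    }
    if (object@renkinB <= 0) {
      return("renkinB must be > 0")
    }
    if (!(object@anchor %in% c("arrival", "peak"))) {
      return("anchor must be 'arrival' or 'peak'")
    }
    TRUE
  }
)

#' @param ... slots to override, see [RetentionParams-class].
#' @rdname RetentionParams-class
#' @return `retentionParams()` returns a validated [RetentionParams-class].
#' @examples
#' retentionParams()
#' retentionParams(sm = 0.3, pv = 0.85)
#' @export
retentionParams <- function(...) {
  new("RetentionParams", ...)
}

#' One-tissue-compartment water model parameters
#'
#' Settings for the O-15-water quantifier: the tissue curve is
#' `Ct(t) = MBF * integral Ca(tau) exp(-(MBF/p) (t - tau)) dtau` and the
#' measured myocardial curve is modelled as `PTF * Ct(t) + Va * Ca(t)`,
#' where PTF is the perfusable tissue fraction and Va the arterial blood
#' volume fraction. Water is freely diffusible, so the uptake rate equals
#' MBF and the washout rate is MBF divided by the partition coefficient p.
#'
#' @slot p partition coefficient of water, mL/g; default 0.91.
#' @slot lower,upper numeric length-3 fit bounds, named `mbf`, `ptf`, `va`;
#'   defaults mbf in [0.1, 6] mL/min/g, ptf in [0.3, 1.2] g/mL,
#'   va in [0, 0.5].
#' @slot starts 3 x 3 numeric matrix of fixed multistart initial values
#'   (rows = starts, columns = mbf, ptf, va); fixed rather than random so
#'   fits are deterministic.
#' @export
setClass("WaterModelParams",
  representation(
    p = "numeric", lower = "numeric", upper = "numeric", starts = "matrix"
  ),
  prototype(
    p = 0.91,
    lower = c(mbf = 0.1, ptf = 0.3, va = 0),
    upper = c(mbf = 6, ptf = 1.2, va = 0.5),
    starts = matrix(
      c(
        0.8, 0.8, 0.05,
        2.5, 0.7, 0.10,
        4.5, 0.9, 0.20
      ),
      nrow = 3, byrow = TRUE,
      dimnames = list(NULL, c("mbf", "ptf", "va"))
    )
  ),
  validity = function(object) {
    if (object@p <= 0) {
      return("partition coefficient p must be > 0")
    }
    if (length(object@lower) != 3L || length(object@upper) != 3L) {
      return("lower and upper must have length 3 (mbf, ptf, va)")
    }
    if (any(object@lower >= object@upper)) {
      return("bounds must satisfy lower < upper")
    }
    if (!all(dim(object@starts) == c(3L, 3L))) {
      return("starts must be a 3 x 3 matrix")
    }
    ok <- sweep(object@starts, 2, object@lower, ">=") &
      sweep(object@starts, 2, object@upper, "<=")
    if (!all(ok)) {
      return("all multistart values must lie inside the bounds")
    }
    TRUE
  }
)

#' @param ... slots to override, see [WaterModelParams-class].
#' @rdname WaterModelParams-class
#' @return `waterModelParams()` returns a validated [WaterModelParams-class].
#' @export
waterModelParams <- function(...) {
  new("WaterModelParams", ...)
}

#' Classification thresholds for abnormality
#'
#' Cutoffs used by the concordance layer. Flow measures are abnormal when
#' strictly below their cutoff (PET MFR < 2, CZT-SPECT MFR < 2.1, stress
#' MBF < 2.5 mL/min/g); FFR is abnormal at or below its cutoff (FFR <= 0.8).
#'
#' @slot petMfrCutoff PET MFR cutoff, default 2.0.
#' @slot cztMfrCutoff CZT-SPECT MFR cutoff, default 2.1.
#' @slot stressMbfCutoff stress MBF cutoff, mL/min/g, default 2.5.
#' @slot ffrCutoff FFR cutoff, default 0.8.
#' @export
setClass("FlowThresholds",
  representation(
    petMfrCutoff = "numeric", cztMfrCutoff = "numeric",
    stressMbfCutoff = "numeric", ffrCutoff = "numeric"
  ),
  prototype(
    petMfrCutoff = 2.0, cztMfrCutoff = 2.1,
    stressMbfCutoff = 2.5, ffrCutoff = 0.8
  ),
  validity = function(object) {
    v <- c(
      object@petMfrCutoff, object@cztMfrCutoff,
      object@stressMbfCutoff, object@ffrCutoff
    )
    if (any(v <= 0)) {
      return("all thresholds must be positive")
    }
    if (object@ffrCutoff >= 1) {
      return("ffrCutoff must be < 1")
    }
    TRUE
  }
)

#' @param ... slots to override, see [FlowThresholds-class].
#' @rdname FlowThresholds-class
#' @return `flowThresholds()` returns a validated [FlowThresholds-class].
#' @export
flowThresholds <- function(...) {
  new("FlowThresholds", ...)
}

#' Synthetic cohort configuration
#'
#' Every knob of the synthetic dynamic rest/stress study generator. The
#' defaults emulate the target study design: 30 patients, 3 coronary
#' territories each, with roughly 12/90 territories FFR-abnormal; a tight
#' bolus arterial input with recirculation; trapping (sestamibi) kinetics on
#' the SPECT frame grid and washout (water) kinetics on the PET grid;
#' spillover and partial-volume contamination; optional count-statistics
#' noise.
#'
#' @slot seed integer RNG seed; the whole study is reproducible given it.
#' @slot nPatients number of patients (default 30).
#' @slot aifPeak peak of the continuous arterial input, kBq/mL (default 100).
#' @slot aifTimeToPeak seconds from injection to the bolus peak (default 15).
#' @slot aifAlpha gamma-variate shape (default 3).
#' @slot aifTailFraction recirculation tail amplitude relative to the peak,
#'   in [0, 1) (default 0.10).
#' @slot aifTailHalflife recirculation decay half-life, seconds (default 25).
#'   The default tail is brief because the net-retention estimator assumes
#'   the input is delivered within the bolus phase; persistent recirculation
#'   biases R upward (see the vignette).
#' @slot injectionDelay seconds between acquisition start and injection
#'   (default 5).
#' @slot smTrue blood-to-myocardium spillover fraction in the simulated
#'   measurement model (default 0.3).
#' @slot pvTrue partial-volume recovery factor in (0, 1] (default 1.0).
#' @slot noiseScale noise magnitude, >= 0; 0 disables noise (default 0).
#' @slot prevalenceAbnormalFfr fraction of territories that are diseased
#'   (default 12/90).
#' @slot restMbfMean,restMbfSd resting MBF distribution, mL/min/g
#'   (defaults 1.0 and 0.2).
#' @slot mfrNormalRange,mfrDiseasedRange uniform MFR ranges for normal and
#'   diseased territories (defaults (2.2, 3.8) and (1.0, 1.9)).
#' @slot ffrNormalMean,ffrNormalSd,ffrDiseasedMean,ffrDiseasedSd truncated
#'   normal FFR distributions given disease status (defaults 0.87 +/- 0.06
#'   and 0.72 +/- 0.06, truncated to (0, 1]).
#' @export
setClass("SimConfig",
  representation(
    seed = "integer", nPatients = "integer",
    aifPeak = "numeric", aifTimeToPeak = "numeric", aifAlpha = "numeric",
    aifTailFraction = "numeric", aifTailHalflife = "numeric",
    injectionDelay = "numeric",
    smTrue = "numeric", pvTrue = "numeric", noiseScale = "numeric",
    prevalenceAbnormalFfr = "numeric",
    restMbfMean = "numeric", restMbfSd = "numeric",
    mfrNormalRange = "numeric", mfrDiseasedRange = "numeric",
    ffrNormalMean = "numeric", ffrNormalSd = "numeric",
    ffrDiseasedMean = "numeric", ffrDiseasedSd = "numeric"
  ),
  prototype(
    seed = 1L, nPatients = 30L,
    aifPeak = 100, aifTimeToPeak = 15, aifAlpha = 3,
    aifTailFraction = 0.10, aifTailHalflife = 25,
    injectionDelay = 5,
    smTrue = 0.3, pvTrue = 1.0, noiseScale = 0,
    prevalenceAbnormalFfr = 12 / 90,
    restMbfMean = 1.0, restMbfSd = 0.2,
    mfrNormalRange = c(2.2, 3.8), mfrDiseasedRange = c(1.0, 1.9),
    ffrNormalMean = 0.87, ffrNormalSd = 0.06,
    ffrDiseasedMean = 0.72, ffrDiseasedSd = 0.06
  ),
  validity = function(object) {
    if (object@nPatients < 1L) {
      return("nPatients must be >= 1")
    }
    if (object@aifTimeToPeak <= 0) {
      return("aifTimeToPeak must be > 0")
    }
    if (object@aifTailFraction < 0 || object@aifTailFraction >= 1) {
      return("aifTailFraction must lie in [0, 1)")
    }
    if (object@aifTailHalflife <= 0) {
      return("aifTailHalflife must be > 0")
    }
    if (object@pvTrue <= 0 || object@pvTrue > 1) {
      return("pvTrue must lie in (0, 1]")
    }
    if (object@noiseScale < 0) {
      return("noiseScale must be >= 0")
    }
    if (object@prevalenceAbnormalFfr <= 0 ||
      object@prevalenceAbnormalFfr >= 1) {
      return("prevalenceAbnormalFfr must lie in (0, 1)")
    }
    if (object@restMbfMean <= 0 || object@restMbfSd < 0) {
      return("rest MBF distribution must have positive mean and sd >= 0")
    }
    for (r in list(object@mfrNormalRange, object@mfrDiseasedRange)) {
      if (length(r) != 2L || r[1] <= 0 || r[1] >= r[2]) {
        return("MFR ranges must be ordered positive pairs")
      }
    }
    TRUE
  }
)

#' @param seed integer RNG seed.
#' @param nPatients number of patients.
#' @param ... further slots to override, see [SimConfig-class].
#' @rdname SimConfig-class
#' @return `simConfig()` returns a validated [SimConfig-class].
#' @examples
#' simConfig(seed = 7, nPatients = 5)
#' @export
simConfig <- function(seed = 1L, nPatients = 30L, ...) {
  new("SimConfig",
    seed = as.integer(seed), nPatients = as.integer(nPatients), ...
  )
}
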