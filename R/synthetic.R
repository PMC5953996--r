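#' Continuous arterial input function model
#'
#' Builds the continuous bolus model used by the simulator: a gamma-variate
#' `Ca(t) = peak * ((t - d)/tp)^alpha * exp(alpha * (1 - (t - d)/tp))` for
#' `t > d` (injection delay `d`, time-to-peak `tp`), whose maximum is exactly
#' `peak` at `t = d + tp`, plus a slowly decaying recirculation tail of
#' relative amplitude `aifTailFraction` that switches on at the bolus peak
#' with zero slope (so the continuous maximum stays at `d + tp`) and decays
#' with half-life `aifTailHalflife`.
#'
#' @param config a [SimConfig-class].
#' @return `aifFunction()` returns a vectorized function of time (seconds)
#'   giving kBq/mL; `makeAif()` returns the frame-averaged
#'   [TimeActivityCurve-class] on `schedule` (averaging on a 0.1 s grid).
#' @examples
#' ca <- aifFunction(simConfig())
#' ca(20) # continuous peak: 100 kBq/mL at t = 5 + 15 s
#' @export
aifFunction <- function(config) {
  stopifnot(is(config, "SimConfig"))
  peak <- config@aifPeak
  tp <- config@aifTimeToPeak
  if (tp <= 0) stop("aifTimeToPeak must be > 0")
  alpha <- config@aifAlpha
  d <- config@injectionDelay
  f <- config@aifTailFraction
  thalf <- config@aifTailHalflife
  function(t) {
    u <- (t - d) / tp
    bolus <- ifelse(u > 0, peak * u^alpha * exp(alpha * (1 - u)), 0)
    s <- t - d - tp # time past the bolus peak
    tail <- ifelse(
      s > 0,
      f * peak * (1 - exp(-(s / tp)^2)) * 2^(-s / thalf),
      0
    )
    bolus + tail
  }
}

# Fine time grid (0.1 s) spanning a schedule, plus per-frame node indices.
.fineGrid <- function(schedule, dt = 0.1) {
  t0 <- schedule@frameStart[1L]
  tEnd <- totalDuration(schedule)
  seq(t0, tEnd, by = dt)
}

# Average a fine-grid signal over each frame (trapezoid / duration). Frame
# boundaries must sit on the grid, which holds for integer-second frames.
.frameAverage <- function(schedule, tGrid, yGrid) {
  dt <- tGrid[2L] - tGrid[1L]
  starts <- schedule@frameStart
  ends <- starts + schedule@frameDuration
  vapply(seq_along(starts), function(i) {
    i0 <- round((starts[i] - tGrid[1L]) / dt) + 1L
    i1 <- round((ends[i] - tGrid[1L]) / dt) + 1L
    y <- yGrid[i0:i1]
    sum(diff(tGrid[i0:i1]) * (y[-1L] + y[-length(y)]) / 2) /
      (ends[i] - starts[i])
  }, numeric(1))
}

#' @param schedule a [FrameSchedule-class] on which to frame-average.
#' @rdname aifFunction
#' @export
makeAif <- function(config, schedule) {
  ca <- aifFunction(config)
  tGrid <- .fineGrid(schedule)
  TimeActivityCurve(schedule, .frameAverage(schedule, tGrid, ca(tGrid)),
    label = "BLOOD"
  )
}

# One-tissue impulse-response convolution on a fine grid:
# Ct(t) = k1 * integral_0^t Ca(tau) exp(-k2 (t - tau)) dtau, time in minutes.
# Recursive trapezoid: exact for k2 = 0, O(dt^2) otherwise.
.convolveOneTissue <- function(tGrid, caGrid, k1, k2) {
  dtm <- (tGrid[2L] - tGrid[1L]) / 60
  n <- length(tGrid)
  if (k2 == 0) {
    inc <- dtm * (caGrid[-1L] + caGrid[-n]) / 2
    return(k1 * c(0, cumsum(inc)))
  }
  a <- exp(-k2 * dtm)
  b <- c(0, dtm / 2 * (caGrid[-1L] + a * caGrid[-n]))
  k1 * as.numeric(stats::filter(b, a, method = "recursive"))
}

#' Simulate a measured myocardial time-activity curve
#'
#' Generates the observed tissue curve under the simulator's measurement
#' model: one-tissue kinetics
#' `Ct(t) = k1 * integral_0^t Ca(tau) exp(-k2 (t - tau)) dtau`
#' (time in minutes inside the convolution; `k2 = 0` gives pure trapping as
#' assumed for sestamibi), contaminated as
#' `P(t) = pv * Ct(t) + sm * Ca(t)` and frame-averaged on `schedule`.
#' Computation uses a 0.1 s grid.
#'
#' @param aif continuous arterial input: a function of time in seconds
#'   returning kBq/mL (see [aifFunction()]).
#' @param k1 uptake rate, mL/min/g (>= 0).
#' @param k2 washout rate, 1/min (>= 0; 0 = irreversible trapping).
#' @param sm blood-to-myocardium spillover fraction.
#' @param pv partial-volume recovery factor on the tissue signal.
#' @param schedule a [FrameSchedule-class].
#' @param label region label for the returned TAC.
#' @return a [TimeActivityCurve-class].
#' @examples
#' ca <- aifFunction(simConfig())
#' makeTissueTac(ca, k1 = 0.44, k2 = 0, sm = 0.3, pv = 1, spectSchedule())
#' @export
makeTissueTac <- function(aif, k1, k2 = 0, sm = 0, pv = 1,
                          schedule = spectSchedule(), label = "GLOBAL") {
  stopifnot(is.function(aif), k1 >= 0, k2 >= 0)
  tGrid <- .fineGrid(schedule)
  caGrid <- aif(tGrid)
  ct <- .convolveOneTissue(tGrid, caGrid, k1, k2)
  obs <- pv * ct + sm * caGrid
  TimeActivityCurve(schedule, pmax(.frameAverage(schedule, tGrid, obs), 0),
    label = label
  )
}

#' Add count-statistics noise to a TAC
#'
#' Adds zero-mean Gaussian noise whose standard deviation scales like
#' counting statistics: `sd[i] = noiseScale * sqrt(max(v[i], vFloor) /
#' durationMin[i])`, i.e. variance inversely proportional to frame duration
#' (in minutes) and proportional to signal, with a floor `vFloor` of 1% of
#' the curve maximum so baseline frames are not noise-free. Negative results
#' are clamped to 0. Deterministic for a fixed `seed`.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param noiseScale noise magnitude (>= 0); 0 returns `tac` unchanged.
#' @param seed optional integer; if supplied the RNG is seeded locally, if
#'   `NULL` the current RNG stream is used.
#' @return a [TimeActivityCurve-class] with noisy values.
#' @export
addNoise <- function(tac, noiseScale, seed = NULL) {
  stopifnot(is(tac, "TimeActivityCurve"), noiseScale >= 0)
  if (noiseScale == 0) {
    return(tac)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- tac@values
  vFloor <- 0.01 * max(v)
  durMin <- tac@schedule@frameDuration / 60
  sdv <- noiseScale * sqrt(pmax(v, vFloor) / durMin)
  TimeActivityCurve(
    tac@schedule, pmax(v + stats::rnorm(length(v), 0, sdv), 0),
    label = tac@label
  )
}

#' Noise scale giving a relative noise level at the bolus peak
#'
#' Convenience inverse of the [addNoise()] model: the `noiseScale` for which
#' the noise SD at the curve's maximal frame equals `relSd` times that
#' maximum.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param relSd target relative SD at the peak frame (e.g. 0.05 for 5%).
#' @return scalar `noiseScale`.
#' @export
noiseScaleFor <- function(tac, relSd) {
  v <- tac@values
  i <- which.max(v)
  relSd * v[i] / sqrt(v[i] / (tac@schedule@frameDuration[i] / 60))
}

# truncated-normal draws by rejection (simple; bounds far from the bulk)
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x > lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate a complete rest/stress dual-modality cohort
#'
#' Draws, for every patient and coronary territory (LAD, LCx, RCA), a true
#' resting MBF, a true MFR (diseased vs. normal territories per the
#' configured prevalence) and an FFR linked to disease status; then renders
#' the corresponding dynamic studies: sestamibi SPECT TACs on the 32-frame
#' schedule with trapping kinetics (`k2 = 0`, uptake from the forward
#' Renkin-Crone relation) and water PET TACs on the 24-frame schedule with
#' `k1 = MBF` and `k2 = MBF / p` (`p` = 0.91 mL/g). The global curve is
#' generated from the mean of the three territory flows. Spillover,
#' partial volume and (optionally) count noise contaminate every myocardial
#' curve. Fully deterministic for a fixed `config@seed`.
#'
#' @param config a [SimConfig-class].
#' @return a list with elements
#'   \describe{
#'     \item{patients}{list; per patient: `id` and nested TAC sets
#'       `spect$rest`, `spect$stress`, `pet$rest`, `pet$stress`, each a named
#'       list `blood`, `global`, `lad`, `lcx`, `rca` of
#'       [TimeActivityCurve-class] objects.}
#'     \item{truth}{data.frame of ground truth: `patient_id`, `territory`,
#'       `true_rest_mbf`, `true_stress_mbf`, `true_mfr`, `ffr`,
#'       `diseased`.}
#'     \item{config}{the [SimConfig-class] used.}
#'   }
#' @examples
#' study <- simulateStudy(simConfig(seed = 11, nPatients = 2))
#' study$truth
#' @export
simulateStudy <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  territories <- c("LAD", "LCX", "RCA")
  p_water <- 0.91
  ca <- aifFunction(config)
  schedSpect <- spectSchedule()
  schedPet <- petSchedule()

  truth <- NULL
  patients <- vector("list", config@nPatients)
  for (ip in seq_len(config@nPatients)) {
    pid <- sprintf("P%03d", ip)
    diseased <- stats::runif(3) < config@prevalenceAbnormalFfr
    restMbf <- .rtruncnorm(3, config@restMbfMean, config@restMbfSd,
      lower = 0.3
    )
    mfr <- ifelse(diseased,
      stats::runif(3, config@mfrDiseasedRange[1], config@mfrDiseasedRange[2]),
      stats::runif(3, config@mfrNormalRange[1], config@mfrNormalRange[2])
    )
    stressMbf <- restMbf * mfr
    ffr <- ifelse(diseased,
      .rtruncnorm(3, config@ffrDiseasedMean, config@ffrDiseasedSd, 0, 1),
      .rtruncnorm(3, config@ffrNormalMean, config@ffrNormalSd, 0, 1)
    )
    truth <- rbind(truth, data.frame(
      patient_id = pid, territory = territories,
      true_rest_mbf = restMbf, true_stress_mbf = stressMbf,
      true_mfr = mfr, ffr = ffr, diseased = diseased
    ))

    # region flows: the 3 territories plus GLOBAL = mean territory flow
    flows <- function(state) {
      m <- if (state == "rest") restMbf else stressMbf
      c(GLOBAL = mean(m), LAD = m[1], LCX = m[2], RCA = m[3])
    }
    renderState <- function(state, modality) {
      sched <- if (modality == "spect") schedSpect else schedPet
      blood <- makeAif(config, sched)
      blood <- addNoise(blood, config@noiseScale)
      regs <- flows(state)
      tacs <- list(blood = blood)
      for (r in names(regs)) {
        mbf <- regs[[r]]
        if (modality == "spect") {
          k1 <- renkinCroneForward(mbf)$k1
          k2 <- 0
        } else {
          k1 <- mbf
          k2 <- mbf / p_water
        }
        tac <- makeTissueTac(ca, k1, k2,
          sm = config@smTrue, pv = config@pvTrue,
          schedule = sched, label = r
        )
        tacs[[tolower(r)]] <- addNoise(tac, config@noiseScale)
      }
      tacs
    }
    patients[[ip]] <- list(
      id = pid,
      spect = list(
        rest = renderState("rest", "spect"),
        stress = renderState("stress", "spect")
      ),
      pet = list(
        rest = renderState("rest", "pet"),
        stress = renderState("stress", "pet")
      )
    )
  }
  list(patients = patients, truth = truth, config = config)
}
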