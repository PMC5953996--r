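#' Frame midtimes and total duration
#'
#' `frameMidtimes()` returns the temporal midpoint of every frame
#' (`start + duration/2`, seconds); `totalDuration()` the acquisition length
#' (sum of durations, seconds). TAC values are interpreted as frame averages
#' attached to the frame midtimes.
#'
#' @param schedule a [FrameSchedule-class].
#' @return numeric vector of midtimes (strictly increasing), or a scalar
#'   duration, both in seconds.
#' @examples
#' frameMidtimes(spectSchedule())[1] # 1.5
#' totalDuration(spectSchedule()) # 345
#' @export
frameMidtimes <- function(schedule) {
  stopifnot(is(schedule, "FrameSchedule"))
  schedule@frameStart + schedule@frameDuration / 2
}

#' @rdname frameMidtimes
#' @export
totalDuration <- function(schedule) {
  stopifnot(is(schedule, "FrameSchedule"))
  schedule@frameStart[1L] + sum(schedule@frameDuration)
}

# Piecewise-linear interpolant through (midtime, value), extended flat to the
# acquisition boundaries. Returns knot vectors (x, y) covering
# [start_of_first_frame, end_of_last_frame].
.tacKnots <- function(tac) {
  sched <- tac@schedule
  mid <- frameMidtimes(sched)
  t0 <- sched@frameStart[1L]
  tEnd <- totalDuration(sched)
  x <- c(t0, mid, tEnd)
  y <- c(tac@values[1L], tac@values, tac@values[length(tac@values)])
  list(x = x, y = y)
}

#' Definite integral of a time-activity curve
#'
#' Integrates the piecewise-linear interpolant through the
#' (frame midtime, value) points of a TAC between two time limits, with flat
#' extension from the first/last midtime to the acquisition boundaries. This
#' is the integral operator of the net-retention estimator. Time limits are
#' given in seconds; the result is reported in kBq/mL x min (time converted
#' to minutes), the unit in which flow formulas are written.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param tLo,tHi integration limits in seconds, with
#'   `tLo < tHi` and both inside the acquisition window.
#' @return scalar integral in kBq/mL x min.
#' @examples
#' tac <- TimeActivityCurve(petSchedule(), rep(2, 24), "BLOOD")
#' integrateTac(tac, 0, 60) # 2 kBq/mL x min
#' @export
integrateTac <- function(tac, tLo, tHi) {
  stopifnot(is(tac, "TimeActivityCurve"))
  t0 <- tac@schedule@frameStart[1L]
  tEnd <- totalDuration(tac@schedule)
  if (!is.finite(tLo) || !is.finite(tHi) || tLo >= tHi) {
    stop("need tLo < tHi (got [", tLo, ", ", tHi, "])")
  }
  if (tLo < t0 - 1e-9 || tHi > tEnd + 1e-9) {
    stop(
      "integration limits [", tLo, ", ", tHi,
      "] s fall outside the acquisition window [", t0, ", ", tEnd, "] s"
    )
  }
  tLo <- max(tLo, t0)
  tHi <- min(tHi, tEnd)
  k <- .tacKnots(tac)
  # close the limits onto the knot grid, then trapezoid over sub-knots
  xs <- sort(unique(c(tLo, tHi, k$x[k$x > tLo & k$x < tHi])))
  ys <- stats::approx(k$x, k$y, xout = xs, rule = 2)$y
  area_s <- sum(diff(xs) * (ys[-1L] + ys[-length(ys)]) / 2)
  area_s / 60
}

#' Bolus landmarks of a blood-pool curve
#'
#' Locates the tracer bolus on the blood (input-function) TAC: the peak is
#' the midtime of the maximal frame, and arrival is the midtime of the first
#' frame whose value exceeds 10% of that maximum. These anchor the
#' net-retention integration limits.
#'
#' @param blood a blood-pool [TimeActivityCurve-class] with a positive
#'   maximum.
#' @return named list with `tArrival` and `tPeak`, seconds
#'   (`tArrival <= tPeak`).
#' @examples
#' aif <- makeAif(simConfig(), spectSchedule())
#' detectBolusLandmarks(aif)
#' @export
detectBolusLandmarks <- function(blood) {
  stopifnot(is(blood, "TimeActivityCurve"))
  v <- blood@values
  vmax <- max(v)
  if (vmax <= 0) {
    stop("blood TAC is identically zero; no bolus to locate")
  }
  mid <- frameMidtimes(blood@schedule)
  iPeak <- which.max(v)
  iArr <- which(v > 0.10 * vmax)[1L]
  list(tArrival = mid[iArr], tPeak = mid[iPeak])
}
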