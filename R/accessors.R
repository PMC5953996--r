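#' Accessors for frame schedules and time-activity curves
#'
#' @param object a [FrameSchedule-class] or [TimeActivityCurve-class].
#' @return `frameStart()` and `frameDuration()` return numeric vectors in
#'   seconds; `nFrames()` the frame count; `tacSchedule()`, `tacValues()` and
#'   `tacLabel()` the corresponding slots of a TAC.
#' @name schedule-accessors
NULL

#' @rdname schedule-accessors
#' @export
setGeneric("frameStart", function(object) standardGeneric("frameStart"))

#' @rdname schedule-accessors
#' @export
setGeneric("frameDuration", function(object) standardGeneric("frameDuration"))

#' @rdname schedule-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname schedule-accessors
setMethod("frameStart", "FrameSchedule", function(object) object@frameStart)

#' @rdname schedule-accessors
setMethod(
  "frameDuration", "FrameSchedule",
  function(object) object@frameDuration
)

#' @rdname schedule-accessors
setMethod(
  "nFrames", "FrameSchedule",
  function(object) length(object@frameDuration)
)

#' @rdname schedule-accessors
setMethod("frameStart", "TimeActivityCurve", function(object) {
  object@schedule@frameStart
})

#' @rdname schedule-accessors
setMethod("frameDuration", "TimeActivityCurve", function(object) {
  object@schedule@frameDuration
})

#' @rdname schedule-accessors
setMethod("nFrames", "TimeActivityCurve", function(object) {
  length(object@values)
})

#' @rdname schedule-accessors
#' @export
tacSchedule <- function(object) object@schedule

#' @rdname schedule-accessors
#' @export
tacValues <- function(object) object@values

#' @rdname schedule-accessors
#' @export
tacLabel <- function(object) object@label

setMethod("show", "FrameSchedule", function(object) {
  rle_d <- rle(object@frameDuration)
  proto <- paste(sprintf("%dx%gs", rle_d$lengths, rle_d$values),
    collapse = ", "
  )
  cat(
    "FrameSchedule:", nFrames(object), "frames,",
    totalDuration(object), "s total\n  ", proto, "\n"
  )
})

setMethod("show", "TimeActivityCurve", function(object) {
  v <- object@values
  cat(
    "TimeActivityCurve [", object@label, "]: ",
    nFrames(object), " frames over ", totalDuration(object@schedule),
    " s; peak ", signif(max(v), 4), " kBq/mL at ",
    frameMidtimes(object@schedule)[which.max(v)], " s\n",
    sep = ""
  )
})

setMethod("show", "RetentionParams", function(object) {
  cat("RetentionParams: PV =", object@pv, "CF =", object@cf,
    "Sm =", ifelse(is.na(object@sm), "estimated", object@sm),
    "Sb =", object@sb, "\n  offsets (s):", object@t1Offset,
    object@t2Offset, object@t3Offset, "anchored at", object@anchor,
    "\n  Renkin-Crone A =", object@renkinA, "B =", object@renkinB, "\n"
  )
})

setMethod("show", "FlowThresholds", function(object) {
  cat(
    "FlowThresholds: PET MFR <", object@petMfrCutoff,
    "| CZT MFR <", object@cztMfrCutoff,
    "| stress MBF <", object@stressMbfCutoff,
    "| FFR <=", object@ffrCutoff, "\n"
  )
})

setMethod("show", "SimConfig", function(object) {
  cat(
    "SimConfig: seed", object@seed, "|", object@nPatients,
    "patients x 3 territories | prevalence",
    signif(object@prevalenceAbnormalFfr, 3),
    "| noiseScale", object@noiseScale, "\n"
  )
})
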