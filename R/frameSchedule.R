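#' @include AllClasses.R
NULL

.toUnit <- function(seconds, unit) {
  unit <- match.arg(unit, c("s", "min"))
  if (unit == "min") seconds / 60 else seconds
}

#' Construct a frame schedule from frame durations
#'
#' Frames are contiguous and start at injection (t = 0), so the schedule
#' is fully determined by the durations.
#'
#' @param durations Numeric vector of frame durations in seconds.
#' @return A [FrameSchedule-class].
#' @examples
#' frameSchedule(c(30, 30, 60))
#' @export
frameSchedule <- function(durations) {
  durations <- as.numeric(durations)
  starts <- cumsum(c(0, durations[-length(durations)]))
  methods::new("FrameSchedule", start = starts, duration = durations)
}

#' The standard dynamic FDG acquisition schedule
#'
#' 8 frames of 30 s, 8 of 60 s, 6 of 180 s and 2 of 300 s: 24 frames
#' spanning a 40-minute acquisition, with short frames over the bolus
#' and long frames over the slow trapping phase.
#'
#' @return A 24-frame [FrameSchedule-class] totalling 40 min.
#' @examples
#' totalDuration(fdgFrameSchedule())  # 40
#' @export
fdgFrameSchedule <- function() {
  frameSchedule(c(rep(30, 8), rep(60, 8), rep(180, 6), rep(300, 2)))
}

#' @describeIn frameSchedule Frame count of a schedule.
#' @param x A `FrameSchedule`.
#' @export
setMethod("nFrames", "FrameSchedule", function(x) length(x@start))

#' @rdname frameStarts
#' @export
setMethod("frameStarts", "FrameSchedule",
  function(x, unit = "s") .toUnit(x@start, unit))

#' @rdname frameDurations
#' @export
setMethod("frameDurations", "FrameSchedule",
  function(x, unit = "s") .toUnit(x@duration, unit))

#' @rdname frameMidTimes
#' @export
setMethod("frameMidTimes", "FrameSchedule",
  function(x, unit = "min") .toUnit(x@start + x@duration / 2, unit))

#' @rdname totalDuration
#' @export
setMethod("totalDuration", "FrameSchedule",
  function(x, unit = "min") {
    n <- length(x@start)
    .toUnit(x@start[n] + x@duration[n], unit)
  })

setMethod("show", "FrameSchedule", function(object) {
  n <- length(object@start)
  cat(sprintf("FrameSchedule: %d frames, %.1f min total\n",
              n, totalDuration(object, "min")))
  rl <- rle(object@duration)
  cat("  durations:",
      paste(sprintf("%dx%gs", rl$lengths, rl$values), collapse = ", "), "\n")
})

#' Construct a time-activity curve
#'
#' @param schedule A [FrameSchedule-class].
#' @param activity Numeric per-frame mean activity, kBq/mL.
#' @param label Free-text region label.
#' @return A [TimeActivityCurve-class].
#' @export
timeActivityCurve <- function(schedule, activity, label = "") {
  methods::new("TimeActivityCurve", schedule = schedule,
               activity = as.numeric(activity), label = label)
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "TimeActivityCurve", function(x) nFrames(x@schedule))

#' @rdname schedule
#' @export
setMethod("schedule", "TimeActivityCurve", function(x) x@schedule)

#' @rdname activity
#' @export
setMethod("activity", "TimeActivityCurve", function(x) x@activity)

#' @rdname curveLabel
#' @export
setMethod("curveLabel", "TimeActivityCurve", function(x) x@label)

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve '%s': %d frames, peak %.2f kBq/mL\n",
              object@label, nFrames(object), max(object@activity)))
})

#' Convert a time-activity curve to a data frame
#'
#' @param x A [TimeActivityCurve-class].
#' @param ... Unused.
#' @return Data frame with columns `frame_start_s`, `frame_duration_s`,
#'   `mean_activity_kBq_per_mL` (the on-disk CSV layout).
#' @export
as.data.frame.TimeActivityCurve <- function(x, ...) {
  data.frame(frame_start_s = frameStarts(x@schedule),
             frame_duration_s = frameDurations(x@schedule),
             mean_activity_kBq_per_mL = x@activity)
}

# internal: check two curves share a schedule
.sameSchedule <- function(a, b) {
  isTRUE(all.equal(a@schedule@start, b@schedule@start)) &&
    isTRUE(all.equal(a@schedule@duration, b@schedule@duration))
}
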