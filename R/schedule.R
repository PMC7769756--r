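#' Frame schedule for a dynamic PET acquisition
#'
#' A frame schedule holds frame start times and durations in seconds. Frames
#' must be contiguous (each frame starts where the previous one ends) and
#' non-overlapping with strictly positive durations.
#'
#' @param durations_s numeric vector of frame durations in seconds.
#' @param start_s acquisition start time in seconds (default 0).
#' @return An object of class `frame_schedule` with fields `start` and
#'   `duration` (seconds), plus derived `mid_min` and `duration_min` (minutes).
#' @examples
#' sch <- default_frame_schedule()
#' nframes(sch)            # 22
#' sum(sch$duration) / 60  # 80 minutes
#' @export
frame_schedule <- function(durations_s, start_s = 0) {
  durations_s <- as.numeric(durations_s)
  if (any(!is.finite(durations_s)) || any(durations_s <= 0)) {
    stop("frame durations must be finite and > 0")
  }
  start <- start_s + cumsum(c(0, head(durations_s, -1)))
  structure(
    list(
      start = start,
      duration = durations_s,
      mid_min = (start + durations_s / 2) / 60,
      duration_min = durations_s / 60
    ),
    class = "frame_schedule"
  )
}

#' @describeIn frame_schedule The acquisition framing used throughout:
#'   4 x 60 s, 2 x 120 s, 4 x 180 s, 12 x 300 s — 22 frames covering 80 min.
#' @export
default_frame_schedule <- function() {
  frame_schedule(c(rep(60, 4), rep(120, 2), rep(180, 4), rep(300, 12)))
}

#' @describeIn frame_schedule Number of frames in a schedule.
#' @param schedule a `frame_schedule`.
#' @export
nframes <- function(schedule) length(schedule$duration)

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf(
    "<frame_schedule> %d frames, %.1f min total (%.0f-%.0f s frames)\n",
    nframes(x), sum(x$duration) / 60, min(x$duration), max(x$duration)
  ))
  invisible(x)
}

stopifnot_same_schedule <- function(a, b) {
  if (nframes(a) != nframes(b) ||
      max(abs(a$start - b$start)) > 1e-9 ||
      max(abs(a$duration - b$duration)) > 1e-9) {
    stop("frame schedules do not match")
  }
  invisible(TRUE)
}
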