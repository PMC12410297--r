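#' Frame schedules and time-activity curves
#'
#' A frame schedule lists, in minutes, the start and duration of each
#' acquisition frame of a dynamic PET scan. Frames must be ordered, strictly
#' increasing and non-overlapping; the mid-time of a frame is
#' `start + duration / 2`.
#'
#' @param frame_start numeric vector of frame start times (minutes).
#' @param frame_duration numeric vector of frame durations (minutes).
#' @return A `frame_schedule` data frame with columns `frame_start` and
#'   `frame_duration`.
#' @examples
#' frame_schedule(c(0, 1, 2), c(1, 1, 1))
#' @export
frame_schedule <- function(frame_start, frame_duration) {
  stopifnot(is.numeric(frame_start), is.numeric(frame_duration),
            length(frame_start) == length(frame_duration))
  if (length(frame_start) == 0L) stop("frame schedule is empty")
  if (any(frame_duration <= 0)) stop("frame durations must be positive")
  if (any(diff(frame_start) <= 0)) stop("frame starts must be strictly increasing")
  ends <- frame_start + frame_duration
  if (any(frame_start[-1] < ends[-length(ends)] - 1e-9)) {
    stop("frames overlap")
  }
  out <- data.frame(frame_start = as.numeric(frame_start),
                    frame_duration = as.numeric(frame_duration))
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Default 60-minute dynamic framing
#'
#' Emulates a one-hour small-animal acquisition with short early frames:
#' 6 x 0.5, 3 x 1, 2 x 2, 10 x 5 minutes (21 frames, 60 min total).
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 10))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' Construct a time-activity curve
#'
#' A TAC holds the frame-averaged activity concentration (kBq/mL, or SUV
#' after normalization) of one region over a framed acquisition.
#'
#' @param schedule a [frame_schedule()].
#' @param activity numeric vector, one value per frame.
#' @param region optional region name.
#' @return A `tac` data frame with columns `frame_start`, `frame_duration`,
#'   `activity`; the region name is kept in the `"region"` attribute.
#' @export
tac <- function(schedule, activity, region = NA_character_) {
  stopifnot(inherits(schedule, "frame_schedule") || is.data.frame(schedule))
  if (!inherits(schedule, "frame_schedule")) {
    schedule <- frame_schedule(schedule$frame_start, schedule$frame_duration)
  }
  stopifnot(is.numeric(activity), length(activity) == nrow(schedule))
  out <- data.frame(frame_start = schedule$frame_start,
                    frame_duration = schedule$frame_duration,
                    activity = as.numeric(activity))
  class(out) <- c("tac", "data.frame")
  attr(out, "region") <- region
  out
}

#' @rdname tac
#' @param x a `tac`.
#' @export
tac_midtimes <- function(x) x$frame_start + x$frame_duration / 2

tac_schedule <- function(x) frame_schedule(x$frame_start, x$frame_duration)

tac_region <- function(x) attr(x, "region")

same_schedule <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) &&
    max(abs(a$frame_start - b$frame_start)) <= tol &&
    max(abs(a$frame_duration - b$frame_duration)) <= tol
}

stop_if_schedule_mismatch <- function(a, b) {
  if (!same_schedule(a, b)) stop("TACs do not share a frame schedule")
  invisible(TRUE)
}
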