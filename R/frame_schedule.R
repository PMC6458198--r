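#' Dynamic PET frame schedule
#'
#' Frame start times and durations (minutes from the start of infusion,
#' t = 0).  Frames must be non-overlapping and in increasing order.  Curve
#' samples are placed at frame midpoints.
#'
#' @param frame_starts Numeric vector of frame start times (min), strictly
#'   increasing, first frame at t >= 0.
#' @param frame_durations Numeric vector of frame durations (min), > 0,
#'   same length as `frame_starts`.
#'
#' @return A `frame_schedule` object (list with `frame_starts`,
#'   `frame_durations`).
#' @seealso [default_frame_schedule()]
#' @examples
#' frame_schedule(c(0, 1, 2), c(1, 1, 1))
#' @export
frame_schedule <- function(frame_starts, frame_durations) {
  if (length(frame_starts) == 0L)
    stop("frame schedule is empty", call. = FALSE)
  if (length(frame_starts) != length(frame_durations))
    stop("frame_starts and frame_durations must have equal length",
         call. = FALSE)
  if (any(!is.finite(frame_starts)) || any(!is.finite(frame_durations)))
    stop("frame schedule contains non-finite values", call. = FALSE)
  if (any(frame_durations <= 0))
    stop("frame durations must be > 0", call. = FALSE)
  if (frame_starts[1L] < 0)
    stop("first frame must start at t >= 0", call. = FALSE)
  if (is.unsorted(frame_starts, strictly = TRUE))
    stop("frame starts must be strictly increasing", call. = FALSE)
  ends <- frame_starts + frame_durations
  if (length(frame_starts) > 1L &&
      any(frame_starts[-1L] < ends[-length(ends)] - 1e-9))
    stop("frames overlap", call. = FALSE)
  structure(list(frame_starts = as.numeric(frame_starts),
                 frame_durations = as.numeric(frame_durations)),
            class = "frame_schedule")
}

#' @describeIn frame_schedule The acquisition protocol used throughout:
#'   10 x 1 min, 10 x 5 min, 4 x 15 min, covering 0-120 min.
#' @export
default_frame_schedule <- function() {
  durations <- c(rep(1, 10), rep(5, 10), rep(15, 4))
  frame_schedule(cumsum(c(0, durations[-length(durations)])), durations)
}

#' Frame midpoint times of a schedule
#'
#' @param schedule A [frame_schedule()].
#' @return Numeric vector of midpoints (min).
#' @export
frame_midpoints <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$frame_starts + schedule$frame_durations / 2
}

n_frames <- function(schedule) length(schedule$frame_starts)

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %g-%g min\n",
              n_frames(x), x$frame_starts[1L],
              x$frame_starts[n_frames(x)] + x$frame_durations[n_frames(x)]))
  invisible(x)
}
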