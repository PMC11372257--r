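#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule is the ordered list of frame start and end times that
#' defines the sampling grid of every time-activity curve (TAC) of a scan.
#' Times are accepted in seconds (the convention of scanner protocols) and
#' stored internally in minutes, matching the per-minute convention of the
#' kinetic rate constants.
#'
#' @param starts,ends numeric vectors of frame start/end times.
#' @param unit `"s"` (default) or `"min"`.
#' @return An object of class `frame_schedule` with elements `start`, `end`,
#'   `mid`, `dur` (all minutes) and `n`.
#' @examples
#' sch <- frame_schedule(c(0, 2, 4), c(2, 4, 6))
#' sch$mid  # minutes
#' @export
frame_schedule <- function(starts, ends, unit = c("s", "min")) {
  unit <- match.arg(unit)
  starts <- as.numeric(starts)
  ends <- as.numeric(ends)
  if (length(starts) != length(ends) || length(starts) == 0L)
    stop("starts and ends must be non-empty and of equal length")
  if (unit == "s") {
    starts <- starts / 60
    ends <- ends / 60
  }
  if (any(!is.finite(starts)) || any(!is.finite(ends)))
    stop("non-finite frame times")
  if (any(ends <= starts))
    stop("every frame must satisfy end > start")
  if (any(diff(starts) <= 0))
    stop("frame starts must be strictly increasing")
  if (any(starts[-1] < ends[-length(ends)] - 1e-9))
    stop("frames must not overlap")
  gaps <- starts[-1] - ends[-length(ends)]
  contiguous <- all(gaps < 1e-9)
  if (!contiguous)
    message("frame schedule has gaps between frames (allowed, flagged)")
  out <- list(
    start = starts, end = ends, mid = (starts + ends) / 2,
    dur = ends - starts, n = length(starts), contiguous = contiguous
  )
  class(out) <- "frame_schedule"
  out
}

#' Default 90-min total-body framing protocol
#'
#' High-temporal-resolution early framing followed by progressively longer
#' frames: 30 x 2 s, 12 x 10 s, 7 x 60 s, 16 x 300 s (90 min total).  The
#' dense early frames are what makes joint time-delay estimation feasible.
#'
#' @return A [frame_schedule()].
#' @export
default_schedule <- function() {
  dur <- c(rep(2, 30), rep(10, 12), rep(60, 7), rep(300, 16))
  ends <- cumsum(dur)
  frame_schedule(ends - dur, ends, unit = "s")
}

#' Restrict a frame schedule to frames ending by a time limit
#'
#' @param schedule a [frame_schedule()].
#' @param t_max scan-time limit in minutes.
#' @return A shorter `frame_schedule`; used for 60-min truncation analyses.
#' @export
truncate_schedule <- function(schedule, t_max) {
  stopifnot(inherits(schedule, "frame_schedule"), .is_number(t_max))
  keep <- schedule$end <= t_max + 1e-9
  if (!any(keep)) stop("no frames end before t_max")
  frame_schedule(schedule$start[keep], schedule$end[keep], unit = "min")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.4g-%.4g min%s\n", x$n,
              x$start[1], x$end[x$n],
              if (x$contiguous) "" else " (non-contiguous)"))
  invisible(x)
}

# total scan duration in minutes
.duration <- function(schedule) schedule$end[schedule$n] - schedule$start[1]
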