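#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule is an ordered set of non-overlapping time frames, each
#' defined by its start and end time in minutes post injection. Frame
#' mid-times serve as the abscissa for kinetic fitting; frame durations set
#' integration windows and statistical weights.
#'
#' @param starts numeric vector of frame start times (minutes).
#' @param ends numeric vector of frame end times (minutes), same length.
#' @return an object of class `frame_schedule`.
#' @examples
#' frame_schedule(c(0, 5), c(5, 10))
#' @export
frame_schedule <- function(starts, ends) {
  starts <- as.numeric(starts)
  ends <- as.numeric(ends)
  if (length(starts) == 0L || length(starts) != length(ends))
    stop("'starts' and 'ends' must be non-empty vectors of equal length")
  if (any(!is.finite(starts)) || any(!is.finite(ends)))
    stop("frame times must be finite")
  if (any(ends <= starts))
    stop("every frame end must be later than its start")
  if (length(starts) > 1L) {
    if (any(diff(starts) <= 0))
      stop("frame start times must be strictly increasing")
    if (any(starts[-1L] < ends[-length(ends)] - 1e-9))
      stop("frames must not overlap")
  }
  structure(list(starts = starts, ends = ends), class = "frame_schedule")
}

#' @export
length.frame_schedule <- function(x) length(x$starts)

#' Frame mid-times and durations
#'
#' @param sched a [frame_schedule()].
#' @return numeric vector, minutes.
#' @export
frame_mids <- function(sched) (sched$starts + sched$ends) / 2

#' @rdname frame_mids
#' @export
frame_durations <- function(sched) sched$ends - sched$starts

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames covering [%g, %g] min\n",
              length(x), x$starts[1L], x$ends[length(x)]))
  invisible(x)
}

#' The 29-frame 1-hour dynamic FDG schedule
#'
#' The standard total-body dynamic FDG protocol: 6 x 10 s, 2 x 30 s,
#' 6 x 60 s, 5 x 120 s, 4 x 180 s and 6 x 300 s, 29 frames covering
#' 0--60 minutes post injection.
#'
#' @return a [frame_schedule()] with 29 frames.
#' @export
default_schedule_1h <- function() {
  durs <- c(rep(10, 6), rep(30, 2), rep(60, 6), rep(120, 5),
            rep(180, 4), rep(300, 6)) / 60
  ends <- cumsum(durs)
  frame_schedule(ends - durs, ends)
}

#' Contiguous late-frame schedule
#'
#' Builds the short late-time schedule used for relative Patlak imaging,
#' e.g. `late_schedule(40, 4, 5)` for the 4 x 5-min frames of a 20-min scan
#' starting at t* = 40 min.
#'
#' @param t_start start of the first frame (minutes).
#' @param n number of frames.
#' @param dur duration of each frame (minutes).
#' @return a [frame_schedule()].
#' @export
late_schedule <- function(t_start, n, dur) {
  if (n < 1L) stop("'n' must be at least 1")
  if (dur <= 0) stop("'dur' must be positive")
  starts <- t_start + dur * (seq_len(n) - 1L)
  frame_schedule(starts, starts + dur)
}
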