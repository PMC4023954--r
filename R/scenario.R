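#' Build a momentum time-gap schedule
#'
#' Constructs the piecewise-constant displayed time gap (in seconds, signed
#' from the team's perspective) over a simulated ergometer race. A schedule
#' has three phases: a priming phase in which the boats keep in step before
#' the gap moves to the momentum starting value, a momentum phase in which
#' the gap steps monotonically by 2 s across seven equal-duration sections
#' (from -6 s to +6 s for positive momentum, +6 s to -6 s for negative),
#' and a completion phase that holds a final gap strictly between -8 and
#' +8 s (no race ends in full victory or defeat).
#'
#' @param direction `"positive"` (team gains 2 s per section) or
#'   `"negative"` (team loses 2 s per section).
#' @param momentum_section_duration Duration of each of the 7 momentum
#'   sections, seconds. Default `6.40 * 60 / 7` so the momentum phase lasts
#'   6.40 minutes.
#' @param priming_duration Priming-phase duration, seconds (default 3.20 min).
#' @param completion_duration Completion-phase duration, seconds (default 1 min).
#' @param completion_gap Displayed gap held during the completion phase,
#'   seconds; must satisfy `abs(completion_gap) < 8`. Defaults to the final
#'   momentum gap (+6 for positive, -6 for negative).
#'
#' @return A `tg_schedule` object: list with `direction`, `segments` (a
#'   tibble with `t_start`, `t_end`, `gap`, `phase`), and `session_length`
#'   in seconds. Segments tile `[0, session_length]`; each segment is
#'   right-open except the last, which is closed.
#' @seealso [gap_at()], [momentum_segments()], [write_schedule_json()]
#' @export
#' @examples
#' sched <- build_schedule("positive")
#' momentum_segments(sched)$gap   # -6 -4 -2 0 2 4 6
#' sched$session_length / 60      # 10.6 minutes
build_schedule <- function(direction = c("positive", "negative"),
                           momentum_section_duration = 6.40 * 60 / 7,
                           priming_duration = 3.20 * 60,
                           completion_duration = 1.00 * 60,
                           completion_gap = NULL) {
  direction <- match.arg(direction)
  durs <- c(momentum_section_duration, priming_duration, completion_duration)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("momentumdyn_invalid_duration: all phase durations must be positive",
         call. = FALSE)
  }

  gaps <- seq(-6, 6, by = 2)
  if (direction == "negative") gaps <- -gaps
  if (is.null(completion_gap)) completion_gap <- gaps[7L]
  if (!is.finite(completion_gap) || abs(completion_gap) >= 8) {
    stop("momentumdyn_invalid_gap: completion gap must lie strictly between -8 and +8 s",
         call. = FALSE)
  }

  momentum_start <- priming_duration
  bounds <- momentum_start + momentum_section_duration * (0:7)
  segments <- tibble::tibble(
    t_start = c(0, bounds[1:7], bounds[8]),
    t_end   = c(bounds[1], bounds[2:8], bounds[8] + completion_duration),
    gap     = c(0, gaps, completion_gap),
    phase   = c("priming", rep("momentum", 7L), "completion")
  )

  structure(
    list(direction = direction,
         segments = segments,
         session_length = bounds[8] + completion_duration),
    class = "tg_schedule"
  )
}

#' @export
print.tg_schedule <- function(x, ...) {
  cat(sprintf("<tg_schedule> %s momentum, %.2f min, %d segments\n",
              x$direction, x$session_length / 60, nrow(x$segments)))
  print(x$segments)
  invisible(x)
}

#' Momentum-phase segments of a schedule
#'
#' @param schedule A [build_schedule()] object.
#' @return Tibble of the 7 momentum segments, in time order.
#' @export
momentum_segments <- function(schedule) {
  stopifnot(inherits(schedule, "tg_schedule"))
  schedule$segments[schedule$segments$phase == "momentum", ]
}

#' Displayed time gap at a given session time
#'
#' Segments are right-open `[t_start, t_end)`, except the final segment,
#' which is closed so `t = session_length` is valid.
#'
#' @param schedule A [build_schedule()] object.
#' @param t Time within the session, seconds (vectorised).
#' @return Displayed gap(s) in seconds.
#' @export
gap_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "tg_schedule"))
  if (any(!is.finite(t)) || any(t < 0) || any(t > schedule$session_length)) {
    stop("momentumdyn_time_out_of_session: t must lie in [0, session_length]",
         call. = FALSE)
  }
  seg <- schedule$segments
  idx <- findInterval(t, seg$t_start)        # right-open by construction
  idx[t >= schedule$session_length] <- nrow(seg)  # closed final segment
  seg$gap[idx]
}

#' Serialise a schedule to JSON
#'
#' @param schedule A [build_schedule()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  stopifnot(inherits(schedule, "tg_schedule"))
  jsonlite::write_json(
    list(direction = schedule$direction,
         segments = schedule$segments,
         session_length = schedule$session_length),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a schedule from JSON
#'
#' @param path JSON file written by [write_schedule_json()].
#' @return A `tg_schedule` object.
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(direction = x$direction,
         segments = tibble::as_tibble(x$segments),
         session_length = x$session_length),
    class = "tg_schedule"
  )
}
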