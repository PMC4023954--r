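#' Sample-index ranges of the seven momentum sections
#'
#' Maps the momentum-phase segments of a schedule onto sample indices for a
#' record sampled at `sample_rate` starting at t = 0. Sample k has time
#' `(k - 1) / sample_rate`; a sample belongs to the section whose
#' right-open interval contains its time. Priming and completion samples
#' are excluded: the analysis operates only on the seven constant-gap
#' periods.
#'
#' @param schedule A [build_schedule()] object with exactly 7 momentum
#'   segments.
#' @param sample_rate Hz.
#' @param n_samples Record length; defaults to
#'   `round(session_length * sample_rate)`.
#' @return Tibble with `section` (1-7, time order), `gap` (s), `from`,
#'   `to` (inclusive sample indices).
#' @export
section_slices <- function(schedule, sample_rate,
                           n_samples = round(schedule$session_length * sample_rate)) {
  stopifnot(inherits(schedule, "tg_schedule"))
  mseg <- momentum_segments(schedule)
  if (nrow(mseg) != 7L) {
    stop("momentumdyn_bad_schedule: schedule must have exactly 7 momentum segments",
         call. = FALSE)
  }
  # first sample with t >= t_start; last sample with t < t_end
  from <- pmin(n_samples + 1L, ceiling(mseg$t_start * sample_rate - 1e-9) + 1L)
  to <- pmin(n_samples, ceiling(mseg$t_end * sample_rate - 1e-9))
  if (any(from > to)) {
    stop("momentumdyn_bad_schedule: record too short for the momentum phase",
         call. = FALSE)
  }
  tibble::tibble(section = 1:7, gap = mseg$gap, from = as.integer(from),
                 to = as.integer(to))
}

circular_sd_deg <- function(deg) {
  r <- deg * pi / 180
  R <- sqrt(mean(cos(r))^2 + mean(sin(r))^2)
  sqrt(pmax(0, -2 * log(R))) * 180 / pi
}

#' Per-section summaries for one session
#'
#' Cuts a session and its relative-phase series into the seven momentum
#' sections and computes, per section: team mean force (average over both
#' rowers' samples, N), mean and SD of the wrapped relative phase
#' (degrees, excluding edge-trimmed samples), mean absolute relative
#' phase, and the team-mean (two-rower average) efficacy and cohesion
#' scores. Missing item responses propagate as `NA`, never as a default.
#'
#' @param session A `team_session`.
#' @param phase A `phase_series` from [process_session()] /
#'   [relative_phase()] computed from this session's kinematics.
#' @param circular_sd If `TRUE`, `sd_phi` is the circular SD; the default
#'   is the ordinary SD of the wrapped series, which coincides with the
#'   circular SD in the small-angle regime the data occupy.
#' @return Tibble with one row per section: `team_id`, `direction`,
#'   `section`, `gap`, `mean_force`, `mean_phi`, `mean_abs_phi`, `sd_phi`,
#'   `efficacy`, `cohesion`.
#' @export
summarize_session <- function(session, phase, circular_sd = FALSE) {
  stopifnot(inherits(session, "team_session"), inherits(phase, "phase_series"))
  n <- length(phase$relative_phase)
  if (n != nrow(session$pos_cm)) {
    stop("momentumdyn_length_mismatch: phase series does not match session",
         call. = FALSE)
  }
  sl <- section_slices(session$schedule, session$sample_rate, n_samples = n)

  out <- lapply(1:7, function(s) {
    idx <- sl$from[s]:sl$to[s]
    keep <- idx[!phase$trimmed[idx]]
    rel <- phase$relative_phase[keep]
    it <- session$items[session$items$section == s, ]
    team_item <- function(m) {
      v <- it[[m]]
      if (length(v) != 2L || anyNA(v)) NA_real_ else mean(v)
    }
    tibble::tibble(
      team_id = session$team_id,
      direction = session$direction,
      section = s,
      gap = sl$gap[s],
      mean_force = mean(session$force_N[idx, ]),
      mean_phi = if (length(rel)) mean(rel) else NA_real_,
      mean_abs_phi = if (length(rel)) mean(abs(rel)) else NA_real_,
      sd_phi = if (length(rel) < 2) NA_real_
               else if (circular_sd) circular_sd_deg(rel) else stats::sd(rel),
      efficacy = team_item("efficacy"),
      cohesion = team_item("cohesion")
    )
  })
  dplyr::bind_rows(out)
}

#' Summarize a whole cohort
#'
#' Runs [process_session()] and [summarize_session()] over a list of
#' sessions and binds the per-section summaries.
#'
#' @param sessions List of `team_session` objects (e.g. from
#'   [generate_cohort()]).
#' @inheritParams process_session
#' @inheritParams summarize_session
#' @return Tibble of section summaries, 7 rows per session.
#' @export
summarize_cohort <- function(sessions, cutoff = 4, order = 2,
                             trim_fraction = 0.05, circular_sd = FALSE) {
  dplyr::bind_rows(lapply(sessions, function(s) {
    summarize_session(s, process_session(s, cutoff = cutoff, order = order,
                                         trim_fraction = trim_fraction),
                      circular_sd = circular_sd)
  }))
}

#' Across-team sample summary (printed-table shape)
#'
#' For each scenario and time gap, the across-team mean and SD of each
#' measure, plus an `"All"` row per scenario whose mean is the arithmetic
#' mean of the seven per-gap means and whose SD is computed over all
#' team-section values. With a single team the SD is reported as `NA`.
#'
#' @param summaries Section summaries from [summarize_cohort()] (any
#'   number of teams, one or both scenarios).
#' @param measures Columns to summarize.
#' @return Tidy tibble: `direction`, `gap` (character; `"All"` for the
#'   aggregate row), `measure`, `mean`, `sd`, `n_teams`.
#' @export
sample_summary <- function(summaries,
                           measures = c("efficacy", "cohesion",
                                        "mean_force", "mean_phi")) {
  if (nrow(summaries) == 0L) {
    stop("momentumdyn_empty_input: no summaries to aggregate", call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    summaries[, c("team_id", "direction", "gap", measures)],
    dplyr::all_of(measures), names_to = "measure", values_to = "value"
  )
  sd_or_na <- function(v) if (sum(!is.na(v)) < 2) NA_real_ else stats::sd(v, na.rm = TRUE)

  per_gap <- long |>
    dplyr::group_by(.data$direction, .data$gap, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd_or_na(.data$value),
                     n_teams = dplyr::n_distinct(.data$team_id),
                     .groups = "drop")
  all_row <- per_gap |>
    dplyr::group_by(.data$direction, .data$measure) |>
    dplyr::summarise(mean = mean(.data$mean), .groups = "drop") |>
    dplyr::left_join(
      long |>
        dplyr::group_by(.data$direction, .data$measure) |>
        dplyr::summarise(
          sd = if (dplyr::n_distinct(.data$team_id) < 2) NA_real_
               else sd_or_na(.data$value),
          n_teams = dplyr::n_distinct(.data$team_id),
          .groups = "drop"),
      by = c("direction", "measure")
    )
  dplyr::bind_rows(
    dplyr::mutate(all_row, gap = "All"),
    dplyr::mutate(per_gap, gap = as.character(.data$gap))
  ) |>
    dplyr::arrange(.data$measure, .data$direction)
}

#' Published sample summary of the original eight-team experiment
#'
#' The per-gap across-team means (and SDs) of collective efficacy, task
#' cohesion, exerted force (N) and relative phase (degrees) reported for
#' the eight-team study whose design this package emulates, together with
#' the published `"All"` aggregate row. Used as an internal-consistency
#' fixture (the mean of the seven per-gap means must reproduce the
#' published aggregate) and as the reference scale for the generator
#' defaults.
#'
#' @return Tibble: `measure`, `direction`, `gap` (character, `"All"` for
#'   the aggregate), `mean`, `sd`.
#' @export
reference_sample_summary <- function() {
  gaps <- c("All", "-6", "-4", "-2", "0", "2", "4", "6")
  col <- function(measure, direction, mean, sd) {
    tibble::tibble(measure = measure, direction = direction, gap = gaps,
                   mean = mean, sd = sd)
  }
  dplyr::bind_rows(
    col("efficacy", "positive",
        c(6.29, 4.44, 5.63, 6.13, 6.31, 6.75, 7.25, 7.56),
        c(1.22, 0.56, 0.74, 0.58, 0.70, 0.85, 0.71, 1.05)),
    col("efficacy", "negative",
        c(5.20, 3.13, 3.69, 4.38, 5.25, 5.63, 6.38, 7.94),
        c(1.79, 1.16, 0.84, 0.99, 0.93, 0.64, 0.92, 1.15)),
    col("cohesion", "positive",
        c(6.87, 6.38, 6.25, 6.69, 6.63, 7.06, 7.38, 7.69),
        c(1.38, 1.75, 1.31, 1.19, 1.53, 1.12, 1.36, 1.22)),
    col("cohesion", "negative",
        c(6.10, 4.88, 4.88, 5.69, 6.00, 6.56, 6.81, 7.88),
        c(1.57, 1.66, 1.46, 1.19, 1.31, 1.08, 1.00, 1.06)),
    col("mean_force", "positive",
        c(146.33, 156.21, 147.20, 145.51, 143.06, 144.20, 142.26, 145.85),
        c(8.82, 9.79, 7.90, 8.19, 8.69, 6.15, 7.39, 8.25)),
    col("mean_force", "negative",
        c(144.53, 138.71, 139.68, 141.22, 141.77, 143.91, 148.93, 157.48),
        c(10.20, 8.72, 7.00, 6.75, 8.19, 7.86, 8.19, 12.24)),
    col("mean_phi", "positive",
        c(4.86, 3.37, 4.58, 4.93, 5.79, 4.21, 5.82, 5.30),
        c(3.49, 3.28, 4.53, 4.30, 3.01, 3.41, 3.29, 3.04)),
    col("mean_phi", "negative",
        c(5.48, 4.26, 5.70, 6.79, 5.94, 5.67, 5.30, 4.71),
        c(3.79, 2.63, 3.50, 4.40, 4.63, 3.79, 4.45, 3.72))
  )
}

#' Wide sample-summary table ("mean±sd" per scenario and gap)
#'
#' @param summary_tidy Output of [sample_summary()] (or
#'   [reference_sample_summary()], which shares its columns).
#' @param digits Rounding for display.
#' @return Wide tibble: one row per gap (with `"All"` first), one
#'   `measure_direction` column per cell.
#' @export
format_summary_table <- function(summary_tidy, digits = 2) {
  cell <- function(m, s) {
    ifelse(is.na(s), sprintf("%.*f", digits, m),
           sprintf("%.*f±%.*f", digits, m, digits, s))
  }
  wide <- summary_tidy |>
    dplyr::mutate(value = cell(.data$mean, .data$sd),
                  column = paste(.data$measure, .data$direction, sep = "_")) |>
    dplyr::select(dplyr::all_of(c("gap", "column", "value"))) |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  ord <- order(match(wide$gap, c("All", "-6", "-4", "-2", "0", "2", "4", "6")))
  wide[ord, ]
}
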