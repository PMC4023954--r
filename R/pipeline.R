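#' Full-run configuration
#'
#' Bundles every tunable of the pipeline: generator settings, schedule
#' durations, filter settings, edge trim, permutation count, test
#' selection and the master seed. Every stochastic stage receives a
#' substream seed derived from the master seed and the stage name, so
#' adding a stage never perturbs another stage's draws.
#'
#' @param seed Master seed.
#' @param generator A [generator_config()]; its own seed is overridden by
#'   a substream of `seed`.
#' @param momentum_section_duration,priming_duration,completion_duration
#'   Schedule durations in seconds, see [build_schedule()].
#' @param cutoff,order Low-pass filter settings ([lowpass_filter()]).
#' @param trim_fraction Edge-trim fraction ([relative_phase()]).
#' @param circular_sd Use circular SD for phase stability
#'   ([summarize_session()]).
#' @param n_perm Monte Carlo permutations per test.
#' @param tests Subset of
#'   `c("trend", "trend_difference", "pairwise", "combined")`.
#' @param measures Measures analyzed by the trend-family tests.
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1,
                       generator = generator_config(),
                       momentum_section_duration = 6.40 * 60 / 7,
                       priming_duration = 3.20 * 60,
                       completion_duration = 1.00 * 60,
                       cutoff = 4, order = 2,
                       trim_fraction = 0.05, circular_sd = FALSE,
                       n_perm = 5000,
                       tests = c("trend", "trend_difference", "pairwise",
                                 "combined"),
                       measures = c("efficacy", "cohesion", "mean_force",
                                    "mean_phi", "sd_phi")) {
  tests <- match.arg(tests, several.ok = TRUE)
  structure(list(seed = as.integer(seed), generator = generator,
                 momentum_section_duration = momentum_section_duration,
                 priming_duration = priming_duration,
                 completion_duration = completion_duration,
                 cutoff = cutoff, order = order,
                 trim_fraction = trim_fraction, circular_sd = circular_sd,
                 n_perm = n_perm, tests = tests, measures = measures),
            class = "run_config")
}

#' Run the full simulate-process-aggregate-analyze pipeline
#'
#' Generates a cohort under the configured scenarios, extracts the
#' continuous relative phase of every session, builds section summaries
#' and the sample-level table, and runs the selected permutation tests:
#' per-scenario trend tests for each measure, between-scenario
#' trend-difference tests, adjacent-gap force contrasts within each
#' scenario plus between-scenario same-gap contrasts for the psychological
#' measures, and the combined coordination test. Identical config and
#' seed give identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, writes `summaries.csv`,
#'   `table1.csv`, `trends.csv`, `pairwise.csv`, `coordination.csv`,
#'   `results.json` and `run.log`.
#' @return List with `sessions`, `summaries`, `sample_summary`, `table1`,
#'   `tests` (named list of `perm_test` objects), `results` (tidy tibble)
#'   and `log` (character vector of stage entries).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  note <- function(...) {
    log[[length(log) + 1L]] <<- sprintf(...)
    invisible(NULL)
  }

  sched_pos <- build_schedule("positive",
                              momentum_section_duration = config$momentum_section_duration,
                              priming_duration = config$priming_duration,
                              completion_duration = config$completion_duration)
  sched_neg <- build_schedule("negative",
                              momentum_section_duration = config$momentum_section_duration,
                              priming_duration = config$priming_duration,
                              completion_duration = config$completion_duration)
  note("scenario: built positive/negative schedules, %.2f min session",
       sched_pos$session_length / 60)

  gen <- config$generator
  gen$seed <- derive_seed(config$seed, "simulate")
  sessions <- generate_cohort(gen, sched_pos, sched_neg)
  note("simulate: %d teams, %d sessions", gen$n_teams, length(sessions))

  summaries <- summarize_cohort(sessions, cutoff = config$cutoff,
                                order = config$order,
                                trim_fraction = config$trim_fraction,
                                circular_sd = config$circular_sd)
  note("aggregate: %d section summaries", nrow(summaries))
  samp <- sample_summary(summaries)
  tab1 <- format_summary_table(samp)

  tests <- list()
  add <- function(name, t) tests[[name]] <<- t
  perm_seed <- function(...) derive_seed(config$seed, "analyze", ...)
  n_perm <- config$n_perm

  if ("trend" %in% config$tests) {
    for (m in config$measures) {
      for (sc in c("positive", "negative")) {
        add(sprintf("trend_%s_%s", m, sc),
            trend_test(summaries, m, sc, n_perm, perm_seed("trend", m, sc)))
      }
    }
  }
  if ("trend_difference" %in% config$tests) {
    for (m in config$measures) {
      add(sprintf("trend_difference_%s", m),
          trend_difference_test(summaries, m, n_perm = n_perm,
                                seed = perm_seed("trend_difference", m)))
    }
  }
  if ("pairwise" %in% config$tests) {
    gaps <- sort(unique(summaries$gap))
    for (sc in c("positive", "negative")) {       # adjacent-gap force changes
      for (k in seq_len(length(gaps) - 1L)) {
        add(sprintf("force_%s_gap_%+d_vs_%+d", sc, gaps[k + 1], gaps[k]),
            pairwise_gap_test(summaries, "mean_force", gaps[k + 1], gaps[k],
                              scenario_a = sc, n_perm = n_perm,
                              seed = perm_seed("pairwise_force", sc, k)))
      }
    }
    for (m in intersect(c("efficacy", "cohesion", "mean_phi"), config$measures)) {
      for (g in gaps) {                           # same-gap scenario contrasts
        add(sprintf("scenario_%s_gap_%+d", m, g),
            pairwise_gap_test(summaries, m, g, g,
                              scenario_a = "positive", scenario_b = "negative",
                              n_perm = n_perm,
                              seed = perm_seed("pairwise_scenario", m, g)))
      }
    }
  }
  if ("combined" %in% config$tests) {
    add("combined_coordination",
        combined_phase_test(summaries, n_perm, perm_seed("combined")))
  }
  note("analyze: %d permutation tests at n_perm = %d", length(tests), n_perm)

  results <- tidy_perm_results(tests)
  results$name <- names(tests)

  out <- list(sessions = sessions, summaries = summaries,
              sample_summary = samp, table1 = tab1, tests = tests,
              results = results, log = log)
  if (!is.null(out_dir)) write_report_bundle(out, config, out_dir)
  out
}

write_report_bundle <- function(run, config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(run$summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(run$table1, file.path(out_dir, "table1.csv"),
                   row.names = FALSE)
  res <- run$results
  utils::write.csv(res[grepl("^trend", res$name), ],
                   file.path(out_dir, "trends.csv"), row.names = FALSE)
  utils::write.csv(res[grepl("^(force|scenario)_", res$name), ],
                   file.path(out_dir, "pairwise.csv"), row.names = FALSE)
  utils::write.csv(res[grepl("^combined", res$name), ],
                   file.path(out_dir, "coordination.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, n_perm = config$n_perm,
         n_teams = config$generator$n_teams,
         results = res),
    file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA
  )
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Trajectory figures in the published layout
#'
#' One panel per measure: across-team mean trajectory over the seven time
#' gaps, one line per scenario, with markers at gaps where the
#' between-scenario same-gap contrast has p < .05.
#'
#' @param run Output of [run_pipeline()].
#' @param measures Measures to plot.
#' @param alpha Significance threshold for gap markers.
#' @param out_dir Optional directory; when given, each panel is saved as
#'   `trajectory_<measure>.png`.
#' @return Named list of ggplot objects.
#' @export
render_figures <- function(run,
                           measures = c("efficacy", "cohesion",
                                        "mean_force", "mean_phi"),
                           alpha = 0.05, out_dir = NULL) {
  if (is.null(run$summaries) || nrow(run$summaries) == 0L) {
    stop("momentumdyn_no_data: run has no summaries to plot", call. = FALSE)
  }
  res <- run$results
  plots <- list()
  for (m in measures) {
    traj <- run$summaries |>
      dplyr::group_by(.data$direction, .data$gap) |>
      dplyr::summarise(mean = mean(.data[[m]], na.rm = TRUE), .groups = "drop")
    p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$gap, y = .data$mean,
                                            colour = .data$direction)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_continuous(breaks = seq(-6, 6, 2)) +
      ggplot2::labs(x = "Time gap (s)", y = m,
                    colour = "Momentum scenario") +
      ggplot2::theme_minimal()
    if (!is.null(res) && nrow(res)) {
      sig <- res[grepl(sprintf("^scenario_%s_gap_", m), res$name) &
                   res$p_value < alpha, ]
      if (nrow(sig)) {
        sig_gaps <- as.numeric(sub(sprintf("^scenario_%s_gap_", m), "", sig$name))
        marker_y <- max(traj$mean, na.rm = TRUE)
        p <- p + ggplot2::annotate("text", x = sig_gaps, y = marker_y,
                                   label = "*", size = 6)
      }
    }
    plots[[m]] <- p
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (m in names(plots)) {
      ggplot2::ggsave(file.path(out_dir, sprintf("trajectory_%s.png", m)),
                      plots[[m]], width = 6, height = 4, dpi = 150)
    }
  }
  plots
}
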