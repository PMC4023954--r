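#' Team-averaged Cohen's d
#'
#' Effect size computed per team as that team's observed result divided by
#' a pooled SD of the values entering the team's statistic, then averaged
#' over teams. Teams with zero (or non-finite) spread get an undefined
#' `d` and are excluded from the average with a warning.
#'
#' @param per_team_observed Numeric vector of per-team observed results
#'   (on the measure's scale).
#' @param per_team_spread Numeric vector of per-team pooled SDs, same
#'   length.
#' @return An `effect_size` object: `per_team_d`, `average_d`.
#' @export
cohens_d <- function(per_team_observed, per_team_spread) {
  if (length(per_team_observed) != length(per_team_spread)) {
    stop("momentumdyn_length_mismatch: observed and spread must match",
         call. = FALSE)
  }
  bad <- !is.finite(per_team_spread) | per_team_spread <= 0
  d <- per_team_observed / per_team_spread
  d[bad] <- NA_real_
  if (any(bad)) {
    warning(sprintf("momentumdyn: %d team(s) with zero spread excluded from average d",
                    sum(bad)))
  }
  structure(list(per_team_d = d, average_d = mean(d[!bad])),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> average d = %.3f over %d team(s)\n",
              x$average_d, sum(is.finite(x$per_team_d))))
  invisible(x)
}

new_perm_result <- function(test_name, measure, observed, null_stats,
                            n_perm, seed, teams, effect = NULL,
                            two_sided = TRUE) {
  exceed <- if (two_sided) {
    sum(abs(null_stats) >= abs(observed) - 1e-12)
  } else {
    sum(null_stats >= observed - 1e-12)
  }
  structure(
    list(test_name = test_name, measure = measure,
         observed_stat = observed,
         p_value = (1 + exceed) / (n_perm + 1),
         n_permutations = n_perm, seed = seed,
         null_summary = c(mean = mean(null_stats), sd = stats::sd(null_stats)),
         teams = teams, effect = effect, two_sided = two_sided),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s [%s]: observed = %.4g, p = %.4g (%d permutations%s)\n",
              x$test_name, x$measure, x$observed_stat, x$p_value,
              x$n_permutations, if (x$two_sided) ", two-sided" else ", one-sided"))
  if (!is.null(x$effect)) {
    cat(sprintf("  average Cohen's d = %.3f\n", x$effect$average_d))
  }
  invisible(x)
}

# teams x sections matrix of one measure for one scenario, ordered by
# section; teams with any missing section are dropped with a warning.
measure_matrix <- function(summaries, measure, scenario) {
  df <- summaries[summaries$direction == scenario, ]
  if (nrow(df) == 0L) {
    stop(sprintf("momentumdyn_no_data: no '%s' sessions in summaries", scenario),
         call. = FALSE)
  }
  sections <- sort(unique(df$section))
  wide <- tidyr::pivot_wider(
    df[, c("team_id", "section", measure)],
    names_from = "section", values_from = dplyr::all_of(measure)
  )
  m <- as.matrix(wide[, as.character(sections)])
  rownames(m) <- as.character(wide$team_id)
  ok <- stats::complete.cases(m)
  if (any(!ok)) {
    warning(sprintf("momentumdyn: excluding %d team(s) with missing sections (%s, %s)",
                    sum(!ok), measure, scenario))
  }
  m[ok, , drop = FALSE]
}

# least-squares slope of each row on section index 1..k
ls_slopes <- function(m) {
  k <- ncol(m)
  cc <- seq_len(k) - (k + 1) / 2
  as.numeric(m %*% cc) / sum(cc^2)
}

with_local_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  force(expr)
}

#' Within-team Monte Carlo trend test
#'
#' Tests the overall change of a measure across the seven momentum
#' sections of one scenario. The observed statistic is the across-team
#' mean of per-team least-squares slopes of the measure on section index
#' (1-7); the null distribution is generated by independently permuting
#' each team's seven section values (shuffling within teams, never across
#' them, because teams are not a homogeneous sample), with a two-sided
#' add-one p-value. Effect size: per team, the fitted overall change
#' (slope times the section span, 6 x slope for 7 sections) divided by the
#' team's section SD, averaged over teams.
#'
#' @param summaries Section summaries ([summarize_cohort()]).
#' @param measure Summary column to test (e.g. `"efficacy"`,
#'   `"mean_force"`, `"sd_phi"`).
#' @param scenario `"positive"` or `"negative"`.
#' @param n_perm Number of Monte Carlo permutations (default 5000).
#' @param seed Seed for the permutation stream.
#' @return A `perm_test` object.
#' @export
trend_test <- function(summaries, measure, scenario, n_perm = 5000, seed = 1) {
  stopifnot(n_perm >= 1)
  m <- measure_matrix(summaries, measure, scenario)
  if (nrow(m) == 0L) {
    stop("momentumdyn_no_data: no complete teams for trend test", call. = FALSE)
  }
  slopes <- ls_slopes(m)
  observed <- mean(slopes)

  null_stats <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- t(apply(m, 1, sample))
      mean(ls_slopes(perm))
    }, numeric(1))
  })

  eff <- cohens_d((ncol(m) - 1) * slopes, apply(m, 1, stats::sd))
  new_perm_result(paste0("trend_", scenario), measure, observed, null_stats,
                  n_perm, seed, rownames(m), effect = eff)
}

# paired teams x 7 matrices for both scenarios, restricted to teams complete
# in both sessions.
paired_matrices <- function(summaries, measure) {
  mp <- measure_matrix(summaries, measure, "positive")
  mn <- measure_matrix(summaries, measure, "negative")
  teams <- intersect(rownames(mp), rownames(mn))
  if (length(teams) < length(union(rownames(mp), rownames(mn)))) {
    warning("momentumdyn: excluding unpaired team(s) from paired test")
  }
  if (length(teams) == 0L) {
    stop("momentumdyn_no_data: no teams with both sessions", call. = FALSE)
  }
  list(positive = mp[teams, , drop = FALSE],
       negative = mn[teams, , drop = FALSE], teams = teams)
}

#' Trend-difference test between momentum scenarios
#'
#' Compares the overall change of a measure between the positive and
#' negative scenarios, pairing each team's two sessions. In
#' `mode = "steepness"` (for measures whose expected trends have opposite
#' signs, e.g. rising efficacy under positive momentum versus falling
#' under negative) the per-team statistic is
#' `|slope_negative| - |slope_positive|`, positive when the negative-
#' scenario change is steeper. In `mode = "plain"` it is
#' `slope_positive - slope_negative`. The null swaps the two sessions'
#' scenario labels within each team (sign flips over the 2^n space),
#' two-sided add-one p. Effect size: per-team statistic scaled to an
#' overall change (x 6), divided by the team's pooled section SD over
#' both sessions.
#'
#' @inheritParams trend_test
#' @param mode `"steepness"` or `"plain"` (see Details).
#' @return A `perm_test` object.
#' @export
trend_difference_test <- function(summaries, measure,
                                  mode = c("steepness", "plain"),
                                  n_perm = 5000, seed = 1) {
  mode <- match.arg(mode)
  pm <- paired_matrices(summaries, measure)
  sp <- ls_slopes(pm$positive)
  sn <- ls_slopes(pm$negative)
  stat_i <- if (mode == "steepness") abs(sn) - abs(sp) else sp - sn
  observed <- mean(stat_i)

  n_teams <- length(stat_i)
  null_stats <- with_local_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_teams * n_perm, replace = TRUE),
                    nrow = n_teams)
    as.numeric(crossprod(stat_i, signs)) / n_teams
  })

  pooled <- sqrt((apply(pm$positive, 1, stats::var) +
                    apply(pm$negative, 1, stats::var)) / 2)
  eff <- cohens_d((ncol(pm$positive) - 1) * stat_i, pooled)
  new_perm_result(paste0("trend_difference_", mode), measure, observed,
                  null_stats, n_perm, seed, pm$teams, effect = eff)
}

#' Pairwise cell contrast by within-team swaps
#'
#' Tests the mean within-team difference between two cells of the design:
#' either two time gaps within one scenario (e.g. adjacent-gap force
#' changes) or the same gap across the two scenarios (e.g. efficacy at
#' gap -6, positive vs negative). The null swaps each team's two cell
#' values (sign flips), two-sided add-one p. Effect size: per-team
#' difference divided by the team's pooled section SD over the session(s)
#' involved.
#'
#' @inheritParams trend_test
#' @param gap_a,gap_b Time gaps (seconds) of the two cells.
#' @param scenario_a,scenario_b Scenarios of the two cells; default both
#'   `scenario_a` (within-scenario contrast). Set
#'   `scenario_b = "negative"`, `gap_b = gap_a` for a between-scenario
#'   same-gap contrast.
#' @return A `perm_test` object.
#' @export
pairwise_gap_test <- function(summaries, measure, gap_a, gap_b,
                              scenario_a = "positive",
                              scenario_b = scenario_a,
                              n_perm = 5000, seed = 1) {
  cell <- function(scenario, gap) {
    df <- summaries[summaries$direction == scenario & summaries$gap == gap, ]
    stats::setNames(df[[measure]], as.character(df$team_id))
  }
  a <- cell(scenario_a, gap_a)
  b <- cell(scenario_b, gap_b)
  teams <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (length(teams) < length(union(names(a), names(b)))) {
    warning("momentumdyn: excluding team(s) missing either cell")
  }
  if (length(teams) == 0L) {
    stop("momentumdyn_no_data: no teams with both cells", call. = FALSE)
  }
  d_i <- a[teams] - b[teams]
  observed <- mean(d_i)

  null_stats <- with_local_seed(seed, {
    signs <- matrix(sample(c(-1, 1), length(teams) * n_perm, replace = TRUE),
                    nrow = length(teams))
    as.numeric(crossprod(d_i, signs)) / length(teams)
  })

  spread <- vapply(teams, function(tm) {
    v <- summaries[[measure]][summaries$team_id == tm &
                                summaries$direction %in% c(scenario_a, scenario_b)]
    stats::sd(v, na.rm = TRUE)
  }, numeric(1))
  eff <- cohens_d(as.numeric(d_i), spread)
  new_perm_result("pairwise_gap", measure, observed, null_stats, n_perm, seed,
                  teams, effect = eff)
}

#' Combined coordination-quality test (relative phase and its stability)
#'
#' Tests whether the quality of interpersonal coordination — the
#' combination of the mean continuous relative phase and its stability,
#' both "better" when closer to 0 — differs between the scenarios. Per
#' session, quality metrics are the section-mean of |mean phi| and the
#' section-mean of SD phi. Per metric, the team statistic is
#' (negative - positive), so positive values mean better coordination
#' under positive momentum. The same within-team scenario-label swaps are
#' applied jointly to both metrics; per-metric p-hats are rank-based
#' within the joint null and combined with Fisher's statistic
#' `-2 (ln p_phi + ln p_sdphi)`; the combined p is the add-one proportion
#' of permutations whose combined statistic is at least the observed one
#' (one-sided, in the quality direction).
#'
#' @inheritParams trend_test
#' @return A `perm_test` object whose `observed_stat` is the observed
#'   Fisher combination; `per_metric` carries the two marginal statistics
#'   and rank-based p-hats.
#' @export
combined_phase_test <- function(summaries, n_perm = 5000, seed = 1) {
  metric_by_session <- summaries |>
    dplyr::group_by(.data$team_id, .data$direction) |>
    dplyr::summarise(phi = mean(abs(.data$mean_phi)),
                     sdphi = mean(.data$sd_phi),
                     n_sections = sum(!is.na(.data$mean_phi)),
                     .groups = "drop")
  if (anyNA(metric_by_session[, c("phi", "sdphi")])) {
    warning("momentumdyn: excluding team-session(s) with missing phase sections")
    metric_by_session <- metric_by_session[
      stats::complete.cases(metric_by_session[, c("phi", "sdphi")]), ]
  }
  wide <- tidyr::pivot_wider(metric_by_session[, 1:4],
                             names_from = "direction",
                             values_from = c("phi", "sdphi"))
  wide <- wide[stats::complete.cases(wide), ]
  if (nrow(wide) == 0L) {
    stop("momentumdyn_no_data: no teams with both sessions", call. = FALSE)
  }
  q_phi <- wide$phi_negative - wide$phi_positive
  q_sd <- wide$sdphi_negative - wide$sdphi_positive
  obs <- c(phi = mean(q_phi), sdphi = mean(q_sd))

  n_teams <- nrow(wide)
  null_mat <- with_local_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_teams * n_perm, replace = TRUE),
                    nrow = n_teams)
    cbind(phi = as.numeric(crossprod(q_phi, signs)) / n_teams,
          sdphi = as.numeric(crossprod(q_sd, signs)) / n_teams)
  })

  p_hat <- function(null_vec, x) {
    (1 + vapply(x, function(v) sum(null_vec >= v - 1e-12), numeric(1))) /
      (n_perm + 1)
  }
  fisher <- function(p1, p2) -2 * (log(p1) + log(p2))
  c_obs <- fisher(p_hat(null_mat[, "phi"], obs["phi"]),
                  p_hat(null_mat[, "sdphi"], obs["sdphi"]))
  c_null <- fisher(p_hat(null_mat[, "phi"], null_mat[, "phi"]),
                   p_hat(null_mat[, "sdphi"], null_mat[, "sdphi"]))

  res <- new_perm_result("combined_coordination", "phi+sd_phi",
                         as.numeric(c_obs), c_null, n_perm, seed,
                         as.character(wide$team_id), two_sided = FALSE)
  res$per_metric <- list(observed = obs,
                         p_hat = c(phi = p_hat(null_mat[, "phi"], obs["phi"]),
                                   sdphi = p_hat(null_mat[, "sdphi"], obs["sdphi"])))
  res
}

#' Tidy one or more permutation results
#'
#' @param results A `perm_test` or list of them.
#' @return Tibble with one row per test: name, measure, observed statistic,
#'   p, permutation count, seed, number of teams, average d.
#' @export
tidy_perm_results <- function(results) {
  if (inherits(results, "perm_test")) results <- list(results)
  dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(
      test = r$test_name, measure = r$measure,
      observed = r$observed_stat, p_value = r$p_value,
      n_permutations = r$n_permutations, seed = r$seed,
      n_teams = length(r$teams),
      average_d = if (is.null(r$effect)) NA_real_ else r$effect$average_d
    )
  }))
}
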