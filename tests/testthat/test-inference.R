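test_that("cohens_d is per-team observed over spread, averaged", {
  e <- cohens_d(c(1, 1), c(1, 1))
  expect_equal(e$per_team_d, c(1, 1))
  expect_equal(e$average_d, 1)
  expect_equal(cohens_d(c(2, 4), c(2, 2))$per_team_d, c(1, 2))
  expect_equal(cohens_d(c(2, 4), c(2, 2))$average_d, 1.5)

  expect_warning(e0 <- cohens_d(c(1, 2, 3), c(1, 0, 1)), "zero spread")
  expect_true(is.na(e0$per_team_d[2]))
  expect_equal(e0$average_d, 2)
  expect_error(cohens_d(1:3, 1:2), "momentumdyn_length_mismatch")
})

test_that("a maximal monotone trend attains the minimum add-one p", {
  vals <- matrix(rep(1:7, 4), nrow = 4, byrow = TRUE)
  sm <- toy_summaries(vals, "positive")
  res <- trend_test(sm, "efficacy", "positive", n_perm = 999, seed = 2)
  expect_equal(res$observed_stat, 1)
  expect_equal(res$p_value, 1 / 1000)
  expect_equal(res$effect$average_d, 6 / sd(1:7))
})

test_that("Monte Carlo trend p matches exhaustive enumeration on a 2x3 toy", {
  vals <- matrix(c(1.2, 3.1, 2.0,
                   0.5, 1.8, 2.2), nrow = 2, byrow = TRUE)
  p_exact <- oracle_trend_p(vals)          # all (3!)^2 = 36 joint orderings
  sm <- toy_summaries(vals, "positive")
  res <- trend_test(sm, "efficacy", "positive", n_perm = 5000, seed = 7)
  expect_mc_close(res$p_value, p_exact, 5000)
})

test_that("trend test excludes teams with missing sections and needs data", {
  vals <- rbind(1:7, c(2, NA, 4:8))
  sm <- toy_summaries(vals, "positive")
  expect_warning(res <- trend_test(sm, "efficacy", "positive",
                                   n_perm = 99, seed = 1),
                 "missing sections")
  expect_equal(res$teams, "1")
  expect_error(suppressWarnings(
    trend_test(toy_summaries(rbind(c(1, NA, 3, 4, 5, 6, 7)), "positive"),
               "efficacy", "positive")),
    "momentumdyn_no_data")
})

test_that("identical paired sessions give a null trend difference with p = 1", {
  vals <- rbind(1:7, seq(2, 8), c(5, 3, 6, 1, 7, 2, 4))
  sm <- paired_toy_summaries(vals, vals)
  res <- trend_difference_test(sm, "efficacy", mode = "plain",
                               n_perm = 499, seed = 3)
  expect_equal(res$observed_stat, 0)
  expect_equal(res$p_value, 1)
})

test_that("trend-difference p matches the exhaustive sign-flip oracle (3 teams)", {
  set.seed(41)
  pos <- matrix(rnorm(21, sd = 1), 3)
  neg <- matrix(rnorm(21, sd = 1) - 0.3 * rep(1:7, each = 3), 3)
  sm <- paired_toy_summaries(pos, neg)
  for (mode in c("steepness", "plain")) {
    slope <- function(m) apply(m, 1, function(x) coef(lm(x ~ seq_along(x)))[2])
    stat_i <- if (mode == "steepness") abs(slope(neg)) - abs(slope(pos))
              else slope(pos) - slope(neg)
    p_exact <- oracle_signflip_p(unname(stat_i))   # 2^3 = 8 label swaps
    res <- trend_difference_test(sm, "efficacy", mode = mode,
                                 n_perm = 4000, seed = 11)
    expect_mc_close(res$p_value, p_exact, 4000)
  }
})

test_that("pairwise contrast: constant +10 N difference attains minimum p", {
  set.seed(5)
  base <- matrix(rnorm(28, 140, 5), 4)
  vals <- base
  vals[, 4] <- vals[, 3] + 10          # gap 0 vs gap -2: +10 for every team
  sm <- toy_summaries(vals, "positive", "mean_force")
  res <- pairwise_gap_test(sm, "mean_force", 0, -2, scenario_a = "positive",
                           n_perm = 999, seed = 4)
  # minimum attainable two-sided p for 4 teams: all-sign agreement is rare
  # in the null, so p sits near the add-one floor
  expect_equal(res$observed_stat, 10)
  expect_lte(res$p_value, 0.15)
  d4 <- oracle_signflip_p(vals[, 4] - vals[, 3])
  expect_mc_close(res$p_value, d4, 999)
})

test_that("pairwise p matches exhaustive enumeration and respects pairing", {
  set.seed(6)
  pos <- matrix(rnorm(28, 6, 1), 4)
  neg <- matrix(rnorm(28, 5, 1), 4)
  sm <- paired_toy_summaries(pos, neg)
  # between-scenario contrast at the same gap (-6: section 1 pos, section 7 neg)
  res <- pairwise_gap_test(sm, "efficacy", -6, -6, scenario_a = "positive",
                           scenario_b = "negative", n_perm = 4000, seed = 9)
  d_i <- pos[, 1] - neg[, 7]
  expect_equal(res$observed_stat, mean(d_i))
  expect_mc_close(res$p_value, oracle_signflip_p(d_i), 4000)
})

test_that("pairwise p-values are uniform under a zero-difference null", {
  set.seed(77)
  ps <- replicate(200, {
    vals <- matrix(rnorm(8 * 7), 8)
    sm <- toy_summaries(vals, "positive", "mean_force")
    pairwise_gap_test(sm, "mean_force", 0, -2, scenario_a = "positive",
                      n_perm = 256, seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("combined coordination p matches the exhaustive joint oracle", {
  set.seed(21)
  make_phase_summaries <- function(phi_pos, phi_neg, sd_pos, sd_neg) {
    n <- length(phi_pos)
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      tibble::tibble(
        team_id = rep(i, 14),
        direction = rep(c("positive", "negative"), each = 7),
        section = rep(1:7, 2),
        gap = c(seq(-6, 6, 2), seq(6, -6, -2)),
        mean_phi = c(rnorm(7, phi_pos[i], 0.5), rnorm(7, phi_neg[i], 0.5)),
        sd_phi = c(rnorm(7, sd_pos[i], 0.2), rnorm(7, sd_neg[i], 0.2))
      )
    }))
  }
  sm <- make_phase_summaries(c(3, 4, 5), c(6, 7, 5), c(3, 3.5, 4), c(5, 5, 4))
  agg <- sm |>
    dplyr::group_by(team_id, direction) |>
    dplyr::summarise(phi = mean(abs(mean_phi)), sdphi = mean(sd_phi),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = direction,
                             values_from = c(phi, sdphi))
  p_exact <- oracle_combined_p(wide$phi_negative - wide$phi_positive,
                               wide$sdphi_negative - wide$sdphi_positive)
  res <- combined_phase_test(sm, n_perm = 4000, seed = 13)
  expect_mc_close(res$p_value, p_exact, 4000)

  # identical metrics across scenarios: every permutation ties, p = 1
  sm_null <- make_phase_summaries(c(4, 4, 4, 4), c(4, 4, 4, 4),
                                  c(3, 3, 3, 3), c(3, 3, 3, 3))
  sm_null$mean_phi <- rep(rep(c(4, 4), each = 7), 4)
  sm_null$sd_phi <- rep(rep(c(3, 3), each = 7), 4)
  res_null <- combined_phase_test(sm_null, n_perm = 999, seed = 14)
  expect_equal(res_null$p_value, 1)
})

test_that("p-values are invariant to team relabeling and affine rescaling", {
  set.seed(31)
  vals <- matrix(rnorm(5 * 7, 5, 1) + 0.2 * rep(1:7, each = 5), 5)
  sm <- toy_summaries(vals, "positive")
  res <- trend_test(sm, "efficacy", "positive", n_perm = 500, seed = 17)

  relabeled <- sm
  relabeled$team_id <- 6 - relabeled$team_id   # reverse labels
  res_rl <- trend_test(relabeled, "efficacy", "positive", n_perm = 500, seed = 17)
  expect_equal(res_rl$p_value, res$p_value)

  rescaled <- sm
  rescaled$efficacy <- 3 * rescaled$efficacy - 10
  res_rs <- trend_test(rescaled, "efficacy", "positive", n_perm = 500, seed = 17)
  expect_equal(res_rs$p_value, res$p_value)
  expect_equal(res_rs$observed_stat, 3 * res$observed_stat)
})

test_that("rejection rate grows with the configured effect magnitude", {
  set.seed(51)
  reject_rate <- function(slope, reps = 60) {
    mean(replicate(reps, {
      vals <- matrix(rnorm(8 * 7), 8) + slope * rep(1:7, each = 8)
      sm <- toy_summaries(vals, "positive")
      trend_test(sm, "efficacy", "positive", n_perm = 199,
                 seed = sample.int(1e6, 1))$p_value < 0.05
    }))
  }
  rates <- vapply(c(0, 0.25, 0.6), reject_rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.2)
  expect_gt(rates[3], 0.8)
})

test_that("every permutation p respects the add-one lower bound", {
  vals <- matrix(rep(1:7, 2), nrow = 2, byrow = TRUE)
  sm <- paired_toy_summaries(vals, vals[, 7:1])
  res <- list(
    trend_test(sm, "efficacy", "positive", n_perm = 99, seed = 1),
    trend_difference_test(sm, "efficacy", n_perm = 99, seed = 1),
    pairwise_gap_test(sm, "efficacy", 6, -6, scenario_a = "positive",
                      n_perm = 99, seed = 1)
  )
  for (r in res) {
    expect_gte(r$p_value, 1 / 100)
    expect_lte(r$p_value, 1)
  }
})
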