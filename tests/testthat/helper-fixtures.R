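# Small-scale fixtures and independent oracles used across the suite.

# Short schedule so generator-based tests stay fast; structure (7 momentum
# sections, 2 s gap steps) is unchanged.
small_schedule <- function(direction = "positive", section = 5,
                           priming = 4, completion = 2) {
  build_schedule(direction, momentum_section_duration = section,
                 priming_duration = priming, completion_duration = completion)
}

# Generator config at reduced sampling rate; override any field via ...
small_config <- function(seed = 1, n_teams = 2, sample_rate = 20, ...) {
  generator_config(n_teams = n_teams, sample_rate = sample_rate,
                   seed = seed, ...)
}

# Config with every noise source and trend switched off (deterministic
# signals, exchangeable-by-construction item/force structure).
quiet_config <- function(seed = 1, n_teams = 1, sample_rate = 20,
                         offset_mean = 0, ...) {
  defaults <- list(
    n_teams = n_teams, sample_rate = sample_rate, seed = seed,
    phase_offset_mean = list(positive = rep(offset_mean, 7),
                             negative = rep(offset_mean, 7)),
    phase_offset_sd = list(positive = rep(0, 7), negative = rep(0, 7)),
    force_slope = list(positive = 0, negative = 0),
    force_noise_sd = 0, pos_noise_sd = 0,
    item_slope = list(positive = c(efficacy = 0, cohesion = 0),
                      negative = c(efficacy = 0, cohesion = 0)),
    item_noise_sd = 0, team_power_sdlog = 0, team_phase_sd = 0)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# Null-model generator: flat trends, noisy items/forces/offsets, so section
# summaries are exchangeable across sections within each session.
null_config <- function(seed, n_teams = 8, sample_rate = 20) {
  generator_config(
    n_teams = n_teams, sample_rate = sample_rate, seed = seed,
    phase_offset_mean = list(positive = rep(5, 7), negative = rep(5, 7)),
    phase_offset_sd = list(positive = rep(4, 7), negative = rep(4, 7)),
    force_baseline = list(positive = 150, negative = 150),
    force_slope = list(positive = 0, negative = 0),
    item_baseline = list(positive = c(efficacy = 5, cohesion = 5),
                         negative = c(efficacy = 5, cohesion = 5)),
    item_slope = list(positive = c(efficacy = 0, cohesion = 0),
                      negative = c(efficacy = 0, cohesion = 0)))
}

# Build a section-summary tibble directly from a teams x sections matrix of
# one measure (inference tests don't need the signal pipeline).
toy_summaries <- function(values, direction = "positive",
                          measure = "efficacy") {
  k <- ncol(values)
  n <- nrow(values)
  gaps <- if (k == 7) seq(-6, 6, 2) else seq_len(k)
  if (direction == "negative" && k == 7) gaps <- rev(gaps)
  df <- tidyr::expand_grid(team_id = seq_len(n), section = seq_len(k))
  df$direction <- direction
  df$gap <- gaps[df$section]
  df[[measure]] <- as.numeric(t(values))
  df
}

paired_toy_summaries <- function(pos, neg, measure = "efficacy") {
  dplyr::bind_rows(toy_summaries(pos, "positive", measure),
                   toy_summaries(neg, "negative", measure))
}

# ---- independent brute-force oracles -------------------------------------

mean_slope <- function(m) {
  k <- ncol(m)
  cc <- seq_len(k) - (k + 1) / 2
  mean(as.numeric(m %*% cc) / sum(cc^2))
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Exhaustive two-sided trend p over all joint within-team orderings.
oracle_trend_p <- function(m) {
  perms <- all_permutations(ncol(m))
  per_team <- lapply(seq_len(nrow(m)), function(i) {
    apply(perms, 1, function(p) m[i, p])   # sections x n_perms
  })
  idx <- expand.grid(rep(list(seq_len(nrow(perms))), nrow(m)))
  obs <- mean_slope(m)
  stats <- apply(idx, 1, function(j) {
    mm <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) per_team[[i]][, j[i]]))
    mean_slope(mm)
  })
  mean(abs(stats) >= abs(obs) - 1e-12)
}

all_sign_vectors <- function(n) {
  as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
}

# Exhaustive two-sided p for a within-team sign-flip statistic mean(d * s).
oracle_signflip_p <- function(d) {
  s <- all_sign_vectors(length(d))
  stats <- as.numeric(s %*% d) / length(d)
  mean(abs(stats) >= abs(mean(d)) - 1e-12)
}

# Exhaustive combined coordination p: joint sign flips over both metrics,
# rank-based per-metric p-hats within the full enumeration, Fisher combined,
# one-sided in the quality direction.
oracle_combined_p <- function(q_phi, q_sd) {
  s <- all_sign_vectors(length(q_phi))
  n <- nrow(s)
  null_phi <- as.numeric(s %*% q_phi) / length(q_phi)
  null_sd <- as.numeric(s %*% q_sd) / length(q_sd)
  p_hat <- function(null, x) {
    vapply(x, function(v) mean(null >= v - 1e-12), numeric(1))
  }
  fisher <- function(p1, p2) -2 * (log(p1) + log(p2))
  c_obs <- fisher(p_hat(null_phi, mean(q_phi)), p_hat(null_sd, mean(q_sd)))
  c_null <- fisher(p_hat(null_phi, null_phi), p_hat(null_sd, null_sd))
  mean(c_null >= c_obs - 1e-12)
}

# Monte Carlo p consistent with an exhaustive p within 2 binomial SEs
# (both use add-one estimators on the sampled side).
expect_mc_close <- function(p_mc, p_exact, n_perm) {
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(p_mc - p_exact), 2 * se + 2 / n_perm)
}
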