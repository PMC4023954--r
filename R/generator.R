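#' Configuration for the synthetic session generator
#'
#' Defines the statistical structure of simulated two-rower ergometer
#' sessions: coupled quasi-periodic handle kinematics, stroke-locked force
#' pulses with section-level trends, and integer 9-point item responses
#' (collective efficacy, task cohesion) with scenario-dependent trends.
#' Per-section parameters are vectors of length 7, one per momentum
#' section in time order (section 1 is the first momentum section of the
#' session, regardless of its displayed gap).
#'
#' Default trends mimic the ranges observed in the original eight-team
#' experiment: efficacy rising roughly 4.4 to 7.6 under positive momentum
#' and falling 7.9 to 3.1 under negative momentum, mean force near 145 N
#' with a mild decline under positive momentum and a steeper decline under
#' negative momentum, small mean relative-phase offsets (about 5 degrees)
#' and a relative-phase variability that shrinks during positive momentum
#' and grows slightly during negative momentum.
#'
#' @param n_teams Number of teams (default 8).
#' @param stroke_rate Stroke frequency, Hz (default 0.5, i.e. 30
#'   strokes/min).
#' @param sample_rate Sampling rate of the kinematic and force channels, Hz
#'   (default 100).
#' @param stroke_length Peak-to-peak handle excursion, cm (default 150).
#' @param phase_offset_mean,phase_offset_sd Named lists (`positive`,
#'   `negative`) of length-7 vectors: per-section mean and SD (degrees) of
#'   rower 2's phase lag behind rower 1. The instantaneous lag wanders
#'   smoothly within each section with this mean and SD.
#' @param force_baseline,force_slope Named lists (`positive`, `negative`):
#'   section-1 team mean force (N) and its change per section (N/section).
#' @param force_noise_sd Additive force noise SD, N.
#' @param pos_noise_sd Additive position measurement noise SD, cm.
#' @param item_baseline,item_slope Named lists (`positive`, `negative`) of
#'   named vectors `c(efficacy=, cohesion=)`: section-1 expected response
#'   and change per section on the 1-9 scale.
#' @param item_noise_sd Item response noise SD before rounding/clipping.
#' @param team_power_sdlog SD (log scale) of the per-team lognormal force
#'   multiplier (team heterogeneity in power).
#' @param team_phase_sd SD (degrees) of the per-team baseline phase offset.
#' @param calibration List with `newtons_per_volt`, `volts_intercept`
#'   (N = slope * V + intercept) and `cm_per_pixel`; raw volt and pixel
#'   channels are generated by inverting these transforms.
#' @param seed Master seed; identical seed and config give bit-identical
#'   datasets, and each team/session has its own substream.
#' @return A `generator_config` object (validated list).
#' @export
generator_config <- function(
    n_teams = 8,
    stroke_rate = 0.5,
    sample_rate = 100,
    stroke_length = 150,
    phase_offset_mean = list(positive = rep(5, 7), negative = rep(6, 7)),
    phase_offset_sd = list(positive = seq(6, 3, length.out = 7),
                           negative = seq(4.5, 5.5, length.out = 7)),
    force_baseline = list(positive = 156, negative = 157.5),
    force_slope = list(positive = -1.7, negative = -3.1),
    force_noise_sd = 5,
    pos_noise_sd = 0.1,
    item_baseline = list(positive = c(efficacy = 4.4, cohesion = 6.4),
                         negative = c(efficacy = 7.9, cohesion = 7.9)),
    item_slope = list(positive = c(efficacy = 0.52, cohesion = 0.22),
                      negative = c(efficacy = -0.80, cohesion = -0.51)),
    item_noise_sd = 0.7,
    team_power_sdlog = 0.06,
    team_phase_sd = 2,
    calibration = list(newtons_per_volt = 200, volts_intercept = 0,
                       cm_per_pixel = 0.15),
    seed = 1L) {
  cfg <- list(n_teams = n_teams, stroke_rate = stroke_rate,
              sample_rate = sample_rate, stroke_length = stroke_length,
              phase_offset_mean = phase_offset_mean,
              phase_offset_sd = phase_offset_sd,
              force_baseline = force_baseline, force_slope = force_slope,
              force_noise_sd = force_noise_sd, pos_noise_sd = pos_noise_sd,
              item_baseline = item_baseline, item_slope = item_slope,
              item_noise_sd = item_noise_sd,
              team_power_sdlog = team_power_sdlog,
              team_phase_sd = team_phase_sd,
              calibration = calibration, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_teams < 1) stop("momentumdyn_config: n_teams must be >= 1", call. = FALSE)
  if (cfg$stroke_rate <= 0 || cfg$sample_rate <= 0) {
    stop("momentumdyn_config: rates must be positive", call. = FALSE)
  }
  for (dir in c("positive", "negative")) {
    if (length(cfg$phase_offset_mean[[dir]]) != 7L ||
        length(cfg$phase_offset_sd[[dir]]) != 7L) {
      stop("momentumdyn_config: per-section phase parameters must have length 7",
           call. = FALSE)
    }
    if (any(cfg$phase_offset_sd[[dir]] < 0)) {
      stop("momentumdyn_config: phase_offset_sd must be >= 0", call. = FALSE)
    }
    ib <- cfg$item_baseline[[dir]]
    if (any(ib < 1 | ib > 9)) {
      stop("momentumdyn_config: item_baseline must lie in [1, 9]", call. = FALSE)
    }
  }
  if (cfg$force_noise_sd < 0 || cfg$item_noise_sd < 0 ||
      cfg$team_power_sdlog < 0 || cfg$team_phase_sd < 0) {
    stop("momentumdyn_config: noise SDs must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic substream seed; keeps every derived seed inside 32-bit range
# so each team/session/stage has an independent, reproducible stream.
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% 2147483629
  as.integer(h + 1)
}

# Smooth unit-SD noise: low-pass filtered white noise rescaled. Used for the
# slowly wandering phase lag between the two rowers.
smooth_noise <- function(n, fs, cutoff = 0.2) {
  if (n < 30) return(rep(0, n))
  z <- stats::rnorm(n)
  bf <- signal::butter(2, min(cutoff / (fs / 2), 0.9), type = "low")
  zs <- signal::filtfilt(bf, z)
  s <- stats::sd(zs)
  if (s == 0) rep(0, n) else (zs - mean(zs)) / s
}

# Asymmetric stroke waveform on [0, 2pi): drive faster than recovery, smooth
# and band-limited so phase extraction has a clean fundamental.
stroke_waveform <- function(theta, skew = 0.3) {
  sin(theta + skew * sin(theta))
}

#' Generate one synthetic team session
#'
#' Rower 1's handle position is a noisy asymmetric stroke waveform at the
#' configured stroke rate; rower 2 follows the same waveform lagged by a
#' per-section phase offset that wanders smoothly within each momentum
#' section (mean `phase_offset_mean[s]`, SD `phase_offset_sd[s]` for the
#' session's scenario). Forces are nonnegative pulse trains locked to each
#' rower's drive, with section mean force following the configured
#' baseline-plus-slope trend times the team's power multiplier. Item
#' responses are `round(clip(baseline + slope * (section - 1) + noise))`
#' per rower. Raw volt/pixel channels are generated by inverting the
#' calibration transforms.
#'
#' @param config A [generator_config()].
#' @param schedule A [build_schedule()] scenario schedule.
#' @param team_id Team identifier (integer or string).
#' @param team_effects Optional list with `power` (force multiplier) and
#'   `phase` (baseline phase offset, degrees), drawn once per team by
#'   [generate_cohort()]; if `NULL`, drawn from the session's own stream.
#' @return A `team_session` object: `team_id`, `direction`, `schedule`,
#'   `sample_rate`, `t`, `pos_cm` / `force_N` (n x 2 matrices),
#'   `pos_pix` / `force_V` raw counterparts, and `items` (tibble: rower,
#'   section, gap, efficacy, cohesion).
#' @export
generate_session <- function(config, schedule, team_id, team_effects = NULL) {
  stopifnot(inherits(config, "generator_config"), inherits(schedule, "tg_schedule"))
  validate_generator_config(config)
  dir <- schedule$direction
  fs <- config$sample_rate
  n <- round(schedule$session_length * fs)
  t <- (seq_len(n) - 1) / fs

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(derive_seed(config$seed, "session", team_id, dir))

  if (is.null(team_effects)) {
    team_effects <- list(
      power = stats::rlnorm(1, 0, config$team_power_sdlog),
      phase = stats::rnorm(1, 0, config$team_phase_sd)
    )
  }

  # per-sample momentum section index (NA in priming/completion)
  mseg <- momentum_segments(schedule)
  sec <- findInterval(t, mseg$t_start)
  sec[t >= mseg$t_end[7L] | t < mseg$t_start[1L]] <- NA_integer_
  sec_ext <- sec                        # extended: clamp priming/completion
  sec_ext[t < mseg$t_start[1L]] <- 1L
  sec_ext[t >= mseg$t_end[7L]] <- 7L

  # kinematics -------------------------------------------------------------
  theta1 <- 2 * pi * config$stroke_rate * t
  off_mean <- config$phase_offset_mean[[dir]][sec_ext] + team_effects$phase
  off_sd <- config$phase_offset_sd[[dir]][sec_ext]
  offset_deg <- off_mean + off_sd * smooth_noise(n, fs)
  theta2 <- theta1 - offset_deg * pi / 180

  amp <- config$stroke_length / 2
  pos1 <- amp * stroke_waveform(theta1) + stats::rnorm(n, 0, config$pos_noise_sd)
  pos2 <- amp * stroke_waveform(theta2) + stats::rnorm(n, 0, config$pos_noise_sd)

  # force ------------------------------------------------------------------
  target <- (config$force_baseline[[dir]] +
               config$force_slope[[dir]] * (sec_ext - 1)) * team_effects$power
  pulse1 <- pmax(0, sin(theta1))^2     # drive-locked pulse, cycle mean 1/4
  pulse2 <- pmax(0, sin(theta2))^2
  f1 <- pmax(0, 4 * target * pulse1 + stats::rnorm(n, 0, config$force_noise_sd))
  f2 <- pmax(0, 4 * target * pulse2 + stats::rnorm(n, 0, config$force_noise_sd))

  # items ------------------------------------------------------------------
  items <- tidyr::expand_grid(rower = 1:2, section = 1:7)
  for (m in c("efficacy", "cohesion")) {
    mu <- config$item_baseline[[dir]][[m]] +
      config$item_slope[[dir]][[m]] * (items$section - 1)
    items[[m]] <- pmin(9L, pmax(1L, as.integer(round(
      mu + stats::rnorm(nrow(items), 0, config$item_noise_sd)))))
  }
  items$gap <- mseg$gap[items$section]

  cal <- config$calibration
  structure(
    list(team_id = team_id, direction = dir, schedule = schedule,
         sample_rate = fs, t = t,
         pos_cm = cbind(pos1, pos2, deparse.level = 0),
         force_N = cbind(f1, f2, deparse.level = 0),
         pos_pix = cbind(pos1, pos2, deparse.level = 0) / cal$cm_per_pixel,
         force_V = (cbind(f1, f2, deparse.level = 0) - cal$volts_intercept) /
           cal$newtons_per_volt,
         items = items[, c("rower", "section", "gap", "efficacy", "cohesion")],
         team_effects = team_effects),
    class = "team_session"
  )
}

#' @export
print.team_session <- function(x, ...) {
  cat(sprintf("<team_session> team %s, %s momentum, %d samples @ %g Hz\n",
              x$team_id, x$direction, length(x$t), x$sample_rate))
  invisible(x)
}

#' Generate a full cohort: one positive and one negative session per team
#'
#' Per-team random effects (power multiplier, baseline phase offset) are
#' drawn once per team so the cohort is heterogeneous between teams but
#' consistent within each team's pair of sessions — the structure the
#' within-team permutation tests assume.
#'
#' @param config A [generator_config()].
#' @param schedule_positive,schedule_negative Scenario schedules; defaults
#'   are the standard [build_schedule()] schedules.
#' @return List of `2 * n_teams` `team_session` objects (positive then
#'   negative per team), with the config attached as an attribute.
#' @export
generate_cohort <- function(config,
                            schedule_positive = build_schedule("positive"),
                            schedule_negative = build_schedule("negative")) {
  stopifnot(inherits(config, "generator_config"))
  sessions <- vector("list", 2L * config$n_teams)
  for (k in seq_len(config$n_teams)) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(derive_seed(config$seed, "team", k))
    eff <- list(power = stats::rlnorm(1, 0, config$team_power_sdlog),
                phase = stats::rnorm(1, 0, config$team_phase_sd))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    sessions[[2L * k - 1L]] <- generate_session(config, schedule_positive, k, eff)
    sessions[[2L * k]] <- generate_session(config, schedule_negative, k, eff)
  }
  attr(sessions, "config") <- config
  sessions
}

#' Write a cohort to plain-text files
#'
#' One CSV per session (`t, pos1_cm, pos2_cm, force1_N, force2_N`), a
#' combined `items.csv`, and a `manifest.json` describing the sessions.
#'
#' @param sessions List of `team_session` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(sessions, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list()
  items <- list()
  for (s in sessions) {
    fn <- sprintf("session_team%s_%s.csv", s$team_id, s$direction)
    df <- data.frame(t = s$t,
                     pos1_cm = s$pos_cm[, 1], pos2_cm = s$pos_cm[, 2],
                     force1_N = s$force_N[, 1], force2_N = s$force_N[, 2])
    utils::write.csv(df, file.path(dir, fn), row.names = FALSE)
    manifest[[length(manifest) + 1L]] <-
      list(team = s$team_id, direction = s$direction, file = fn,
           sample_rate = s$sample_rate)
    it <- s$items
    it$team <- s$team_id
    it$direction <- s$direction
    items[[length(items) + 1L]] <- it
  }
  utils::write.csv(dplyr::bind_rows(items), file.path(dir, "items.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
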