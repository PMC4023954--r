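zch <- function(x, fs = 100) standardize(channel(x, fs, "cm"))
interior <- function(ps) ps$relative_phase[!ps$trimmed]

test_that("calibration transforms are the declared affine maps", {
  v <- channel(c(1, 2, 3), 100, "V")
  expect_equal(volts_to_newtons(v, 100, 5)$samples, c(105, 205, 305))
  expect_equal(volts_to_newtons(channel(0, 100, "V"), 100, 0)$samples, 0)
  expect_equal(volts_to_newtons(v, 100, 5)$unit, "N")

  px <- channel(c(0, 10), 100, "pix")
  expect_equal(pixels_to_cm(px, 0.15)$samples, c(0, 1.5))

  expect_error(volts_to_newtons(px, 100, 0), "momentumdyn_wrong_unit")
  expect_error(pixels_to_cm(v, 0.15), "momentumdyn_wrong_unit")
})

test_that("calibration round-trips the generator's raw channels", {
  s <- generate_session(small_config(seed = 8), small_schedule("positive"), 1)
  cal <- small_config()$calibration
  f1 <- volts_to_newtons(channel(s$force_V[, 1], s$sample_rate, "V"),
                         cal$newtons_per_volt, cal$volts_intercept)
  expect_equal(f1$samples, s$force_N[, 1], tolerance = 1e-12)
  p2 <- pixels_to_cm(channel(s$pos_pix[, 2], s$sample_rate, "pix"),
                     cal$cm_per_pixel)
  expect_equal(p2$samples, s$pos_cm[, 2], tolerance = 1e-12)
})

test_that("low-pass filter has unit DC gain and clean passband", {
  const <- channel(rep(3.7, 500), 100, "cm")
  expect_equal(lowpass_filter(const)$samples, rep(3.7, 500), tolerance = 1e-9)

  t <- (0:4999) / 100
  x <- sin(2 * pi * 0.5 * t)
  y <- lowpass_filter(channel(x, 100, "cm"))$samples
  mid <- 500:4500
  fit <- lm(y[mid] ~ x[mid])           # passband: gain ~ 1, no phase lag
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.01)
  expect_lt(summary(fit)$sigma, 0.01)
})

test_that("stopband attenuation matches the bidirectional Butterworth magnitude", {
  fs <- 100; fc <- 4; f_hi <- 20; ord <- 2
  t <- (0:9999) / fs
  x <- sin(2 * pi * 0.5 * t) + sin(2 * pi * f_hi * t)
  y <- lowpass_filter(channel(x, fs, "cm"), cutoff = fc, order = ord)$samples
  mid <- 1000:9000
  # residual 20 Hz amplitude by quadrature regression
  base <- sin(2 * pi * 0.5 * t[mid])
  c20 <- cos(2 * pi * f_hi * t[mid]); s20 <- sin(2 * pi * f_hi * t[mid])
  co <- coef(lm(y[mid] ~ base + s20 + c20))
  amp <- sqrt(co["s20"]^2 + co["c20"]^2)
  # closed-form digital Butterworth magnitude (prewarped), squared for the
  # forward-backward pass
  r <- tan(pi * f_hi / fs) / tan(pi * fc / fs)
  expected <- 1 / (1 + r^(2 * ord))
  expect_equal(unname(amp), expected, tolerance = 0.05 * expected)
})

test_that("filter rejects unusable inputs", {
  expect_error(lowpass_filter(channel(rnorm(100), 7, "cm"), cutoff = 4),
               "momentumdyn_filter_rate")
  expect_error(lowpass_filter(channel(rnorm(10), 100, "cm")),
               "momentumdyn_series_too_short")
})

test_that("standardize gives exact z-scores, is affine-invariant and idempotent", {
  ch <- channel(1:5, 100, "cm")
  z <- standardize(ch)
  expect_equal(mean(z$samples), 0)
  expect_equal(sd(z$samples), 1)
  expect_equal(z$unit, "z-score")

  x <- rnorm(200)
  expect_equal(standardize(channel(3 * x + 7, 50, "cm"))$samples,
               standardize(channel(x, 50, "cm"))$samples, tolerance = 1e-12)
  expect_equal(standardize(z)$samples, z$samples, tolerance = 1e-12)
  expect_error(standardize(channel(rep(1, 10), 100, "cm")),
               "momentumdyn_zero_variance")
})

test_that("relative phase recovers closed forms for sinusoid pairs", {
  t <- (0:9999) / 100
  w <- 2 * pi * 0.5
  expect_equal(max(abs(interior(relative_phase(zch(sin(w * t)), zch(sin(w * t)))))),
               0, tolerance = 1e-9)

  quad <- relative_phase(zch(sin(w * t)), zch(cos(w * t)))
  expect_equal(mean(interior(quad)), -90, tolerance = 1)

  for (f in c(0.3, 0.5, 0.8)) {
    wf <- 2 * pi * f
    lag <- relative_phase(zch(sin(wf * t)), zch(sin(wf * t - 37 * pi / 180)))
    expect_lt(max(abs(interior(lag) - 37)), 1)
  }
})

test_that("relative phase is antisymmetric, amplitude-invariant and wrapped", {
  t <- (0:4999) / 100
  a <- sin(2 * pi * 0.5 * t) + 0.1 * sin(2 * pi * 1.5 * t)
  b <- sin(2 * pi * 0.5 * t - 0.9)
  ab <- relative_phase(zch(a), zch(b))
  ba <- relative_phase(zch(b), zch(a))
  expect_equal(ab$relative_phase, -ba$relative_phase, tolerance = 1e-9)
  expect_true(all(abs(ab$relative_phase) <= 180))

  scaled <- relative_phase(zch(25 * a), zch(b))
  expect_equal(scaled$relative_phase, ab$relative_phase, tolerance = 1e-9)

  expect_error(relative_phase(zch(a), zch(b[-1])),
               "momentumdyn_length_mismatch")
  expect_error(relative_phase(channel(a, 100, "cm"), zch(b)),
               "momentumdyn_wrong_unit")
})

test_that("analytic-signal phase agrees with a peak-timing oracle", {
  f <- 0.5; fs <- 100
  t <- (0:5999) / fs
  lag_deg <- 24
  x1 <- sin(2 * pi * f * t)
  x2 <- sin(2 * pi * f * t - lag_deg * pi / 180)
  ps <- relative_phase(zch(x1), zch(x2))

  # oracle: discrete relative phase from stroke peak timings
  peaks <- function(x) which(diff(sign(diff(x))) == -2) + 1
  p1 <- peaks(x1); p2 <- peaks(x2)
  p1 <- p1[p1 > 300 & p1 < 5700]
  nearest <- vapply(p1, function(k) p2[which.min(abs(p2 - k))], numeric(1))
  oracle <- 360 * f * (nearest - p1) / fs
  expect_lt(max(abs(ps$relative_phase[p1] - oracle)), 5)
})

test_that("edge trimming flags the configured fraction at both ends", {
  t <- (0:999) / 100
  ps <- relative_phase(zch(sin(2 * pi * t)), zch(cos(2 * pi * t)),
                       trim_fraction = 0.1)
  expect_equal(sum(ps$trimmed), 200)
  expect_true(all(ps$trimmed[1:100]), all(ps$trimmed[901:1000]))
  ps0 <- relative_phase(zch(sin(2 * pi * t)), zch(cos(2 * pi * t)),
                        trim_fraction = 0)
  expect_false(any(ps0$trimmed))
})
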