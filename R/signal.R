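#' Create a signal channel
#'
#' Lightweight container for one uniformly sampled series with an explicit
#' unit, so calibration transforms can enforce that they are applied to the
#' right raw channel.
#'
#' @param samples Numeric vector.
#' @param sample_rate Sampling rate, Hz.
#' @param unit One of `"V"`, `"N"`, `"pix"`, `"cm"`, `"z-score"`.
#' @return A `channel` object.
#' @export
channel <- function(samples, sample_rate,
                    unit = c("V", "N", "pix", "cm", "z-score")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(samples), is.numeric(sample_rate), sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 unit = unit),
            class = "channel")
}

#' @export
print.channel <- function(x, ...) {
  cat(sprintf("<channel> %d samples @ %g Hz [%s]\n",
              length(x$samples), x$sample_rate, x$unit))
  invisible(x)
}

check_unit <- function(ch, expected) {
  if (!inherits(ch, "channel")) {
    stop("momentumdyn_not_a_channel: expected a channel object", call. = FALSE)
  }
  if (ch$unit != expected) {
    stop(sprintf("momentumdyn_wrong_unit: expected a '%s' channel, got '%s'",
                 expected, ch$unit), call. = FALSE)
  }
  invisible(ch)
}

#' Calibrate a force channel from volts to newtons
#'
#' Applies the sensor manufacturer's affine calibration `N = slope * V +
#' intercept`.
#'
#' @param raw A `channel` in volts.
#' @param slope Newtons per volt.
#' @param intercept Offset in newtons (default 0).
#' @return A `channel` in newtons, same length and rate.
#' @export
volts_to_newtons <- function(raw, slope, intercept = 0) {
  check_unit(raw, "V")
  channel(slope * raw$samples + intercept, raw$sample_rate, "N")
}

#' Calibrate a position channel from camera pixels to centimeters
#'
#' @param raw A `channel` in pixels.
#' @param cm_per_pixel Scale factor, cm per pixel.
#' @return A `channel` in centimeters.
#' @export
pixels_to_cm <- function(raw, cm_per_pixel) {
  check_unit(raw, "pix")
  channel(cm_per_pixel * raw$samples, raw$sample_rate, "cm")
}

#' Zero-phase Butterworth low-pass filter for kinematic channels
#'
#' A Butterworth low-pass (default 2nd order, 4 Hz cut-off) applied
#' forward and backward (`signal::filtfilt`), so the net phase shift is
#' zero: phase distortion here would bias the relative-phase estimate
#' downstream. Force channels are calibrated but never filtered.
#'
#' @param pos A position `channel` (cm).
#' @param cutoff Cut-off frequency, Hz (default 4).
#' @param order Filter order of each pass (default 2).
#' @return Filtered `channel`, same unit, length and rate.
#' @export
lowpass_filter <- function(pos, cutoff = 4, order = 2) {
  check_unit(pos, "cm")
  fs <- pos$sample_rate
  if (fs <= 2 * cutoff) {
    stop("momentumdyn_filter_rate: sample rate must exceed twice the cut-off",
         call. = FALSE)
  }
  # filtfilt needs a record comfortably longer than the filter warm-up
  if (length(pos$samples) <= 6 * (order + 1)) {
    stop("momentumdyn_series_too_short: record shorter than filter warm-up",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (DC gain stays exactly 1)
  x <- pos$samples
  n <- length(x)
  pad <- min(n - 1L, 3L * (2L * order + 1L) * max(1L, ceiling(fs / cutoff)))
  front <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  back <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(front, x, back))
  channel(y[(pad + 1L):(pad + n)], fs, pos$unit)
}

#' Standardize a channel to zero mean and unit SD
#'
#' @param pos A `channel` with nonzero variance.
#' @return A z-score `channel`.
#' @export
standardize <- function(pos) {
  if (!inherits(pos, "channel")) {
    stop("momentumdyn_not_a_channel: expected a channel object", call. = FALSE)
  }
  s <- stats::sd(pos$samples)
  if (!is.finite(s) || s == 0) {
    stop("momentumdyn_zero_variance: cannot standardize a constant series",
         call. = FALSE)
  }
  channel((pos$samples - mean(pos$samples)) / s, pos$sample_rate, "z-score")
}

#' Analytic signal via the frequency-domain construction
#'
#' Pairs a real series with its quadrature component: the spectrum's
#' negative frequencies are zeroed and positive frequencies doubled, so the
#' imaginary part of the inverse transform is the Hilbert transform of the
#' input. Instantaneous phase is the complex argument of the result.
#'
#' @param x Numeric vector.
#' @return Complex vector, same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Wrap angles in degrees to (-180, 180]
#'
#' @param deg Numeric vector of angles, degrees.
#' @return Wrapped angles.
#' @export
wrap_degrees <- function(deg) {
  w <- deg - 360 * floor(deg / 360)   # [0, 360)
  ifelse(w > 180, w - 360, w)
}

#' Continuous relative phase of a dyad via the analytic signal
#'
#' Computes each rower's instantaneous phase phi_i(t) as the argument of the
#' analytic signal of the standardized kinematic series, and the continuous
#' relative phase phi(t) = phi1(t) - phi2(t), wrapped to (-180, 180]
#' degrees. If rower 2's movement lags rower 1's by a phase delta, the
#' relative phase is +delta. A fraction of samples at each end of the
#' record (default 5%) is flagged as trimmed because analytic-signal phase
#' estimates are unreliable at record edges; section summaries exclude
#' flagged samples.
#'
#' @param pos1,pos2 Standardized (`z-score`) channels of equal length and
#'   rate; rower 1 is the first channel.
#' @param trim_fraction Fraction of samples flagged at each end (default
#'   0.05).
#' @return A `phase_series` object: list with `phi1`, `phi2`,
#'   `relative_phase` (degrees), `sample_rate`, and logical `trimmed`.
#' @export
relative_phase <- function(pos1, pos2, trim_fraction = 0.05) {
  check_unit(pos1, "z-score")
  check_unit(pos2, "z-score")
  n <- length(pos1$samples)
  if (n != length(pos2$samples) || pos1$sample_rate != pos2$sample_rate) {
    stop("momentumdyn_length_mismatch: channels must share length and rate",
         call. = FALSE)
  }
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)

  phi1 <- Arg(analytic_signal(pos1$samples)) * 180 / pi
  phi2 <- Arg(analytic_signal(pos2$samples)) * 180 / pi
  rel <- wrap_degrees(phi1 - phi2)

  n_trim <- floor(n * trim_fraction)
  trimmed <- rep(FALSE, n)
  if (n_trim > 0) trimmed[c(seq_len(n_trim), n - seq_len(n_trim) + 1L)] <- TRUE

  structure(
    list(phi1 = phi1, phi2 = phi2, relative_phase = rel,
         sample_rate = pos1$sample_rate, trimmed = trimmed),
    class = "phase_series"
  )
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples @ %g Hz, %d trimmed\n",
              length(x$relative_phase), x$sample_rate, sum(x$trimmed)))
  invisible(x)
}

#' Full kinematic processing for one session
#'
#' Filter (zero-phase Butterworth), standardize, and extract the continuous
#' relative phase from a session's two position channels.
#'
#' @param session A [generate_session()] object.
#' @param cutoff,order Low-pass settings, see [lowpass_filter()].
#' @param trim_fraction Edge-trim fraction, see [relative_phase()].
#' @return A `phase_series` object.
#' @export
process_session <- function(session, cutoff = 4, order = 2,
                            trim_fraction = 0.05) {
  stopifnot(inherits(session, "team_session"))
  fs <- session$sample_rate
  ch <- lapply(1:2, function(i) {
    standardize(lowpass_filter(channel(session$pos_cm[, i], fs, "cm"),
                               cutoff = cutoff, order = order))
  })
  relative_phase(ch[[1]], ch[[2]], trim_fraction = trim_fraction)
}
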