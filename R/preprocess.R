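#' Butterworth filtering of a time series
#'
#' Designs a Butterworth filter with [signal::butter()] and applies it
#' either causally (single forward pass) or in zero-lag mode (forward then
#' backward, cancelling phase shift and squaring the magnitude response, so
#' the gain at the cutoff is 0.5 instead of 1/sqrt(2)). Zero-lag mode pads
#' the signal by odd reflection over 3 x `order` samples at each end to
#' suppress startup transients.
#'
#' @param series A [belt_ts()] object, longer than `3 * order` samples.
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff Cutoff frequency in Hz, below Nyquist.
#' @param order Filter order (default 2, as used throughout the pipeline).
#' @param zero_lag Apply forward-backward (zero-phase) filtering?
#' @return A filtered [belt_ts()] with unchanged rate and length.
#' @export
butterworth_filter <- function(series, kind = c("lowpass", "highpass"),
                               cutoff, order = 2L, zero_lag = FALSE) {
  stopifnot(inherits(series, "belt_ts"))
  kind <- match.arg(kind)
  if (!is.finite(cutoff) || cutoff <= 0)
    stop("filter spec error: cutoff must be positive")
  if (cutoff >= series$rate / 2)
    stop(sprintf("filter spec error: cutoff %g Hz is at or above Nyquist (%g Hz)",
                 cutoff, series$rate / 2))
  if (order < 1L) stop("filter spec error: order must be >= 1")
  n <- length(series$values)
  if (n <= 3L * order)
    stop(sprintf("series too short for filtering: %d samples, need > %d", n, 3L * order))
  bt <- signal::butter(order, cutoff / (series$rate / 2),
                       type = if (kind == "lowpass") "low" else "high")
  y <- apply_filter(bt, series$values, zero_lag = zero_lag, order = order)
  ts_with(series, y)
}

# forward (causal) or forward-backward (zero-lag) IIR application.
# Causal mode references the filter state to the first sample (subtract
# x[1], filter, add back x[1] times the DC gain) so a step at t=0 does not
# ring through the zero initial state; zero-lag mode pads by odd reflection
# over 3 x order samples.
apply_filter <- function(bt, x, zero_lag, order) {
  run <- function(v) {
    dc <- sum(bt$b) / sum(bt$a)
    as.numeric(signal::filter(bt, v - v[1])) + v[1] * dc
  }
  if (!zero_lag) return(run(x))
  n <- length(x)
  pad <- min(n - 1L, 3L * order)
  left <- 2 * x[1] - x[seq(pad + 1L, 2L, by = -1L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad, by = -1L)]
  ext <- c(left, x, right)
  y <- rev(run(rev(run(ext))))
  y[seq(pad + 1L, pad + n)]
}

#' Full-wave rectification
#'
#' Element-wise absolute value, the standard step between high-pass
#' filtering and envelope extraction of surface EMG.
#'
#' @param series A [belt_ts()] object.
#' @return Rectified [belt_ts()].
#' @export
full_wave_rectify <- function(series) {
  stopifnot(inherits(series, "belt_ts"))
  ts_with(series, abs(series$values))
}

#' Surface-EMG linear envelope
#'
#' The envelope chain applied to every raw EMG channel: high-pass at 20 Hz
#' (2nd-order zero-lag Butterworth, removes motion artefact and DC), full-wave
#' rectification, then low-pass at 10 Hz (2nd-order Butterworth, causal by
#' default; set `lowpass_zero_lag = TRUE` for phase-aligned analysis). Small
#' negative values introduced by the final low-pass are clipped to zero.
#'
#' @param raw A raw EMG [belt_ts()] (rate comfortably above 40 Hz).
#' @param highpass_hz,lowpass_hz Corner frequencies in Hz.
#' @param order Filter order for both filters.
#' @param lowpass_zero_lag Use zero-lag mode for the final low-pass?
#' @param clip_negative Clip negative envelope samples to zero?
#' @return Envelope [belt_ts()] (non-negative when `clip_negative`).
#' @export
emg_envelope <- function(raw, highpass_hz = 20, lowpass_hz = 10, order = 2L,
                         lowpass_zero_lag = FALSE, clip_negative = TRUE) {
  hp <- butterworth_filter(raw, "highpass", highpass_hz, order, zero_lag = TRUE)
  env <- butterworth_filter(full_wave_rectify(hp), "lowpass", lowpass_hz,
                            order, zero_lag = lowpass_zero_lag)
  if (clip_negative) env$values <- pmax(env$values, 0)
  ts_with(env, env$values, name = paste0(raw$name, "_env"))
}

#' Maximum voluntary contraction (MVC) reference per muscle
#'
#' The MVC of each muscle is the maximum of its envelope across the supplied
#' maximal co-contraction trials (static standing and sitting positions).
#'
#' @param cocontraction_envelopes Named list (one entry per muscle) of either
#'   a single envelope [belt_ts()] or a list of envelope trials.
#' @return Named numeric vector of per-muscle MVC values.
#' @export
compute_mvc <- function(cocontraction_envelopes) {
  if (!is.list(cocontraction_envelopes) || length(cocontraction_envelopes) == 0L)
    stop("need at least one co-contraction trial per muscle")
  vapply(cocontraction_envelopes, function(trials) {
    if (inherits(trials, "belt_ts")) trials <- list(trials)
    if (length(trials) == 0L) stop("empty trial list for a muscle")
    max(vapply(trials, function(tr) {
      stopifnot(inherits(tr, "belt_ts"))
      max(tr$values)
    }, numeric(1)))
  }, numeric(1))
}

#' Normalize an EMG envelope by its MVC
#'
#' @param envelope Envelope [belt_ts()].
#' @param mvc Positive scalar MVC reference for this muscle.
#' @return [belt_ts()] in fractions of MVC (may exceed 1 for supramaximal
#'   dynamic activity).
#' @export
normalize_mvc <- function(envelope, mvc) {
  stopifnot(inherits(envelope, "belt_ts"))
  if (!is.numeric(mvc) || length(mvc) != 1L || !is.finite(mvc) || mvc <= 0)
    stop("MVC must be a positive scalar")
  ts_with(envelope, envelope$values / mvc, unit = "%MVC")
}

#' Circumference and circumference velocity from belt capacitance
#'
#' Converts the capacitance channel to elastic-part length through the
#' calibration curve, low-pass filters the length at 10 Hz (2nd order,
#' causal by default), and differentiates it by central differences
#' (one-sided at the ends) to obtain the rate of circumference change.
#'
#' @param capacitance Capacitance [belt_ts()] in nF.
#' @param curve A `belt_calibration` object.
#' @param lowpass_hz Low-pass cutoff in Hz; `NA` skips filtering (useful for
#'   exact round-trip checks).
#' @param order Filter order.
#' @param zero_lag Zero-lag mode for the low-pass?
#' @return List with `length` (mm) and `velocity` (mm/s) [belt_ts()] objects.
#' @export
process_circumference <- function(capacitance, curve, lowpass_hz = 10,
                                  order = 2L, zero_lag = FALSE) {
  stopifnot(inherits(capacitance, "belt_ts"))
  len <- ts_with(capacitance,
                 capacitance_to_length(curve, capacitance$values),
                 unit = "mm", name = "circumference_mm")
  if (!is.na(lowpass_hz))
    len <- butterworth_filter(len, "lowpass", lowpass_hz, order,
                              zero_lag = zero_lag)
  list(length = len,
       velocity = ts_with(len, central_diff(len$values, len$rate),
                          unit = "mm/s", name = "circumference_velocity"))
}

# derivative by central differences, one-sided at the ends
central_diff <- function(x, rate) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  d <- numeric(n)
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d
}
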