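# shared fixture builders; everything is generated in code at test time

# calibration points lying exactly on the reference quadratic
eq_curve_points <- function(C = c(465, 500, 550, 606)) {
  cal <- default_calibration()
  data.frame(capacitance_nF = C,
             length_mm = cal$a2 * C^2 + cal$a1 * C + cal$a0)
}

# pure sinusoid as a belt_ts
sine_ts <- function(freq, rate = 1000, duration = 2, amplitude = 1, phase = 0) {
  t <- (0:(round(duration * rate) - 1)) / rate
  belt_ts(amplitude * sin(2 * pi * freq * t + phase), rate = rate)
}

# steady-state amplitude of a filtered tone, measured away from transients
# (sqrt(2) x RMS of the de-meaned tail, exact for a pure sinusoid)
tail_amplitude <- function(x, skip_frac = 0.5) {
  v <- if (inherits(x, "belt_ts")) x$values else x
  v <- v[-seq_len(floor(length(v) * skip_frac))]
  sqrt(2) * stats::sd(v)
}

# square-wave GRF with known rising edges (stance value, swing 0)
square_grf <- function(n_stance = 5, stance_n = 600, swing_n = 400,
                       level = 600, rate = 1000) {
  v <- c(rep(0, swing_n),
         rep(c(rep(level, stance_n), rep(0, swing_n)), n_stance))
  list(ts = belt_ts(v, rate = rate, unit = "N", name = "vgrf_N"),
       rises = swing_n + 1 + (0:(n_stance - 1)) * (stance_n + swing_n))
}

# brute-force least squares by the normal equations (independent oracle)
normal_eq_solve <- function(X, y)
  unname(drop(solve(crossprod(X), crossprod(X, y))))

# independent ICC(2,1) oracle via stats::aov mean squares
icc_oracle_aov <- function(x, y) {
  n <- length(x)
  d <- data.frame(score = c(x, y),
                  target = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ target + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
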