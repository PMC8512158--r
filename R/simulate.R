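#' Ground-truth cross-modal model used by the simulator
#'
#' Plausible coefficients for the quadratic activity-to-circumference map:
#' intercept near the elastic part's natural length (96.6 mm), linear terms
#' of a few mm per unit MVC with the vasti contributing most, and smaller
#' mixed-sign quadratic curvature.
#'
#' @return A `crossmodal` object.
#' @export
default_truth_model <- function() {
  crossmodal_model(w1 = c(5, 4, 6, 3, 2),
                   w2 = c(-2, 3, -1, 2, 1),
                   b = 96.6)
}

#' Default per-muscle activation templates
#'
#' Gaussian bumps (center, width, peak — center and width in percent of the
#' cycle, peak in fractions of MVC) describing plausible gait phasing:
#' quadriceps (VL, RF, VM) burst around heel contact with a smaller late
#' swing burst, hamstrings (BFL, BFS) around mid-cycle and before contact.
#' Running uses the same phasing with roughly 2.2-fold peaks; squatting a
#' single broad knee-extensor bump per repetition. These are synthetic
#' templates, not measured activation profiles.
#'
#' @param condition One of `"walk"`, `"run"`, `"squat"`.
#' @return Named list (per muscle) of data frames with columns `center`,
#'   `width`, `peak`.
#' @export
default_templates <- function(condition = c("walk", "run", "squat")) {
  condition <- match.arg(condition)
  walk <- list(
    VL  = data.frame(center = c(5, 92),  width = c(6, 5), peak = c(0.35, 0.15)),
    RF  = data.frame(center = c(8, 90),  width = c(7, 5), peak = c(0.25, 0.12)),
    VM  = data.frame(center = c(4, 93),  width = c(6, 5), peak = c(0.40, 0.15)),
    BFL = data.frame(center = c(50, 97), width = c(8, 6), peak = c(0.15, 0.35)),
    BFS = data.frame(center = c(55, 95), width = c(8, 6), peak = c(0.12, 0.30)))
  switch(condition,
    walk = walk,
    run = lapply(walk, function(d) { d$peak <- d$peak * 2.2; d }),
    squat = list(
      VL  = data.frame(center = 50, width = 18, peak = 0.70),
      RF  = data.frame(center = 50, width = 18, peak = 0.60),
      VM  = data.frame(center = 50, width = 18, peak = 0.75),
      BFL = data.frame(center = 50, width = 18, peak = 0.30),
      BFS = data.frame(center = 50, width = 18, peak = 0.25)))
}

#' Simulation configuration for one synthetic session
#'
#' Bundles every parameter of the synthetic multimodal session generator.
#' Condition presets: `"walk"` (4 km/h, 1.1 s stride, 62% stance),
#' `"run"` (12 km/h, 0.7 s stride, 35% stance), `"squat"` (4 s repetitions),
#' `"cocontraction_standing"` (one 10 s maximal tonic co-contraction),
#' `"cocontraction_sitting"` (a series of five 2 s maximal bursts),
#' `"passive"` (zero activity, five passive knee flexion oscillations).
#' Walking/running additionally take a `style`: `"neutral"`,
#' `"cocontraction"` (tonic offset added to all muscles) or `"relaxation"`
#' (swing-phase activity scaled down).
#'
#' @param condition Condition preset label.
#' @param style Gait style (walk/run only).
#' @param rate Sampling rate in Hz.
#' @param n_cycles Number of cycles / repetitions / bursts.
#' @param cycle_duration Cycle duration in s.
#' @param templates Per-muscle Gaussian bump templates; defaults per
#'   condition (ignored by co-contraction/passive presets).
#' @param truth_model Ground-truth `crossmodal` model.
#' @param calibration `belt_calibration` used to synthesize capacitance.
#' @param emg_band Band of the EMG carrier in Hz (inside Nyquist).
#' @param emg_gain Carrier RMS amplitude in V at full activation.
#' @param circumference_noise_sd Additive measurement noise SD in mm.
#' @param passive_amplitude Amplitude in mm of the swing-phase passive
#'   circumference decrease (0 disables it).
#' @param grf_body_weight Body weight in N.
#' @param cocontraction_offset Tonic activation offset for the
#'   co-contraction gait style.
#' @param relaxation_scale Swing-activity multiplier for the relaxation
#'   gait style.
#' @param amplitude_jitter Half-width of the uniform per-cycle, per-muscle
#'   activation amplitude scaling (0.3 gives between-cycle activity CVs in
#'   the 10-30% range typical of treadmill gait).
#' @param lead_in Zero-activity lead-in before the first cycle, s.
#' @param seed Integer seed; one global seed drives independent per-channel
#'   substreams, so the same seed gives byte-identical sessions.
#' @return An object of class `session_config` (a list).
#' @export
session_config <- function(condition = c("walk", "run", "squat",
                                         "cocontraction_standing",
                                         "cocontraction_sitting", "passive"),
                           style = c("neutral", "cocontraction", "relaxation"),
                           rate = 1000, n_cycles = NULL, cycle_duration = NULL,
                           templates = NULL,
                           truth_model = default_truth_model(),
                           calibration = default_calibration(),
                           emg_band = c(20, 450), emg_gain = 0.5,
                           circumference_noise_sd = 1.8,
                           passive_amplitude = NULL,
                           grf_body_weight = 700,
                           cocontraction_offset = 0.2,
                           relaxation_scale = 0.5,
                           amplitude_jitter = 0.3,
                           lead_in = NULL, seed = 1L) {
  condition <- match.arg(condition)
  style <- match.arg(style)
  preset <- switch(condition,
    walk                   = list(n = 20L, dur = 1.1, stance = 0.62, lead = 0.5, passive = 0),
    run                    = list(n = 20L, dur = 0.7, stance = 0.35, lead = 0.5, passive = 0),
    squat                  = list(n = 5L,  dur = 4.0, stance = NA,   lead = 0,   passive = 0),
    cocontraction_standing = list(n = 1L,  dur = 12,  stance = NA,   lead = 0,   passive = 0),
    cocontraction_sitting  = list(n = 5L,  dur = 4.0, stance = NA,   lead = 0,   passive = 0),
    passive                = list(n = 5L,  dur = 2.0, stance = NA,   lead = 1.0, passive = 2))
  n_cycles <- as.integer(n_cycles %||% preset$n)
  cycle_duration <- cycle_duration %||% preset$dur
  lead_in <- lead_in %||% preset$lead
  passive_amplitude <- passive_amplitude %||% preset$passive
  if (rate <= 0 || cycle_duration <= 0 || n_cycles < 1L || lead_in < 0)
    stop("rates, durations and cycle counts must be positive")
  if (condition %in% c("walk", "run", "squat")) {
    templates <- templates %||% default_templates(condition)
    if (!all(muscle_names() %in% names(templates)))
      stop("templates must be defined for all 5 muscles")
    for (d in templates)
      if (nrow(d) && any(d$width <= 0)) stop("config error: bump widths must be positive")
  }
  if (length(emg_band) != 2L || emg_band[1] <= 0 || emg_band[2] <= emg_band[1])
    stop("config error: emg_band must be an increasing pair of frequencies")
  structure(list(condition = condition, style = style, rate = rate,
                 n_cycles = n_cycles, cycle_duration = cycle_duration,
                 stance_fraction = preset$stance, templates = templates,
                 truth_model = truth_model, calibration = calibration,
                 emg_band = emg_band, emg_gain = emg_gain,
                 circumference_noise_sd = circumference_noise_sd,
                 passive_amplitude = passive_amplitude,
                 grf_body_weight = grf_body_weight,
                 cocontraction_offset = cocontraction_offset,
                 relaxation_scale = relaxation_scale,
                 amplitude_jitter = amplitude_jitter,
                 lead_in = lead_in, seed = as.integer(seed)),
            class = "session_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample layout of a session: lead-in + n_cycles equal cycles
session_layout <- function(config) {
  n_lead <- round(config$lead_in * config$rate)
  cycle_len <- round(config$cycle_duration * config$rate)
  n <- n_lead + config$n_cycles * cycle_len
  phase <- rep(NA_real_, n)
  cyc <- rep(NA_integer_, n)
  for (c in seq_len(config$n_cycles)) {
    at <- n_lead + (c - 1L) * cycle_len + seq_len(cycle_len)
    phase[at] <- (seq_len(cycle_len) - 1) / cycle_len
    cyc[at] <- c
  }
  list(n = n, n_lead = n_lead, cycle_len = cycle_len, phase = phase,
       cycle_index = cyc)
}

# Gaussian bumps on the cycle phase with wrap-around continuity
eval_bumps <- function(phase, bumps) {
  a <- numeric(length(phase))
  if (is.null(bumps) || nrow(bumps) == 0L) return(a)
  for (j in seq_len(nrow(bumps))) {
    c0 <- bumps$center[j] / 100; w <- bumps$width[j] / 100; p <- bumps$peak[j]
    for (sh in c(-1, 0, 1))
      a <- a + p * exp(-0.5 * ((phase - c0 + sh) / w)^2)
  }
  a
}

# raised-cosine plateau on [on_start, on_end] of the cycle with ramp width r
plateau <- function(phase, on_start, on_end, r) {
  a <- numeric(length(phase))
  up <- phase >= on_start & phase < on_start + r
  a[up] <- 0.5 - 0.5 * cos(pi * (phase[up] - on_start) / r)
  a[phase >= on_start + r & phase <= on_end - r] <- 1
  down <- phase > on_end - r & phase <= on_end
  a[down] <- 0.5 + 0.5 * cos(pi * (phase[down] - (on_end - r)) / r)
  a
}

#' Simulate ground-truth muscle activations
#'
#' Evaluates the per-muscle Gaussian bump templates on the cycle phase with
#' independent per-cycle, per-muscle amplitude jitter (gait conditions), a
#' maximal raised-cosine plateau for the co-contraction presets, and zero
#' activity for the passive preset. The co-contraction gait style adds a
#' tonic offset to every muscle; the relaxation style scales swing-phase
#' activity by `relaxation_scale`.
#'
#' @param config A [session_config()] object.
#' @return Named list of five `%MVC` [belt_ts()] objects (VL, RF, VM, BFL,
#'   BFS).
#' @export
simulate_activations <- function(config) {
  stopifnot(inherits(config, "session_config"))
  lay <- session_layout(config)
  ph <- ifelse(is.na(lay$phase), 0, lay$phase)
  in_cycle <- !is.na(lay$phase)
  acts <- lapply(seq_along(muscle_names()), function(i) {
    m <- muscle_names()[i]
    a <- switch(config$condition,
      passive = numeric(lay$n),
      cocontraction_standing = plateau(ph, 1 / 12, 11 / 12, 1 / 12),
      cocontraction_sitting = plateau(ph, 0.10, 0.60, 0.075),
      { # walk / run / squat: jittered bump templates
        scale <- with_seed(substream_seed(config$seed, i), {
          1 + config$amplitude_jitter * stats::runif(config$n_cycles, -1, 1)
        })
        a <- eval_bumps(ph, config$templates[[m]])
        a[in_cycle] <- a[in_cycle] * scale[lay$cycle_index[in_cycle]]
        a
      })
    a[!in_cycle] <- 0
    if (config$condition %in% c("walk", "run")) {
      if (config$style == "cocontraction")
        a[in_cycle] <- a[in_cycle] + config$cocontraction_offset
      if (config$style == "relaxation") {
        swing <- in_cycle & lay$phase > config$stance_fraction
        a[swing] <- a[swing] * config$relaxation_scale
      }
    }
    belt_ts(pmin(a, 1.2), rate = config$rate, unit = "%MVC",
            name = paste0("activation_", m))
  })
  names(acts) <- muscle_names()
  acts
}

#' Simulate a raw surface-EMG channel
#'
#' The standard surrogate for surface EMG: a zero-mean band-limited
#' Gaussian carrier (20-450 Hz by default, unit RMS) multiplied sample-wise
#' by the activation and the gain. Deterministic for a given seed.
#'
#' @param activation Activation [belt_ts()] in fractions of MVC.
#' @param config A [session_config()] object.
#' @param seed Integer seed for this channel's carrier.
#' @return Raw EMG [belt_ts()] in volts.
#' @export
simulate_emg <- function(activation, config, seed = config$seed) {
  stopifnot(inherits(activation, "belt_ts"), inherits(config, "session_config"))
  nyq <- config$rate / 2
  if (config$emg_band[2] >= nyq)
    stop(sprintf("EMG band edge %g Hz is at or above Nyquist (%g Hz)",
                 config$emg_band[2], nyq))
  n <- length(activation$values)
  carrier <- with_seed(seed, stats::rnorm(n))
  bt <- signal::butter(4, config$emg_band / nyq, type = "pass")
  carrier <- apply_filter(bt, carrier, zero_lag = TRUE, order = 4L)
  carrier <- carrier / stats::sd(carrier)
  ts_with(activation, config$emg_gain * activation$values * carrier,
          unit = "V", name = sub("activation", "emg", activation$name))
}

#' Simulate the vertical ground reaction force
#'
#' Walking stance is modelled as two Gaussian humps (about 1.1 and 1.0
#' body weight), running as a single higher hump (about 2.3 body weight),
#' both tapered to zero at the stance edges; swing samples are exactly
#' 0 N. Squatting and standing give constant body weight; sitting/passive
#' presets give 0 N.
#'
#' @param config A [session_config()] object.
#' @return Vertical GRF [belt_ts()] in newtons.
#' @export
simulate_grf <- function(config) {
  stopifnot(inherits(config, "session_config"))
  if (!is.finite(config$grf_body_weight) || config$grf_body_weight <= 0)
    stop("config error: body weight must be positive")
  lay <- session_layout(config)
  bw <- config$grf_body_weight
  f <- numeric(lay$n)
  if (config$condition %in% c("walk", "run")) {
    sf <- config$stance_fraction
    stance <- !is.na(lay$phase) & lay$phase < sf
    u <- lay$phase[stance] / sf           # position within stance, [0, 1)
    prof <- if (config$condition == "walk")
      1.10 * exp(-0.5 * ((u - 0.30) / 0.11)^2) +
      1.00 * exp(-0.5 * ((u - 0.75) / 0.10)^2)
    else
      2.30 * exp(-0.5 * ((u - 0.50) / 0.16)^2)
    taper <- pmin(1, u / 0.08) * pmin(1, (1 - u) / 0.08)
    f[stance] <- bw * prof * taper
  } else if (config$condition %in% c("squat", "cocontraction_standing")) {
    f[!is.na(lay$phase)] <- bw
  }                                       # sitting / passive: stays 0
  belt_ts(f, rate = config$rate, unit = "N", name = "vgrf_N")
}

#' Simulate the measured belt circumference
#'
#' The ground-truth circumference is the truth model's quadratic map of the
#' activations, plus an optional passive-deformation term (a negative
#' half-sine confined to the swing phase — the circumference decrease seen
#' during passive knee flexion when muscles are silent), plus additive
#' Gaussian measurement noise.
#'
#' @param activations Named list of five activation [belt_ts()] objects.
#' @param config A [session_config()] object.
#' @param seed Integer seed for the noise substream.
#' @return List with `noiseless` and `measured` circumference [belt_ts()]
#'   objects in mm.
#' @export
simulate_circumference <- function(activations, config, seed = config$seed) {
  stopifnot(inherits(config, "session_config"))
  A <- as_activity_matrix(activations)
  lay <- session_layout(config)
  base <- predict(config$truth_model, A)
  s <- numeric(lay$n)
  if (config$passive_amplitude != 0) {
    if (config$condition %in% c("walk", "run")) {
      sf <- config$stance_fraction
      swing <- !is.na(lay$phase) & lay$phase >= sf
      s[swing] <- -sin(pi * (lay$phase[swing] - sf) / (1 - sf))
    } else {
      in_cycle <- !is.na(lay$phase)
      s[in_cycle] <- -sin(pi * lay$phase[in_cycle])
    }
  }
  noiseless <- base + config$passive_amplitude * s
  noise <- with_seed(seed, stats::rnorm(lay$n, 0, config$circumference_noise_sd))
  rate <- config$rate
  list(noiseless = belt_ts(noiseless, rate, unit = "mm",
                           name = "circumference_mm"),
       measured = belt_ts(noiseless + noise, rate, unit = "mm",
                          name = "circumference_mm"))
}

#' Simulate the belt capacitance channel
#'
#' Per-sample inversion of the calibration quadratic on its monotone
#' branch; lengths below the parabola minimum raise an error naming the
#' offending sample.
#'
#' @param circumference Circumference [belt_ts()] in mm.
#' @param calibration A `belt_calibration` object.
#' @return Capacitance [belt_ts()] in nF.
#' @export
simulate_capacitance <- function(circumference, calibration) {
  stopifnot(inherits(circumference, "belt_ts"))
  ts_with(circumference,
          length_to_capacitance(calibration, circumference$values),
          unit = "nF", name = "capacitance_nF")
}

#' Generate a complete synthetic multimodal session
#'
#' Assembles all measured channels (capacitance, five raw EMG channels,
#' vertical GRF) plus the ground truth (activations, noiseless
#' circumference, heel-contact samples for gait conditions, the truth
#' model) for one condition preset. One global seed drives independent
#' per-channel substreams, so the same configuration and seed are
#' byte-identical and adding a channel never perturbs the others.
#'
#' @param condition Condition preset (see [session_config()]), or a ready
#'   `session_config` object passed as the first argument.
#' @param ... Further arguments to [session_config()].
#' @param seed Integer seed.
#' @return An object of class `belt_session`: list with `channels` (named
#'   [belt_ts()] set: `capacitance_nF`, `emg_VL_V` ... `emg_BFS_V`,
#'   `vgrf_N`), `truth` (activations matrix, noiseless circumference,
#'   `contact_indices`/`contact_times`, `model`, `condition`, `style`),
#'   and `config`.
#' @examples
#' ses <- generate_session("walk", n_cycles = 3, seed = 7)
#' ses
#' @export
generate_session <- function(condition = "walk", ..., seed = 1L) {
  config <- if (inherits(condition, "session_config")) condition
            else session_config(condition, ..., seed = seed)
  acts <- simulate_activations(config)
  A <- as_activity_matrix(acts)
  grf <- simulate_grf(config)
  circ <- simulate_circumference(acts, config,
                                 seed = substream_seed(config$seed, 10L))
  cap <- simulate_capacitance(circ$measured, config$calibration)
  emg <- lapply(seq_along(muscle_names()), function(i)
    simulate_emg(acts[[i]], config, seed = substream_seed(config$seed, 20L + i)))
  names(emg) <- paste0("emg_", muscle_names(), "_V")
  channels <- c(list(capacitance_nF = cap), emg, list(vgrf_N = grf))

  contacts <- integer(0)
  if (config$condition %in% c("walk", "run")) {
    lay <- session_layout(config)
    contacts <- vapply(seq_len(config$n_cycles), function(c) {
      at <- lay$n_lead + (c - 1L) * lay$cycle_len + seq_len(lay$cycle_len)
      as.integer(at[which(grf$values[at] > 20)[1]])
    }, integer(1))
  }
  structure(list(channels = channels,
                 truth = list(activations = A,
                              circumference = circ$noiseless,
                              contact_indices = contacts,
                              contact_times = (contacts - 1L) / config$rate,
                              model = config$truth_model,
                              condition = config$condition,
                              style = config$style),
                 config = config),
            class = "belt_session")
}

#' @export
print.belt_session <- function(x, ...) {
  n <- length(x$channels[[1]]$values)
  cat(sprintf("<belt_session> %s%s: %d channels, %d samples @ %g Hz (%.1f s)\n",
              x$truth$condition %||% "recorded",
              if (!is.null(x$truth$style) &&
                  x$truth$condition %in% c("walk", "run"))
                paste0(" / ", x$truth$style) else "",
              length(x$channels), n, x$channels[[1]]$rate,
              n / x$channels[[1]]$rate))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (length(x$truth$contact_indices))
    cat(sprintf("  truth heel contacts: %d\n", length(x$truth$contact_indices)))
  invisible(x)
}

#' Concatenate two sessions sharing rate and channel layout
#'
#' Used to assemble multi-condition recordings (e.g. the evaluation
#' protocol: a series of sitting maximal co-contractions followed by
#' squats).
#'
#' @param a,b `belt_session` objects with identical channel names and rate.
#' @return A `belt_session`; truth contact indices of `b` are shifted.
#' @export
concat_sessions <- function(a, b) {
  stopifnot(inherits(a, "belt_session"), inherits(b, "belt_session"))
  if (!identical(names(a$channels), names(b$channels)))
    stop("sessions have different channel sets")
  rate <- a$channels[[1]]$rate
  if (rate != b$channels[[1]]$rate) stop("sessions have different rates")
  na <- length(a$channels[[1]]$values)
  channels <- lapply(names(a$channels), function(nm)
    ts_with(a$channels[[nm]], c(a$channels[[nm]]$values, b$channels[[nm]]$values)))
  names(channels) <- names(a$channels)
  structure(list(
    channels = channels,
    truth = list(
      activations = rbind(a$truth$activations, b$truth$activations),
      circumference = ts_with(a$truth$circumference,
                              c(a$truth$circumference$values,
                                b$truth$circumference$values)),
      contact_indices = c(a$truth$contact_indices,
                          b$truth$contact_indices + na),
      contact_times = c(a$truth$contact_times,
                        b$truth$contact_times + na / rate),
      model = a$truth$model,
      condition = paste(a$truth$condition, b$truth$condition, sep = "+"),
      style = a$truth$style),
    config = a$config),
    class = "belt_session")
}

#' Synthetic evaluation protocol session
#'
#' The session used to evaluate the cross-modal model: a series of five
#' maximal voluntary co-contractions in the sitting position followed by
#' squats — movements with and without explicit co-contraction. Defaults
#' give a 60 s (60 000 frame) session at 1 kHz.
#'
#' @param seed Integer seed.
#' @param n_squats Number of squat repetitions (4 s each).
#' @param circumference_noise_sd Measurement noise SD in mm.
#' @return A `belt_session`.
#' @export
evaluation_session <- function(seed = 1L, n_squats = 10L,
                               circumference_noise_sd = 1.8) {
  coco <- generate_session("cocontraction_sitting",
                           circumference_noise_sd = circumference_noise_sd,
                           seed = seed)
  sq <- generate_session("squat", n_cycles = n_squats,
                         circumference_noise_sd = circumference_noise_sd,
                         seed = seed + 1L)
  concat_sessions(coco, sq)
}
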