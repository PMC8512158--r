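#' Write a session's channels to CSV
#'
#' Column 1 is `time_s`, followed by one column per channel with units
#' encoded in the names (`capacitance_nF`, `emg_VL_V` ... `emg_BFS_V`,
#' `vgrf_N`).
#'
#' @param session A `belt_session` (truth, if present, is not written; see
#'   [write_truth_json()]).
#' @param path File path.
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "belt_session"))
  df <- data.frame(time_s = ts_times(session$channels[[1]]))
  for (nm in names(session$channels)) df[[nm]] <- session$channels[[nm]]$values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a session CSV
#'
#' Expects a header row with `time_s` plus named channel columns; the rate
#' is inferred from the time column, which must be uniform to a relative
#' tolerance of 1e-6.
#'
#' @param path File path.
#' @param require Character vector of channel columns that must be present;
#'   missing ones raise an error naming them.
#' @return A `belt_session` with channels only (no ground truth).
#' @export
read_session_csv <- function(path, require = NULL) {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df)) stop("missing required column: time_s")
  chan_names <- setdiff(names(df), "time_s")
  if (length(chan_names) == 0L) stop("no channel columns found")
  miss <- setdiff(require, chan_names)
  if (length(miss))
    stop(sprintf("missing required channel column(s): %s",
                 paste(miss, collapse = ", ")))
  t <- df$time_s
  if (length(t) < 2L) stop("need at least 2 samples")
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-6 * abs(dt[1])))
    stop("non-uniform sampling in time_s")
  rate <- 1 / dt[1]
  units <- vapply(chan_names, function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    utils::tail(parts, 1)
  }, character(1))
  channels <- lapply(seq_along(chan_names), function(i)
    belt_ts(df[[chan_names[i]]], rate = rate, start = t[1],
            unit = units[i], name = chan_names[i]))
  names(channels) <- chan_names
  structure(list(channels = channels, truth = NULL, config = NULL),
            class = "belt_session")
}

#' Write a session's ground truth as a JSON sidecar
#'
#' Carries the truth model coefficients, heel-contact times, condition and
#' seed, so a written synthetic session can be re-evaluated against its
#' generator.
#'
#' @param session A `belt_session` with truth.
#' @param path File path.
#' @export
write_truth_json <- function(session, path) {
  stopifnot(inherits(session, "belt_session"))
  tr <- session$truth
  if (is.null(tr)) stop("session carries no ground truth")
  jsonlite::write_json(
    list(condition = tr$condition, style = tr$style,
         model = list(muscles = muscle_names(),
                      w1 = unname(tr$model$w1), w2 = unname(tr$model$w2),
                      b = tr$model$b),
         contact_times_s = tr$contact_times,
         seed = session$config$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full analysis pipeline on one session
#'
#' Chains every stage — calibration, preprocessing, gait segmentation,
#' cycle statistics, cross-modal fit and evaluation — and returns (and
#' optionally writes) a JSON-serializable report. Each stage logs one line
#' with its parameters; any stage error aborts with the stage name.
#'
#' @param config Either a named list or a path to a JSON file with fields:
#'   `session` (path to a session CSV, or a `belt_session` when called with
#'   a list), `calibration` (path to a calibration-points CSV, a curve
#'   JSON, or a `belt_calibration`; default [default_calibration()]),
#'   `activities_source` (`"envelope"`/`"truth"`), `circumference_source`
#'   (`"capacitance"`/`"truth"`), `heel_threshold` (N, default 20),
#'   `min_swing`, `min_cycle` (s), `n_points` (default 101), `eval_rate`
#'   (Hz, default 10), `reference_length` (mm; defaults to the session's
#'   median circumference), `seed`.
#' @param out Optional path for the JSON report.
#' @param quiet Suppress per-stage log messages?
#' @return The report as a list (invisibly when `out` is given):
#'   `schema_version`, resolved `config` echo, `calibration`, `events`,
#'   `cycle_stats`, `fit`.
#' @export
run_pipeline <- function(config, out = NULL, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("'config' must be a list or a JSON file path")
  log_stage <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  at_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }
  cfg <- utils::modifyList(
    list(activities_source = "envelope", circumference_source = "capacitance",
         heel_threshold = 20, min_swing = 0.05, min_cycle = 0.3,
         n_points = 101L, eval_rate = 10, reference_length = NULL,
         lowpass_zero_lag = FALSE, seed = 1L),
    config[!vapply(config, is.null, logical(1))])

  # -- calibration ----------------------------------------------------------
  curve <- at_stage("calibration", {
    cal <- cfg$calibration
    if (is.null(cal)) default_calibration()
    else if (inherits(cal, "belt_calibration")) cal
    else if (is.character(cal) && grepl("\\.json$", cal)) read_calibration_json(cal)
    else if (is.character(cal)) fit_calibration(read_calibration_points(cal))
    else stop("unrecognized 'calibration' entry")
  })
  log_stage("calibration", "L = %.5g C^2 %+.5g C %+.5g, range [%.4g, %.4g] nF",
            curve$a2, curve$a1, curve$a0,
            curve$valid_range[1], curve$valid_range[2])

  # -- load session ---------------------------------------------------------
  session <- at_stage("load", {
    if (inherits(cfg$session, "belt_session")) cfg$session
    else if (is.character(cfg$session)) read_session_csv(cfg$session)
    else stop("'session' must be a belt_session or a CSV path")
  })
  rate <- session$channels[[1]]$rate
  n <- length(session$channels[[1]]$values)
  log_stage("load", "%d channels, %d samples @ %g Hz", length(session$channels),
            n, rate)

  # -- preprocessing (circumference; envelopes are computed in evaluation) --
  circ <- at_stage("preprocess", {
    if (cfg$circumference_source == "truth") session$truth$circumference
    else if (is.null(session$channels$capacitance_nF))
      stop("missing channel 'capacitance_nF'")
    else suppressWarnings(
      process_circumference(session$channels$capacitance_nF, curve,
                            zero_lag = cfg$lowpass_zero_lag)$length)
  })
  log_stage("preprocess", "circumference via %s, 10 Hz low-pass (%s)",
            cfg$circumference_source,
            if (cfg$lowpass_zero_lag) "zero-lag" else "causal")

  # -- gait segmentation + cycle statistics ---------------------------------
  events <- NULL; cyc_stats <- NULL
  if (!is.null(session$channels$vgrf_N)) {
    events <- at_stage("segmentation",
      detect_heel_contacts(session$channels$vgrf_N,
                           threshold = cfg$heel_threshold,
                           min_swing = cfg$min_swing,
                           min_cycle = cfg$min_cycle))
    log_stage("segmentation", "%d heel contact(s) at threshold %g N",
              length(events$contact_indices), cfg$heel_threshold)
    if (length(events$contact_indices) >= 2L) {
      cyc_stats <- at_stage("stats", {
        ref <- cfg$reference_length %||% stats::median(circ$values)
        ccs <- gait_cycles(circ, events, n_points = cfg$n_points)
        list(circumference = unclass(circumference_cycle_stats(ccs, ref)),
             reference_length = ref, n_cycles = nrow(ccs$cycles))
      })
      log_stage("stats", "%d cycle(s); circumference CV %.3g%%",
                cyc_stats$n_cycles, cyc_stats$circumference$cv_percent)
    }
  }

  # -- cross-modal fit + evaluation -----------------------------------------
  fit <- at_stage("fit", evaluate_session(
    session, curve = curve,
    activities_source = cfg$activities_source,
    circumference_source = cfg$circumference_source,
    eval_rate = cfg$eval_rate,
    lowpass_zero_lag = cfg$lowpass_zero_lag))
  log_stage("fit", "T = %d frames; RMSE %.4g mm; ICC(2,1) %.4g",
            fit$n_frames, fit$rmse, fit$icc21)

  report <- list(
    schema_version = "1.0",
    config = cfg[setdiff(names(cfg), c("session", "calibration"))],
    calibration = list(a2 = curve$a2, a1 = curve$a1, a0 = curve$a0,
                       c_lo = curve$valid_range[1],
                       c_hi = curve$valid_range[2]),
    events = if (!is.null(events)) list(
      n = length(events$contact_indices),
      times_s = events$contact_times),
    cycle_stats = cyc_stats,
    fit = list(model = list(muscles = muscle_names(),
                            w1 = unname(fit$model$w1),
                            w2 = unname(fit$model$w2),
                            b = fit$model$b),
               rmse_mm = fit$rmse, icc21 = fit$icc21,
               regression_slope = fit$regression_slope,
               regression_intercept_mm = fit$regression_intercept,
               n_frames = fit$n_frames, n_eval = fit$n_eval))
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         null = "null")
    log_stage("report", "written to %s", out)
    return(invisible(report))
  }
  report
}
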