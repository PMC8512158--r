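#' Detect heel contacts from vertical ground reaction force
#'
#' A heel contact is the first frame at which the vertical GRF rises above
#' the threshold (default 20 N): a rising-edge crossing `F[i] > thr` with
#' `F[i-1] <= thr`. Two guards make the bare rule robust to noise: the
#' crossing must be preceded by at least `min_swing` seconds continuously at
#' or below the threshold (debounce against chatter within one rise), and
#' events closer than `min_cycle` seconds to the previously accepted event
#' are discarded.
#'
#' @param vgrf Vertical GRF [belt_ts()] in newtons (low-pass filtered
#'   upstream, e.g. 50 Hz zero-lag).
#' @param threshold Contact threshold in N (> 0).
#' @param min_swing Minimum continuous sub-threshold time before a contact, s.
#' @param min_cycle Minimum separation between successive contacts, s.
#' @return An object of class `gait_events`: list with `contact_indices`
#'   (1-based sample indices), `contact_times` (s), and `threshold`. No
#'   crossings yields an empty event list, not an error.
#' @export
detect_heel_contacts <- function(vgrf, threshold = 20, min_swing = 0.05,
                                 min_cycle = 0.3) {
  stopifnot(inherits(vgrf, "belt_ts"))
  if (!is.finite(threshold) || threshold <= 0) stop("threshold must be positive")
  x <- vgrf$values
  n <- length(x)
  if (n < 2L) stop("vertical GRF series is too short")
  cross <- which(x[-1] > threshold & x[-n] <= threshold) + 1L
  need <- max(1L, ceiling(min_swing * vgrf$rate))
  keep <- vapply(cross, function(i) {
    lo <- i - need
    lo >= 1L && all(x[lo:(i - 1L)] <= threshold)
  }, logical(1))
  cross <- cross[keep]
  gap <- max(1L, round(min_cycle * vgrf$rate))
  accepted <- integer(0)
  for (i in cross) {
    if (length(accepted) == 0L || i - accepted[length(accepted)] >= gap)
      accepted <- c(accepted, i)
  }
  structure(list(contact_indices = accepted,
                 contact_times = vgrf$start + (accepted - 1L) / vgrf$rate,
                 threshold = threshold),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d heel contact(s), threshold %g N\n",
              length(x$contact_indices), x$threshold))
  if (length(x$contact_times))
    cat("  times (s):", paste(sprintf("%.3f", utils::head(x$contact_times, 8)),
                              collapse = ", "),
        if (length(x$contact_times) > 8) "...\n" else "\n")
  invisible(x)
}

#' Export gait events as CSV
#'
#' Two columns: `event_index` (sample index) and `event_time_s`.
#'
#' @param events A `gait_events` object.
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  utils::write.csv(data.frame(event_index = events$contact_indices,
                              event_time_s = events$contact_times),
                   path, row.names = FALSE)
  invisible(path)
}

#' Segment a signal into gait cycles
#'
#' Cycle k spans samples `[event_k, event_{k+1})`, so n events delimit
#' n - 1 cycles; data before the first and after the last contact are
#' discarded.
#'
#' @param series A [belt_ts()] object.
#' @param events A `gait_events` object with at least 2 events.
#' @return List of numeric vectors, one per cycle.
#' @export
segment_cycles <- function(series, events) {
  stopifnot(inherits(series, "belt_ts"), inherits(events, "gait_events"))
  idx <- events$contact_indices
  if (length(idx) < 2L) stop("need at least 2 heel contacts to segment cycles")
  if (any(diff(idx) <= 0)) stop("event indices must be strictly increasing")
  if (idx[length(idx)] > length(series$values))
    stop("event index beyond end of series")
  lapply(seq_len(length(idx) - 1L), function(k)
    series$values[idx[k]:(idx[k + 1L] - 1L)])
}

#' Time-normalize one gait cycle to a percent-of-cycle grid
#'
#' Linear interpolation of the cycle onto `n_points` equally spaced
#' fractions of its duration (0% to 100%); endpoints are preserved.
#'
#' @param cycle Numeric vector (length >= 2).
#' @param n_points Grid size; 101 (0%, 1%, ..., 100%) is the biomechanics
#'   convention.
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(cycle, n_points = 101L) {
  cycle <- as.numeric(cycle)
  if (length(cycle) < 2L) stop("cycle must contain at least 2 samples")
  if (n_points < 2L) stop("n_points must be at least 2")
  stats::approx(x = seq(0, 1, length.out = length(cycle)), y = cycle,
                xout = seq(0, 1, length.out = n_points))$y
}

#' Ensemble mean and standard deviation across normalized cycles
#'
#' Per grid point: arithmetic mean and sample standard deviation (divisor
#' n - 1) across cycles; the SD is 0 when only one cycle is supplied.
#'
#' @param cycles List of equal-length normalized cycles, or a matrix with
#'   one row per cycle.
#' @return List with `mean` and `sd` vectors.
#' @export
ensemble_stats <- function(cycles) {
  if (is.list(cycles)) {
    if (length(cycles) == 0L) stop("need at least 1 cycle")
    len <- unique(vapply(cycles, length, integer(1)))
    if (length(len) != 1L) stop("cycles must share a common grid length")
    cycles <- do.call(rbind, cycles)
  }
  if (!is.matrix(cycles) || nrow(cycles) < 1L) stop("need at least 1 cycle")
  m <- colMeans(cycles)
  s <- if (nrow(cycles) == 1L) rep(0, ncol(cycles)) else apply(cycles, 2, stats::sd)
  list(mean = m, sd = s)
}

#' Build a time-normalized gait cycle set for one channel
#'
#' Segments the channel at the heel contacts, time-normalizes every cycle
#' to the percent grid, and attaches the per-point ensemble mean and SD.
#'
#' @param series A [belt_ts()] object.
#' @param events A `gait_events` object (>= 2 events).
#' @param n_points Percent-grid size (default 101).
#' @return An object of class `gait_cycle_set`: list with `grid` (percent),
#'   `cycles` (n_cycles x n_points matrix), `mean`, `sd`, and `channel`.
#' @export
gait_cycles <- function(series, events, n_points = 101L) {
  segs <- segment_cycles(series, events)
  mat <- do.call(rbind, lapply(segs, time_normalize, n_points = n_points))
  st <- ensemble_stats(mat)
  structure(list(grid = seq(0, 100, length.out = n_points),
                 cycles = mat, mean = st$mean, sd = st$sd,
                 channel = series$name, unit = series$unit),
            class = "gait_cycle_set")
}

#' @export
print.gait_cycle_set <- function(x, ...) {
  cat(sprintf("<gait_cycle_set> %s: %d cycle(s) on a %d-point %% grid\n",
              if (nzchar(x$channel)) x$channel else "unnamed",
              nrow(x$cycles), length(x$grid)))
  cat(sprintf("  ensemble mean range [%.4g, %.4g]; mean SD %.4g\n",
              min(x$mean), max(x$mean), mean(x$sd)))
  invisible(x)
}

#' @export
plot.gait_cycle_set <- function(x, ...) {
  ylim <- range(x$mean - x$sd, x$mean + x$sd)
  graphics::plot(x$grid, x$mean, type = "n", ylim = ylim,
                 xlab = "gait cycle (%)",
                 ylab = if (nzchar(x$unit)) paste0(x$channel, " (", x$unit, ")") else x$channel,
                 ...)
  graphics::polygon(c(x$grid, rev(x$grid)),
                    c(x$mean + x$sd, rev(x$mean - x$sd)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$grid, x$mean, lwd = 2, col = "steelblue4")
  invisible(x)
}

#' Export a cycle matrix as CSV with a percent-grid header
#'
#' @param cycle_set A `gait_cycle_set` object.
#' @param path File path.
#' @export
write_cycles_csv <- function(cycle_set, path) {
  stopifnot(inherits(cycle_set, "gait_cycle_set"))
  mat <- cycle_set$cycles
  colnames(mat) <- sprintf("pct_%g", cycle_set$grid)
  utils::write.csv(mat, path, row.names = FALSE)
  invisible(path)
}
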