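#' Uniformly sampled time series
#'
#' Lightweight container for one uniformly sampled channel: a numeric vector,
#' a sampling rate in Hz, a start time in seconds, and unit/name labels. All
#' measured and simulated signals in the package (capacitance, EMG, vertical
#' GRF, circumference) travel in this form.
#'
#' @param values Numeric vector of samples (finite).
#' @param rate Sampling rate in Hz (> 0).
#' @param start Time of the first sample in seconds.
#' @param unit Unit label, e.g. `"nF"`, `"V"`, `"N"`, `"mm"`.
#' @param name Channel label, e.g. `"vgrf_N"`.
#' @return An object of class `belt_ts`.
#' @examples
#' x <- belt_ts(sin(2 * pi * 2 * (0:999) / 1000), rate = 1000, unit = "V")
#' x
#' @export
belt_ts <- function(values, rate, start = 0, unit = "", name = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("a time series needs at least one sample")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number (Hz)")
  if (anyNA(values) || any(!is.finite(values)))
    stop("time-series values must be finite")
  structure(list(values = values, rate = rate, start = start,
                 unit = unit, name = name),
            class = "belt_ts")
}

#' @export
print.belt_ts <- function(x, ...) {
  cat(sprintf("<belt_ts> %s: %d samples @ %g Hz (%.3f s)%s\n",
              if (nzchar(x$name)) x$name else "unnamed",
              length(x$values), x$rate, length(x$values) / x$rate,
              if (nzchar(x$unit)) paste0(", unit ", x$unit) else ""))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.double.belt_ts <- function(x, ...) x$values

#' Sample times of a time series
#'
#' @param x A [belt_ts()] object.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "belt_ts"))
  x$start + (seq_along(x$values) - 1) / x$rate
}

#' @export
plot.belt_ts <- function(x, ...) {
  graphics::plot(ts_times(x), x$values, type = "l",
                 xlab = "time (s)",
                 ylab = if (nzchar(x$unit)) paste0(x$name, " (", x$unit, ")") else x$name,
                 ...)
  invisible(x)
}

# rebuild a series with new values, keeping metadata
ts_with <- function(x, values, unit = x$unit, name = x$name) {
  belt_ts(values, rate = x$rate, start = x$start, unit = unit, name = name)
}

#' Muscle channel order
#'
#' The five recorded thigh muscles in the fixed order used by every matrix
#' and serialization in the package: vastus lateralis (VL), rectus femoris
#' (RF), vastus medialis (VM), biceps femoris long head (BFL), biceps
#' femoris short head (BFS).
#'
#' @return Character vector of length 5.
#' @export
muscle_names <- function() c("VL", "RF", "VM", "BFL", "BFS")

# evaluate an expression under a temporary RNG seed, restoring global state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic per-channel substream seed; keeps 0 <= seed < 2^31 - 1
# so adding a channel never perturbs the streams of existing channels
substream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + id * 1000003) %% 2147483629)
}
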