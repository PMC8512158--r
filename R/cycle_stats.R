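#' Between-cycle coefficient of variation
#'
#' The stability metric used for both circumference and muscle activity:
#' the average between-cycle standard deviation divided by the average
#' amplitude of one cycle, in percent.
#'
#' @param average_deviation Mean across-grid between-cycle SD (channel units).
#' @param average_amplitude Mean per-cycle amplitude (channel units, non-zero).
#' @return CV in percent; `NA` with a warning when the amplitude is zero.
#' @export
coefficient_of_variation <- function(average_deviation, average_amplitude) {
  if (average_amplitude == 0) {
    warning("CV undefined: average amplitude is zero")
    return(NA_real_)
  }
  100 * average_deviation / average_amplitude
}

#' Cycle statistics of the circumference channel
#'
#' Per cycle, the amplitude is the mean over the cycle of the offset from a
#' reference length (the wearer's natural length must be supplied
#' explicitly); the reported amplitude is the mean of the per-cycle
#' amplitudes. The deviation is the mean over the percent grid of the
#' across-cycle sample SD, and the CV their ratio in percent. The mean
#' within-cycle peak-to-peak range is additionally reported as `range_mm`,
#' the quantity a "cycle amplitude" reading of the excursion corresponds to.
#'
#' @param cycle_set A `gait_cycle_set` of the circumference channel (mm).
#' @param reference_length Reference (natural) length in mm.
#' @return An object of class `cycle_stats`: list with `average_amplitude`,
#'   `average_deviation`, `cv_percent`, `range_mm`, `n_cycles`.
#' @export
circumference_cycle_stats <- function(cycle_set, reference_length) {
  stopifnot(inherits(cycle_set, "gait_cycle_set"))
  if (!is.numeric(reference_length) || length(reference_length) != 1L ||
      !is.finite(reference_length))
    stop("'reference_length' must be a finite scalar (mm)")
  st <- cycle_matrix_stats(cycle_set$cycles, reference = reference_length)
  structure(c(st, list(n_cycles = nrow(cycle_set$cycles))),
            class = "cycle_stats")
}

# shared amplitude/deviation/CV arithmetic on an n_cycles x n_points matrix
cycle_matrix_stats <- function(mat, reference = 0) {
  amp <- mean(rowMeans(mat) - reference)
  dev <- mean(if (nrow(mat) == 1L) rep(0, ncol(mat)) else apply(mat, 2, stats::sd))
  list(average_amplitude = amp,
       average_deviation = dev,
       cv_percent = if (amp == 0) NA_real_ else 100 * dev / amp,
       range_mm = mean(apply(mat, 1, function(r) diff(range(r)))))
}

#' @export
print.cycle_stats <- function(x, ...) {
  cat("Cycle statistics\n")
  cat(sprintf("  average amplitude in a cycle : %.4g\n", x$average_amplitude))
  cat(sprintf("  average deviation between cycles: %.4g\n", x$average_deviation))
  cat(sprintf("  coefficient of variation     : %s\n",
              if (is.na(x$cv_percent)) "undefined (zero amplitude)"
              else sprintf("%.3g %%", x$cv_percent)))
  if (!is.null(x$range_mm))
    cat(sprintf("  mean within-cycle range      : %.4g\n", x$range_mm))
  cat(sprintf("  cycles: %d\n", x$n_cycles))
  invisible(x)
}

#' Cycle statistics of the five muscle-activity channels
#'
#' Per muscle, amplitude/deviation/CV as in
#' [circumference_cycle_stats()] with reference 0 (activities are already
#' fractions of MVC). The averaged row reports the mean of the per-muscle
#' amplitudes and deviations, and the CV under both conventions —
#' ratio-of-averages (`cv_ratio_of_averages`) and mean of the per-muscle
#' CVs (`cv_mean_of_cvs`) — because the two differ whenever muscles have
#' unequal amplitudes.
#'
#' @param cycle_sets Named list of `gait_cycle_set` objects, one per muscle
#'   in the order of [muscle_names()].
#' @return List with `per_muscle` (list of `cycle_stats`) and `averaged`.
#' @export
activity_cycle_stats <- function(cycle_sets) {
  need <- muscle_names()
  if (!is.list(cycle_sets) || !all(need %in% names(cycle_sets)))
    stop(sprintf("missing muscle channel(s): %s",
                 paste(setdiff(need, names(cycle_sets)), collapse = ", ")))
  per <- lapply(cycle_sets[need], function(cs) {
    stopifnot(inherits(cs, "gait_cycle_set"))
    structure(c(cycle_matrix_stats(cs$cycles, reference = 0),
                list(n_cycles = nrow(cs$cycles))),
              class = "cycle_stats")
  })
  amps <- vapply(per, `[[`, numeric(1), "average_amplitude")
  devs <- vapply(per, `[[`, numeric(1), "average_deviation")
  cvs <- vapply(per, `[[`, numeric(1), "cv_percent")
  mean_amp <- mean(amps)
  list(per_muscle = per,
       averaged = list(
         average_amplitude = mean_amp,
         average_deviation = mean(devs),
         cv_ratio_of_averages = if (mean_amp == 0) NA_real_
                                else 100 * mean(devs) / mean_amp,
         cv_mean_of_cvs = if (anyNA(cvs)) NA_real_ else mean(cvs)))
}
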