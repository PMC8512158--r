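#' Fit the quadratic capacitance-to-length calibration of the belt sensor
#'
#' The elastic part of the belt sensor behaves as a capacitor whose
#' capacitance C (nF) grows monotonically and nonlinearly with its length
#' L (mm). The transfer function is modelled as the quadratic
#' \deqn{L = a_2 C^2 + a_1 C + a_0,}
#' fitted by ordinary least squares to a static stretch sweep of
#' (capacitance, length) pairs. Only the increasing branch of the parabola
#' (above its vertex) is physical, so the validity range is set to
#' `[max(vertex C, min observed C), max observed C]`.
#'
#' @param points Data frame with numeric columns `capacitance_nF` and
#'   `length_mm` (strictly positive); at least 3 rows with at least 3
#'   distinct capacitances.
#' @return An object of class `belt_calibration`: a list with coefficients
#'   `a2` (mm/nF^2), `a1` (mm/nF), `a0` (mm), the validity range
#'   `valid_range` (nF), the achieved `agreement_percent` (100 R^2 of the
#'   fit) and the calibration `points`.
#' @seealso [capacitance_to_length()], [length_to_capacitance()],
#'   [goodness_of_fit()], [default_calibration()]
#' @examples
#' cal <- default_calibration()
#' pts <- data.frame(capacitance_nF = c(465, 500, 550, 606))
#' pts$length_mm <- capacitance_to_length(cal, pts$capacitance_nF)
#' fit <- fit_calibration(pts)
#' coef(fit)
#' @export
fit_calibration <- function(points) {
  points <- validate_points(points)
  if (length(unique(points$capacitance_nF)) < 3L)
    stop("degenerate design: need at least 3 distinct capacitance values")
  fit <- stats::lm(length_mm ~ capacitance_nF + I(capacitance_nF^2),
                   data = points)
  cf <- unname(stats::coef(fit))
  curve <- new_calibration(a2 = cf[3], a1 = cf[2], a0 = cf[1],
                           c_obs = range(points$capacitance_nF))
  curve$points <- points
  curve$agreement_percent <- goodness_of_fit(points, curve)
  curve
}

validate_points <- function(points, name = "points") {
  if (!is.data.frame(points))
    stop(sprintf("'%s' must be a data frame", name))
  need <- c("capacitance_nF", "length_mm")
  miss <- setdiff(need, names(points))
  if (length(miss))
    stop(sprintf("'%s' is missing column(s): %s", name,
                 paste(miss, collapse = ", ")))
  points <- points[need]
  if (nrow(points) < 1L || anyNA(points) || any(!is.finite(as.matrix(points))))
    stop(sprintf("'%s' must contain finite values", name))
  if (any(points$capacitance_nF <= 0) || any(points$length_mm <= 0))
    stop(sprintf("capacitance and length in '%s' must be positive", name))
  points
}

new_calibration <- function(a2, a1, a0, c_obs) {
  if (any(!is.finite(c(a2, a1, a0)))) stop("non-finite calibration coefficients")
  if (a2 > 0) {
    vertex <- -a1 / (2 * a2)
    lo <- max(vertex, min(c_obs))
    hi <- max(c_obs)
  } else if (a2 < 0) {
    vertex <- -a1 / (2 * a2)           # increasing branch is left of the vertex
    lo <- min(c_obs)
    hi <- min(vertex, max(c_obs))
  } else {
    lo <- min(c_obs)
    hi <- max(c_obs)
  }
  obj <- structure(list(a2 = a2, a1 = a1, a0 = a0,
                        valid_range = c(lo, hi)),
                   class = "belt_calibration")
  d <- 2 * a2 * c(lo, hi) + a1
  if (any(d <= 0) && !(a2 == 0 && a1 > 0))
    warning("calibration curve is not strictly increasing over its validity range")
  obj
}

#' Reference calibration curve of the belt sensor
#'
#' The quadratic calibration obtained from the static stretch sweep of the
#' prototype belt: `L = 0.00223 C^2 - 1.72592 C + 416.9272` with the sweep
#' covering 465 nF (natural length of the 95 mm elastic part) to 606 nF
#' (fully stretched, 200 mm).
#'
#' @return A `belt_calibration` object.
#' @export
default_calibration <- function() {
  new_calibration(a2 = 0.00223, a1 = -1.72592, a0 = 416.9272,
                  c_obs = c(465, 606))
}

#' @export
print.belt_calibration <- function(x, ...) {
  cat("Quadratic capacitance-to-length calibration\n")
  cat(sprintf("  L(mm) = %.5g C^2 %+.5g C %+.5g   (C in nF)\n",
              x$a2, x$a1, x$a0))
  cat(sprintf("  valid capacitance range: [%.4g, %.4g] nF\n",
              x$valid_range[1], x$valid_range[2]))
  if (!is.null(x$agreement_percent))
    cat(sprintf("  agreement with calibration points: %.2f%%\n",
                x$agreement_percent))
  invisible(x)
}

#' @export
coef.belt_calibration <- function(object, ...) {
  c(a2 = object$a2, a1 = object$a1, a0 = object$a0)
}

#' @export
predict.belt_calibration <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- newdata$capacitance_nF
  capacitance_to_length(object, newdata)
}

#' @export
plot.belt_calibration <- function(x, ...) {
  cs <- seq(x$valid_range[1], x$valid_range[2], length.out = 200)
  graphics::plot(cs, capacitance_to_length(x, cs), type = "l", col = "red",
                 xlab = "capacitance (nF)", ylab = "elastic-part length (mm)",
                 ...)
  if (!is.null(x$points))
    graphics::points(x$points$capacitance_nF, x$points$length_mm, pch = 1)
  invisible(x)
}

#' Convert capacitance to elastic-part length
#'
#' Evaluates the calibration quadratic. Capacitances outside the curve's
#' validity range are extrapolated with a warning (walking data may
#' transiently exceed the static calibration sweep), never an error.
#'
#' @param curve A `belt_calibration` object.
#' @param C Capacitance in nF (vectorized, finite).
#' @return Length in mm.
#' @export
capacitance_to_length <- function(curve, C) {
  stopifnot(inherits(curve, "belt_calibration"))
  if (length(C) < 1L || anyNA(C) || any(!is.finite(C)))
    stop("capacitance must be finite")
  out <- sum(C < curve$valid_range[1] | C > curve$valid_range[2])
  if (out > 0)
    warning(sprintf("%d capacitance value(s) outside the calibration range [%.4g, %.4g] nF; extrapolating",
                    out, curve$valid_range[1], curve$valid_range[2]))
  curve$a2 * C^2 + curve$a1 * C + curve$a0
}

#' Convert elastic-part length to capacitance
#'
#' Inverts the calibration quadratic on its monotone increasing branch:
#' for `a2 > 0` the larger root
#' \deqn{C = \frac{-a_1 + \sqrt{a_1^2 - 4 a_2 (a_0 - L)}}{2 a_2}.}
#' Lengths below the parabola minimum have no solution and raise an error
#' naming the first offending element.
#'
#' @param curve A `belt_calibration` object.
#' @param L Length in mm (vectorized, finite).
#' @return Capacitance in nF.
#' @export
length_to_capacitance <- function(curve, L) {
  stopifnot(inherits(curve, "belt_calibration"))
  if (length(L) < 1L || anyNA(L) || any(!is.finite(L)))
    stop("length must be finite")
  if (curve$a2 == 0) {
    if (curve$a1 == 0) stop("constant calibration curve cannot be inverted")
    return((L - curve$a0) / curve$a1)
  }
  disc <- curve$a1^2 - 4 * curve$a2 * (curve$a0 - L)
  bad <- which(disc < 0)
  if (length(bad))
    stop(sprintf("no solution: length %.6g mm (element %d) is below the parabola minimum %.6g mm",
                 L[bad[1]], bad[1],
                 curve$a0 - curve$a1^2 / (4 * curve$a2)))
  if (curve$a2 > 0)
    (-curve$a1 + sqrt(disc)) / (2 * curve$a2)
  else
    (-curve$a1 - sqrt(disc)) / (2 * curve$a2)   # increasing branch for a2 < 0
}

#' Percent agreement of a calibration curve with measured points
#'
#' 100 times the coefficient of determination of the curve's length
#' predictions: `100 * (1 - SS_res / SS_tot)`.
#'
#' @param points Data frame with `capacitance_nF`, `length_mm` (>= 2 rows).
#' @param curve A `belt_calibration` object.
#' @return Agreement in percent (at most 100; can be negative for a curve
#'   worse than the mean).
#' @export
goodness_of_fit <- function(points, curve) {
  points <- validate_points(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  ss_tot <- sum((points$length_mm - mean(points$length_mm))^2)
  if (ss_tot == 0) stop("undefined fit: zero length variance")
  pred <- suppressWarnings(capacitance_to_length(curve, points$capacitance_nF))
  ss_res <- sum((points$length_mm - pred)^2)
  100 * (1 - ss_res / ss_tot)
}

#' Hysteresis index between stretch and release sweeps
#'
#' Interpolates the forward (stretching) and backward (shrinking) sweeps
#' onto the union of their length abscissae within the overlapping length
#' range and reports the maximum absolute capacitance difference. A
#' hysteresis-free sensor gives values near zero (limited by interpolation
#' error when sample positions interleave).
#'
#' @param forward_sweep,backward_sweep Data frames with `capacitance_nF`,
#'   `length_mm`.
#' @return Maximum absolute capacitance difference in nF.
#' @export
hysteresis_index <- function(forward_sweep, backward_sweep) {
  f <- validate_points(forward_sweep, "forward_sweep")
  b <- validate_points(backward_sweep, "backward_sweep")
  lo <- max(min(f$length_mm), min(b$length_mm))
  hi <- min(max(f$length_mm), max(b$length_mm))
  if (lo > hi) stop("sweeps have non-overlapping length ranges")
  grid <- sort(unique(c(f$length_mm, b$length_mm)))
  grid <- grid[grid >= lo & grid <= hi]
  cf <- stats::approx(f$length_mm, f$capacitance_nF, xout = grid, ties = mean)$y
  cb <- stats::approx(b$length_mm, b$capacitance_nF, xout = grid, ties = mean)$y
  max(abs(cf - cb))
}

#' Mechanical and material characterization of the sensor
#'
#' Elongation of the elastic part between its natural and stretched lengths,
#' and the areal density of the flocked conductive layer.
#'
#' @param L0 Natural length in mm (> 0).
#' @param L1 Stretched length in mm.
#' @param added_mass Mass added by flocking, in mg.
#' @param flock_width,flock_depth Flocked area dimensions in mm (> 0).
#' @return List with `elongation_percent` and `areal_density` (mg/mm^2).
#' @examples
#' sensor_characterization(95, 200, added_mass = 18,
#'                         flock_width = 15, flock_depth = 150)
#' @export
sensor_characterization <- function(L0, L1, added_mass, flock_width, flock_depth) {
  if (!is.finite(L0) || L0 <= 0) stop("natural length L0 must be positive")
  if (!is.finite(flock_width) || !is.finite(flock_depth) ||
      flock_width * flock_depth <= 0)
    stop("flocked area must be positive")
  list(elongation_percent = 100 * (L1 - L0) / L0,
       areal_density = added_mass / (flock_width * flock_depth))
}

#' Read or write calibration points as two-column CSV
#'
#' @param path File path; columns `capacitance_nF`, `length_mm`.
#' @return `read_calibration_points` returns a data frame.
#' @export
read_calibration_points <- function(path) {
  validate_points(utils::read.csv(path))
}

#' @rdname read_calibration_points
#' @param points Data frame of calibration points.
#' @export
write_calibration_points <- function(points, path) {
  utils::write.csv(validate_points(points), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a calibration curve to or from JSON
#'
#' The JSON object carries `a2`, `a1`, `a0`, `c_lo`, `c_hi`.
#'
#' @param curve A `belt_calibration` object.
#' @param path File path.
#' @export
write_calibration_json <- function(curve, path) {
  stopifnot(inherits(curve, "belt_calibration"))
  jsonlite::write_json(list(a2 = curve$a2, a1 = curve$a1, a0 = curve$a0,
                            c_lo = curve$valid_range[1],
                            c_hi = curve$valid_range[2]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(a2 = x$a2, a1 = x$a1, a0 = x$a0,
                 valid_range = c(x$c_lo, x$c_hi)),
            class = "belt_calibration")
}
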