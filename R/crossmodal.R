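#' Quadratic design matrix from five muscle activities
#'
#' Builds the feature matrix of the cross-modal model
#' \deqn{\hat L_t = \sum_{i=1}^{5} (w_{i1} A_{it} + w_{i2} A_{it}^2) + b,}
#' with columns ordered `[A_1 .. A_5, A_1^2 .. A_5^2, 1]` in the fixed
#' muscle order VL, RF, VM, BFL, BFS.
#'
#' @param activities T x 5 numeric matrix (or data frame) of muscle
#'   activities in fractions of MVC.
#' @return T x 11 numeric matrix including the intercept column.
#' @export
build_design <- function(activities) {
  A <- as_activity_matrix(activities)
  X <- cbind(A, A^2, 1)
  colnames(X) <- c(paste0(muscle_names(), "_lin"),
                   paste0(muscle_names(), "_quad"), "intercept")
  X
}

as_activity_matrix <- function(activities) {
  if (is.data.frame(activities)) activities <- as.matrix(activities)
  if (is.list(activities) && !is.matrix(activities))
    activities <- do.call(cbind, lapply(activities, function(a)
      if (inherits(a, "belt_ts")) a$values else as.numeric(a)))
  if (!is.matrix(activities) || ncol(activities) != 5L)
    stop(sprintf("expected exactly 5 muscle activity channels (%s), got %s",
                 paste(muscle_names(), collapse = ", "),
                 if (is.matrix(activities)) ncol(activities) else "a non-matrix"))
  storage.mode(activities) <- "double"
  if (anyNA(activities) || any(!is.finite(activities)))
    stop("activities must be finite")
  if (!is.null(colnames(activities)) &&
      all(muscle_names() %in% colnames(activities)))
    activities <- activities[, muscle_names(), drop = FALSE]
  colnames(activities) <- muscle_names()
  activities
}

#' Fit the quadratic cross-modal circumference model
#'
#' Estimates the coefficients of the quadratic mapping from the five thigh
#' muscle activities to belt circumference by least squares, minimizing
#' \deqn{E = \sum_{t=1}^{T} (L_t - \hat L_t)^2.}
#' The solver is SVD-based: full-rank designs give the unique ordinary
#' least-squares solution, rank-deficient designs (e.g. strongly collinear
#' activities under sustained co-contraction) give the minimum-norm
#' solution with a warning.
#'
#' @param activities T x 5 matrix of activities (fractions of MVC), columns
#'   in the order of [muscle_names()] (named columns are reordered).
#' @param circumference Length-T numeric vector (or [belt_ts()]) of measured
#'   circumference in mm.
#' @return An object of class `crossmodal`: list with `w1`, `w2` (named
#'   5-vectors, mm per unit activity and mm per unit squared activity),
#'   intercept `b` (mm), `muscle_order`, `fitted`, `residuals`, `rmse`,
#'   `n_frames`, `rank`.
#' @examples
#' truth <- default_truth_model()
#' A <- matrix(runif(500), 100, 5)
#' L <- predict(truth, A)
#' fit <- crossmodal_fit(A, L)
#' all.equal(coef(fit), coef(truth), tolerance = 1e-8)
#' @export
crossmodal_fit <- function(activities, circumference) {
  if (inherits(circumference, "belt_ts")) circumference <- circumference$values
  y <- as.numeric(circumference)
  if (anyNA(y) || any(!is.finite(y))) stop("circumference must be finite")
  X <- build_design(activities)
  if (nrow(X) != length(y))
    stop(sprintf("activities (%d frames) and circumference (%d) disagree in length",
                 nrow(X), length(y)))
  if (nrow(X) < ncol(X))
    warning(sprintf("under-determined fit: %d frames for %d parameters; returning the minimum-norm solution",
                    nrow(X), ncol(X)))
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  rank <- sum(pos)
  if (rank < ncol(X) && nrow(X) >= ncol(X))
    warning(sprintf("rank-deficient design (rank %d of %d); returning the minimum-norm least-squares solution",
                    rank, ncol(X)))
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  beta <- drop(beta)
  model <- new_crossmodal(w1 = beta[1:5], w2 = beta[6:10], b = beta[11])
  model$fitted <- drop(X %*% beta)
  model$residuals <- y - model$fitted
  model$rmse <- sqrt(mean(model$residuals^2))
  model$n_frames <- length(y)
  model$rank <- rank
  model
}

new_crossmodal <- function(w1, w2, b) {
  w1 <- as.numeric(w1); w2 <- as.numeric(w2); b <- as.numeric(b)
  if (length(w1) != 5L || length(w2) != 5L || length(b) != 1L ||
      any(!is.finite(c(w1, w2, b))))
    stop("a cross-modal model needs finite w1[5], w2[5] and scalar b")
  names(w1) <- names(w2) <- muscle_names()
  structure(list(w1 = w1, w2 = w2, b = b, muscle_order = muscle_names()),
            class = "crossmodal")
}

#' Construct a cross-modal model from known coefficients
#'
#' @param w1,w2 Length-5 numeric vectors of linear and quadratic
#'   coefficients in the order of [muscle_names()].
#' @param b Intercept in mm.
#' @return A `crossmodal` object (without fit diagnostics).
#' @export
crossmodal_model <- function(w1, w2, b) new_crossmodal(w1, w2, b)

#' @export
coef.crossmodal <- function(object, ...) {
  c(stats::setNames(object$w1, paste0(muscle_names(), "_lin")),
    stats::setNames(object$w2, paste0(muscle_names(), "_quad")),
    intercept = object$b)
}

#' @export
print.crossmodal <- function(x, ...) {
  cat("Quadratic cross-modal model: circumference ~ 5 muscle activities\n")
  tab <- rbind(w1 = x$w1, w2 = x$w2)
  print(round(tab, 4))
  cat(sprintf("intercept b = %.4f mm\n", x$b))
  if (!is.null(x$rmse))
    cat(sprintf("fit: T = %d frames, RMSE = %.4g mm, design rank %d/11\n",
                x$n_frames, x$rmse, x$rank))
  invisible(x)
}

#' @export
summary.crossmodal <- function(object, ...) {
  structure(list(model = object), class = "summary.crossmodal")
}

#' @export
print.summary.crossmodal <- function(x, ...) {
  m <- x$model
  print(m)
  if (!is.null(m$residuals)) {
    cat("residuals (mm):\n")
    print(round(stats::quantile(m$residuals, c(0, .25, .5, .75, 1)), 4))
  }
  invisible(x)
}

#' @export
predict.crossmodal <- function(object, newdata, ...) {
  if (missing(newdata)) {
    if (is.null(object$fitted)) stop("no stored fit; supply 'newdata' activities")
    return(object$fitted)
  }
  drop(build_design(newdata) %*%
         c(object$w1, object$w2, object$b))
}

#' @export
residuals.crossmodal <- function(object, ...) {
  if (is.null(object$residuals)) stop("model carries no fit residuals")
  object$residuals
}

#' @export
fitted.crossmodal <- function(object, ...) {
  if (is.null(object$fitted)) stop("model carries no fitted values")
  object$fitted
}

#' @export
plot.crossmodal <- function(x, y, measured = NULL, ...) {
  if (is.null(measured)) {
    if (is.null(x$fitted)) stop("supply 'measured' or fit the model first")
    measured <- x$fitted + x$residuals
  }
  est <- x$fitted
  graphics::plot(est, measured, pch = 3, col = "darkgreen",
                 xlab = "estimated circumference (mm)",
                 ylab = "measured circumference (mm)", ...)
  rl <- regression_line(est, measured)
  graphics::abline(rl$intercept, rl$slope, col = "red", lwd = 2)
  invisible(x)
}

#' @export
simulate.crossmodal <- function(object, nsim = 1, seed = NULL,
                                activities = NULL, noise_sd = NULL, ...) {
  mu <- if (is.null(activities)) fitted(object) else predict(object, activities)
  if (is.null(noise_sd))
    noise_sd <- if (is.null(object$rmse)) 0 else object$rmse
  draw <- function() mu + stats::rnorm(length(mu), 0, noise_sd)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Root-mean-square error between two equal-length signals
#'
#' @param measured,estimated Numeric vectors of equal length.
#' @return RMSE in the common unit (mm for circumference).
#' @export
rmse <- function(measured, estimated) {
  measured <- as.numeric(measured); estimated <- as.numeric(estimated)
  if (length(measured) != length(estimated))
    stop("length mismatch between measured and estimated")
  sqrt(mean((measured - estimated)^2))
}

#' Ordinary least-squares agreement line
#'
#' Regresses the measured circumference (y) on the estimated one (x) and
#' returns the slope and intercept; perfect agreement is y = x.
#'
#' @param estimated,measured Numeric vectors (>= 2 points; the estimated
#'   values must vary).
#' @return List with `slope` and `intercept` (mm).
#' @export
regression_line <- function(estimated, measured) {
  x <- as.numeric(estimated); y <- as.numeric(measured)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 points")
  vx <- stats::var(x)
  if (vx == 0) stop("zero variance in the estimated circumference")
  slope <- stats::cov(x, y) / vx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation (Shrout-Fleiss) between two paired measurement series,
#' treating the paired frames as targets and the two series as raters
#' (k = 2):
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)},}
#' with mean squares from the two-way ANOVA decomposition (targets x
#' raters).
#'
#' @param x,y Paired numeric vectors in the same unit, n >= 3.
#' @return ICC(2,1), at most 1; `NA` with a warning when the total
#'   variance is zero.
#' @examples
#' icc_2_1(c(1, 2, 3), c(2, 3, 4))  # 2/3
#' @export
icc_2_1 <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(c(x, y)) || any(!is.finite(c(x, y)))) stop("inputs must be finite")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ss_tot <- sum((dat - grand)^2)
  if (ss_tot == 0) {
    warning("ICC undefined: zero total variance")
    return(NA_real_)
  }
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_e <- ss_tot - ss_r - ss_c
  msr <- ss_r / (n - 1)
  msc <- ss_c / (k - 1)
  mse <- ss_e / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' End-to-end evaluation of a session against the cross-modal model
#'
#' Runs the evaluation chain on one (typically synthetic) session: obtain
#' the five activities (either the processed MVC-normalized EMG envelopes
#' or, for validation against ground truth, the generator's true
#' activations), obtain the measured circumference (from the capacitance
#' channel through the calibration curve and 10 Hz low-pass, or the true
#' one), fit the quadratic model on the full-rate frames, predict, and
#' compute RMSE, the agreement regression line, and ICC(2,1) on pairs
#' resampled to `eval_rate` (default 10 Hz).
#'
#' @param session A `belt_session` (see [generate_session()]) or a list
#'   with compatible `channels`/`truth` entries.
#' @param curve Calibration curve; defaults to [default_calibration()].
#' @param activities_source `"envelope"` (process the raw EMG channels) or
#'   `"truth"` (use stored ground-truth activations).
#' @param circumference_source `"capacitance"` (invert + filter the
#'   capacitance channel) or `"truth"`.
#' @param eval_rate Resampling rate in Hz for the evaluation pairs.
#' @param mvc Optional named MVC vector for envelope normalization; when
#'   `NULL` each envelope is normalized by its own maximum.
#' @param lowpass_zero_lag Zero-lag mode for the envelope and circumference
#'   low-passes (phase-aligned variant).
#' @return An object of class `crossmodal_eval`: list with `model`,
#'   `rmse`, `icc21`, `regression_slope`, `regression_intercept`,
#'   `n_frames`, `n_eval`, and the evaluation `pairs` data frame
#'   (`estimated_mm`, `measured_mm`).
#' @export
evaluate_session <- function(session, curve = default_calibration(),
                             activities_source = c("envelope", "truth"),
                             circumference_source = c("capacitance", "truth"),
                             eval_rate = 10, mvc = NULL,
                             lowpass_zero_lag = FALSE) {
  activities_source <- match.arg(activities_source)
  circumference_source <- match.arg(circumference_source)
  ch <- session$channels
  rate <- ch[[1]]$rate

  A <- if (activities_source == "truth") {
    if (is.null(session$truth$activations))
      stop("session carries no ground-truth activations")
    as_activity_matrix(session$truth$activations)
  } else {
    envs <- lapply(muscle_names(), function(m) {
      nm <- paste0("emg_", m, "_V")
      if (is.null(ch[[nm]])) stop(sprintf("missing EMG channel '%s'", nm))
      emg_envelope(ch[[nm]], lowpass_zero_lag = lowpass_zero_lag)
    })
    names(envs) <- muscle_names()
    if (is.null(mvc)) mvc <- compute_mvc(envs)
    as_activity_matrix(lapply(muscle_names(), function(m)
      normalize_mvc(envs[[m]], mvc[[m]])))
  }

  L <- if (circumference_source == "truth") {
    if (is.null(session$truth$circumference))
      stop("session carries no ground-truth circumference")
    session$truth$circumference$values
  } else {
    if (is.null(ch$capacitance_nF)) stop("missing channel 'capacitance_nF'")
    suppressWarnings(
      process_circumference(ch$capacitance_nF, curve,
                            zero_lag = lowpass_zero_lag)$length$values)
  }

  model <- crossmodal_fit(A, L)
  est <- predict(model, A)
  step <- max(1L, round(rate / eval_rate))
  idx <- seq(1L, length(L), by = step)
  pairs <- data.frame(estimated_mm = est[idx], measured_mm = L[idx])
  rl <- regression_line(pairs$estimated_mm, pairs$measured_mm)
  structure(list(model = model,
                 rmse = rmse(pairs$measured_mm, pairs$estimated_mm),
                 icc21 = icc_2_1(pairs$measured_mm, pairs$estimated_mm),
                 regression_slope = rl$slope,
                 regression_intercept = rl$intercept,
                 n_frames = length(L), n_eval = nrow(pairs),
                 pairs = pairs),
            class = "crossmodal_eval")
}

#' @export
print.crossmodal_eval <- function(x, ...) {
  cat("Cross-modal session evaluation\n")
  cat(sprintf("  fit frames: %d; evaluation pairs: %d\n", x$n_frames, x$n_eval))
  cat(sprintf("  RMSE      : %.4g mm\n", x$rmse))
  cat(sprintf("  regression: y = %.4g x %+.4g\n",
              x$regression_slope, x$regression_intercept))
  cat(sprintf("  ICC(2,1)  : %.4g\n", x$icc21))
  invisible(x)
}

#' Serialize a cross-modal model to or from JSON
#'
#' JSON object with `muscles`, `w1`, `w2`, `b`.
#'
#' @param model A `crossmodal` object.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "crossmodal"))
  jsonlite::write_json(list(muscles = muscle_names(),
                            w1 = unname(model$w1), w2 = unname(model$w2),
                            b = model$b),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_crossmodal(x$w1, x$w2, x$b)
}
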