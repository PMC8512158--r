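test_that("design matrix has the fixed column layout", {
  A1 <- matrix(0, 1, 5)
  expect_equal(unname(build_design(A1)[1, ]), c(rep(0, 10), 1))
  A2 <- matrix(c(0.5, 0, 0, 0, 0), 1, 5)
  expect_equal(unname(build_design(A2)[1, ]),
               c(0.5, 0, 0, 0, 0, 0.25, 0, 0, 0, 0, 1))
  set.seed(1)
  A <- matrix(runif(50), 10, 5)
  X <- build_design(A)
  expect_equal(X[, 6:10], A^2, ignore_attr = TRUE)
  expect_equal(X[, 11], rep(1, 10), ignore_attr = TRUE)
  # named columns are reordered into the fixed muscle order
  colnames(A) <- rev(muscle_names())
  expect_equal(unname(build_design(A)[, 1]), A[, "VL"])
  expect_error(build_design(matrix(0, 5, 4)), "5 muscle")
})

test_that("least-squares fit recovers exact coefficients and handles degeneracy", {
  truth <- default_truth_model()
  set.seed(5)
  A <- matrix(runif(60 * 5), 60, 5)
  L <- predict(truth, A)
  fit <- crossmodal_fit(A, L)
  expect_equal(coef(fit), coef(truth), tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-8)
  expect_equal(predict(fit, A), L, tolerance = 1e-8)

  # all-zero activities: minimum-norm solution is the intercept-only model
  A0 <- matrix(0, 30, 5)
  L0 <- rnorm(30, 100, 1)
  expect_warning(fit0 <- crossmodal_fit(A0, L0), "rank-deficient")
  expect_equal(fit0$b, mean(L0))
  expect_equal(unname(c(fit0$w1, fit0$w2)), rep(0, 10))

  # single-muscle 3-frame toy: exact interpolation through the 3x3 system
  # A = (0, .5, 1), L = (1, 1.75, 3) -> w1 = 1, w2 = 1, b = 1
  A3 <- cbind(c(0, 0.5, 1), 0, 0, 0, 0)
  expect_warning(f3 <- crossmodal_fit(A3, c(1, 1.75, 3)), "under-determined")
  expect_equal(unname(c(f3$w1[1], f3$w2[1], f3$b)), c(1, 1, 1),
               tolerance = 1e-8)
  expect_equal(predict(f3, A3), c(1, 1.75, 3), tolerance = 1e-10)

  expect_error(crossmodal_fit(matrix(NA_real_, 20, 5), rnorm(20)), "finite")
})

test_that("fit equals the normal-equations oracle and is a local optimum", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(30:200, 1)
    A <- matrix(runif(n * 5), n, 5)
    L <- predict(default_truth_model(), A) + rnorm(n, 0, 1)
    fit <- crossmodal_fit(A, L)
    X <- build_design(A)
    beta <- normal_eq_solve(X, L)
    expect_equal(unname(coef(fit)), unname(beta), tolerance = 1e-8)
    # perturbing any coefficient never decreases the squared error
    E <- function(b) sum((L - X %*% b)^2)
    e0 <- E(beta)
    for (j in sample(11, 3)) {
      for (d in c(-1e-4, 1e-4)) {
        bp <- beta; bp[j] <- bp[j] + d
        expect_gte(E(bp), e0)
      }
    }
  }
})

test_that("rmse and the agreement regression line are as hand-computed", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(0, 2)), sqrt(2))
  expect_error(rmse(1:3, 1:4), "mismatch")

  expect_equal(regression_line(1:10, 1:10), list(slope = 1, intercept = 0))
  expect_equal(regression_line(1:10, 1:10 + 3), list(slope = 1, intercept = 3))
  rl <- regression_line(c(0, 1, 2), c(0, 2, 4))
  expect_equal(rl$slope, 2)
  expect_equal(rl$intercept, 0)
  expect_error(regression_line(rep(1, 5), 1:5), "zero variance")
})

test_that("ICC(2,1) matches hand ANOVA and an independent aov oracle", {
  expect_equal(icc_2_1(c(1, 2, 3), c(1, 2, 3)), 1)
  # hand ANOVA: MSR = 2, MSC = 1.5, MSE = 0 -> 2/3
  expect_equal(icc_2_1(c(1, 2, 3), c(2, 3, 4)), 2 / 3)
  set.seed(77)
  for (s in 1:5) {
    x <- rnorm(50, 100, 5)
    y <- x + rnorm(50, 0.5, 2)
    expect_equal(icc_2_1(x, y), icc_oracle_aov(x, y), tolerance = 1e-10)
    # symmetry and common-scale invariance
    expect_equal(icc_2_1(x, y), icc_2_1(y, x), tolerance = 1e-12)
    expect_equal(icc_2_1(3.2 * x, 3.2 * y), icc_2_1(x, y), tolerance = 1e-9)
  }
  expect_warning(iccc <- icc_2_1(rep(1, 5), rep(1, 5)), "zero total variance")
  expect_true(is.na(iccc))
  expect_error(icc_2_1(1:2, 1:2), "at least 3")
})

test_that("session evaluation is exact without noise and flags passive segments", {
  ns <- generate_session("walk", n_cycles = 5, circumference_noise_sd = 0,
                         seed = 12)
  r <- evaluate_session(ns, activities_source = "truth",
                        circumference_source = "truth")
  expect_lt(r$rmse, 1e-8)
  expect_equal(r$icc21, 1, tolerance = 1e-9)
  expect_equal(r$regression_slope, 1, tolerance = 1e-9)
  expect_equal(r$regression_intercept, 0, tolerance = 1e-6)

  # passive-deformation segment: zero activity but moving circumference
  # concentrates the residuals there
  act <- generate_session("squat", n_cycles = 4, circumference_noise_sd = 0,
                          seed = 13)
  pas <- generate_session("passive", circumference_noise_sd = 0, seed = 13)
  ses <- concat_sessions(act, pas)
  # few squat cycles make the per-muscle columns collinear; the fit falls
  # back to the minimum-norm solution, which is all this check needs
  suppressWarnings(
    r2 <- evaluate_session(ses, activities_source = "truth",
                           circumference_source = "truth"))
  n_act <- length(act$truth$circumference$values)
  res <- residuals(r2$model)
  in_passive <- seq_along(res) > n_act
  expect_gt(mean(abs(res[in_passive])), 2 * mean(abs(res[!in_passive])))
})

test_that("model methods and JSON serialization round-trip", {
  truth <- default_truth_model()
  set.seed(3)
  A <- matrix(runif(250), 50, 5)
  L <- predict(truth, A) + rnorm(50, 0, 0.5)
  fit <- crossmodal_fit(A, L)
  expect_equal(fitted(fit) + residuals(fit), L)
  expect_output(print(summary(fit)), "intercept")
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(50L, 3L))
  expect_equal(simulate(fit, nsim = 2, seed = 9), simulate(fit, nsim = 2, seed = 9))

  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(coef(back), coef(fit))
})
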