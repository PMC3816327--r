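test_that("double-gamma HRF has canonical shape", {
  h <- double_gamma_hrf(tr = 0.1)
  expect_equal(h$weights[1], 0)
  expect_equal(max(h$weights), 1)
  peak_t <- h$times[which.max(h$weights)]
  expect_gte(peak_t, 4); expect_lte(peak_t, 6)
  # the undershoot makes the late tail negative relative to the
  # undershoot-free kernel
  h_nou <- double_gamma_hrf(tr = 0.1, ratio = 1e9)
  late <- h$times > 10
  expect_lt(sum(h$weights[late] - h_nou$weights[late]) * 0.1, 0)
  expect_lt(min(h$weights), 0)
  expect_error(double_gamma_hrf(peak_delay = -1), "positive")
})

test_that("FIR design has one stick predictor per condition and bin", {
  ev <- data.frame(onset = c(0, 8, 16, 24, 32), duration = 1,
                   trial_type = c("a", "b", "c", "d", "e"))
  dm <- build_fir_design(ev, n_volumes = 60, tr = 1, n_bins = 20,
                         conditions = letters[1:5])
  expect_equal(sum(dm$columns$kind == "fir"), 100)
  expect_equal(sum(dm$columns$kind == "confound"), 1)

  # event at volume 7, bin 3 -> single 1 at volume index 10 (row 11)
  ev2 <- data.frame(onset = 7, duration = 1, trial_type = "a")
  dm2 <- build_fir_design(ev2, n_volumes = 30, tr = 1, n_bins = 20,
                          conditions = "a", mean_confound = FALSE)
  col <- dm2$X[, dm2$columns$condition == "a" & dm2$columns$bin == 3]
  expect_equal(which(col == 1), 11L)
  expect_equal(sum(col), 1)

  # no events -> all-zero stimulus columns
  dm3 <- build_fir_design(ev2, n_volumes = 30, tr = 1, n_bins = 5,
                          conditions = c("a", "zz"))
  expect_equal(max(abs(dm3$X[, dm3$columns$condition %in% "zz"])), 0)

  expect_error(build_fir_design(data.frame(onset = 99, duration = 1,
                                           trial_type = "a"),
                                n_volumes = 30, conditions = "a"),
               "outside")
})

test_that("single-trial design has one column per trial plus a mean
           confound, and recovers injected amplitudes", {
  d <- make_design(n_runs = 1, trials_per_condition = 1,
                   conditions = c("a", "b", "c"),
                   face_conditions = c("a", "b", "c"),
                   lead_in_volumes = 2, lead_out_volumes = 25, seed = 2)
  h <- double_gamma_hrf()
  ev <- d$trials
  dm <- build_single_trial_design(ev, d$n_volumes[1], 1, h,
                                  baseline_condition = "none")
  expect_equal(ncol(dm$X), nrow(ev) + 1)
  expect_equal(dm$X[, ncol(dm$X)], rep(1, d$n_volumes[1]))

  # noiseless forward simulation with per-trial amplitudes {1, 2, 0.5}
  reg <- region_truth(n_eye = 0, n_mouth = 0, n_rest = 1, n_outside = 0)
  amp <- matrix(c(1, 2, 0.5), 3, 1)
  run <- simulate_run(d, 1, reg, NULL, noise_model(sigma = 0), h,
                      trial_amplitudes = amp)
  fit <- fit_ols(dm, run)
  expect_equal(unname(fit$betas[1:3, 1]), c(1, 2, 0.5), tolerance = 1e-6)

  expect_error(
    build_single_trial_design(
      data.frame(onset = c(4, 4), duration = 1, trial_type = "a"),
      30, 1, h, baseline_condition = "none"),
    "identical onsets")
})

test_that("OLS matches closed forms and the normal-equations oracle", {
  # orthonormal design: betas = X'Y
  set.seed(31)
  q <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  y <- matrix(rnorm(12), 6, 2)
  fit <- fit_ols(q, t(y))
  expect_equal(fit$betas, crossprod(q, y), tolerance = 1e-12)

  # random small instances vs normal equations
  set.seed(42)
  for (i in 1:25) {
    X <- matrix(rnorm(24), 8, 3)
    y <- matrix(rnorm(8), 8, 1)
    fit <- fit_ols(X, t(y))
    expect_equal(unname(fit$betas), unname(oracle_ols(X, y)),
                 tolerance = 1e-10)
    expect_equal(fit$dof, 5)
  }

  # response in the column span -> zero residual variance
  X <- cbind(1, 1:10)
  y <- 2 + 3 * (1:10)
  fit <- fit_ols(X, t(matrix(y)))
  expect_equal(unname(fit$residual_variance), 0, tolerance = 1e-20)

  expect_error(fit_ols(X, matrix(0, 1, 7)), "volume count")
  expect_warning(fit_ols(cbind(1, 1, 1:5), t(matrix(rnorm(5)))),
                 "rank deficient")
})

test_that("t contrasts match the classical two-sample formula", {
  # two-group means model
  g <- rep(c(0, 1), each = 6)
  X <- cbind(1 - g, g)
  set.seed(3)
  y <- rnorm(12, mean = g)
  fit <- fit_ols(X, t(matrix(y)))
  tm <- t_contrast(fit, X, c(1, -1))
  tt <- t.test(y[g == 0], y[g == 1], var.equal = TRUE)
  expect_equal(unname(tm$t), unname(tt$statistic), tolerance = 1e-10)
  expect_equal(tm$dof, unname(tt$parameter))

  # zero weights -> t identically 0; sign flip negates t
  expect_equal(t_contrast(fit, X, c(0, 0))$t, 0)
  expect_equal(t_contrast(fit, X, c(-1, 1))$t, -tm$t)
  expect_error(t_contrast(fit, X, c(1, 0, 0)), "one entry per predictor")
})

test_that("peak/window summaries follow the 5-7 s and 3-9 s rules", {
  times <- 0:19
  expect_equal(peak_and_window(rep(4, 20), times)$peak, 4)
  expect_equal(peak_and_window(rep(4, 20), times)$window_mean, 4)

  y <- dnorm(times, mean = 6, sd = 1.2)
  pw <- peak_and_window(y, times)
  expect_equal(pw$peak_time, 6)
  expect_equal(pw$peak, y[7])

  pw2 <- peak_and_window(0:19, times)
  expect_equal(pw2$window_mean, mean(3:9))

  expect_error(peak_and_window(1:3, 0:2), "window")
})

test_that("fixed-effects design carries one confound per subject-run", {
  ev <- expand.grid(subject = 1:9, run = 1:6)
  ev$onset <- 2; ev$duration <- 1; ev$trial_type <- "happy"
  dm <- fixed_effects_design(ev, n_volumes = 10, tr = 1,
                             conditions = "happy")
  expect_equal(sum(dm$columns$kind == "confound"), 54)
  expect_equal(nrow(dm$X), 9 * 6 * 10)
  # boxcar condition columns never exceed 1 per row
  expect_lte(max(rowSums(dm$X[, dm$columns$kind == "condition",
                              drop = FALSE])), 1)

  one <- fixed_effects_design(ev[ev$subject == 1 & ev$run == 1, ],
                              n_volumes = 10, conditions = "happy")
  expect_equal(ncol(one$X), 2)
  expect_error(fixed_effects_design(ev[, c("onset", "duration",
                                           "trial_type")], 10),
               "subject")
})

test_that("FIR deconvolution recovers kernel x amplitude from a noiseless
           run", {
  # HRF support inside the 20 estimation bins so the FIR basis spans the
  # true response exactly
  h <- double_gamma_hrf(tr = 1, length_s = 19)
  d <- make_design(n_runs = 1, trials_per_condition = 10,
                   conditions = c("a", "b"), face_conditions = c("a", "b"),
                   lead_in_volumes = 5, lead_out_volumes = 25, seed = 8)
  reg <- region_truth(n_eye = 0, n_mouth = 0, n_rest = 3, n_outside = 0,
                      seed = 1)
  amps <- c(a = 1.5, b = 0.7)
  pat <- make_pattern_truth(reg, conditions = c("a", "b"),
                            tasks = unique(d$task_per_run),
                            base_amplitude = 0, mapping = character(0),
                            face_conditions = character(0),
                            signal = NULL)
  pat$amplitudes["a", , ] <- amps["a"]
  pat$amplitudes["b", , ] <- amps["b"]
  run <- simulate_run(d, 1, reg, pat, noise_model(sigma = 0), h)
  dm <- build_fir_design(d$trials, d$n_volumes[1], 1, n_bins = 20,
                         conditions = c("a", "b"))
  fit <- fit_ols(dm, run)
  for (cn in c("a", "b")) {
    rows <- which(dm$columns$condition %in% cn)
    est <- fit$betas[rows, 1]
    expect_equal(unname(est), amps[[cn]] * h$weights[1:20],
                 tolerance = 1e-6)
  }
})
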