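test_that("normalization maps training data onto [-1, 1] with the min-max
           affine rule", {
  x <- cbind(c(2, 4, 6), c(1, 1, 1), c(-3, 0, 9))
  norm <- fit_normalizer(x)
  z <- apply_normalizer(norm, x)
  expect_equal(z[, 1], c(-1, 0, 1))
  expect_equal(z[, 2], c(0, 0, 0))         # constant feature -> 0
  expect_equal(apply(z[, c(1, 3)], 2, min), c(-1, -1))
  expect_equal(apply(z[, c(1, 3)], 2, max), c(1, 1))

  # test data use the training parameters and may leave the range
  test <- rbind(c(6, 5, 9), c(2 - 4, 1, -3))  # train max; min - range
  zt <- apply_normalizer(norm, test)
  expect_equal(zt[1, 1], 1)
  expect_equal(zt[2, 1], -3)
  # round trip on the training set equals fit-transform
  expect_equal(apply_normalizer(norm, x), z)
  expect_error(apply_normalizer(norm, x[, 1:2]), "feature count")
})

test_that("sub-sampling schedule gives 15 strictly increasing sizes up to
           160", {
  s <- subsample_schedule(160)
  expect_length(s, 15)
  expect_equal(s[1], 1)
  expect_equal(s[15], 160)
  expect_true(all(diff(s) > 0))

  expect_warning(s1 <- subsample_schedule(1), "distinct")
  expect_equal(s1, 1)
  s2 <- subsample_schedule(300)            # capped at max_size
  expect_equal(max(s2), 160)
  expect_warning(s3 <- subsample_schedule(7), "distinct")
  expect_true(all(s3 <= 7) && all(diff(s3) > 0))

  arith <- subsample_schedule(160, mode = "arithmetic")
  expect_equal(arith, seq(1, 151, by = 10))
})

test_that("feature draws are without replacement, 30 by default, and
           seed-reproducible", {
  d <- draw_subsets(50, 10, seed = 4)
  expect_length(d, 30)
  expect_true(all(vapply(d, function(s) !anyDuplicated(s), logical(1))))
  expect_identical(d, draw_subsets(50, 10, seed = 4))
  expect_false(identical(d, draw_subsets(50, 10, seed = 5)))
  full <- draw_subsets(10, 10, n_draws = 3, seed = 1)
  expect_true(all(vapply(full, function(s) setequal(s, 1:10), logical(1))))
  expect_error(draw_subsets(5, 6), "exceeds")
})

test_that("linear SVM separates separable data and matches a brute-force
           margin oracle", {
  X <- rbind(c(-2, 0), c(-1, 1), c(2, 0), c(1, -1))
  y <- c("a", "a", "b", "b")
  m <- train_linear_classifier(X, y, cost = 1000)
  expect_equal(predict(m, X), y)

  # geometric margin 1/||w|| vs grid search over unit normals
  w <- drop(t(m$model$coefs) %*% m$model$SV)
  expect_equal(1 / sqrt(sum(w^2)), oracle_max_margin_2d(X, y),
               tolerance = 1e-3)

  # duplicating every training point leaves the decision function intact
  m2 <- train_linear_classifier(rbind(X, X), c(y, y), cost = 1000)
  grid <- as.matrix(expand.grid(seq(-3, 3, 0.5), seq(-3, 3, 0.5)))
  expect_equal(predict(m, grid), predict(m2, grid))

  expect_error(train_linear_classifier(X, rep("a", 4)), "single class")
})

test_that("leave-one-run-out produces one leak-free fold per run", {
  pats <- separable_patterns(1, n_runs = 6)
  res <- loro_cv(pats, seed = 1)
  expect_equal(res$n_folds, 6)
  runs_tested <- vapply(res$folds, `[[`, FUN.VALUE = 1, "run")
  expect_equal(sort(runs_tested), 1:6)
  for (f in res$folds) {
    expect_length(intersect(pats$run_ids[f$train_index],
                            pats$run_ids[f$test_index]), 0)
    # normalization parameters are a function of the training rows only
    expect_equal(f$norm,
                 fit_normalizer(pats$betas[f$train_index, , drop = FALSE]))
  }
  # perfectly separable patterns decode at 100% in both test modes
  expect_equal(res$accuracy, 100)
  expect_equal(loro_cv(pats, test_mode = "averaged", seed = 1)$accuracy,
               100)
  expect_error(loro_cv(trial_patterns(matrix(1:4, 2), c("a", "b"),
                                      c(1, 1))), "2 runs")
})

test_that("decoding is deterministic and calibrated at chance under label
           shuffling", {
  pats <- separable_patterns(2)
  expect_identical(loro_cv(pats, set_sizes = c(2, 5), n_draws = 5,
                           seed = 9),
                   loro_cv(pats, set_sizes = c(2, 5), n_draws = 5,
                           seed = 9))

  accs <- vapply(1:25, function(s) {
    p <- null_patterns(s, n_runs = 4, per_class = 8, n_feat = 12)
    loro_cv(p, seed = s)$accuracy
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 50), 2 * se + 1e-9)

  # three-class null sits at 33.3%
  accs3 <- vapply(1:25, function(s) {
    p <- null_patterns(100 + s, n_runs = 4, per_class = 6, n_feat = 12,
                       classes = c("a", "b", "c"))
    loro_cv(p, seed = s)$accuracy
  }, numeric(1))
  se3 <- sd(accs3) / sqrt(length(accs3))
  expect_lt(abs(mean(accs3) - 100 / 3), 2 * se3 + 1e-9)
})

test_that("accuracy grows with signal strength and averaged test patterns
           beat single trials on noisy data", {
  mean_acc <- function(delta) {
    mean(vapply(1:8, function(s) {
      p <- separable_patterns(200 + s, n_runs = 4, per_class = 8,
                              n_feat = 8, delta = delta, noise = 2)
      loro_cv(p, seed = s)$accuracy
    }, numeric(1)))
  }
  accs <- vapply(c(0, 0.4, 1.2), mean_acc, numeric(1))
  expect_true(all(diff(accs) > -5))     # non-decreasing within 1 SE-ish
  expect_gt(accs[3], accs[1])

  wins <- vapply(1:25, function(s) {
    p <- separable_patterns(300 + s, n_runs = 4, per_class = 8,
                            n_feat = 8, delta = 0.35, noise = 2)
    avg <- loro_cv(p, test_mode = "averaged", seed = s)$accuracy
    st <- loro_cv(p, test_mode = "single_trial", seed = s)$accuracy
    avg >= st
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("group performance test matches the closed-form one-sample t", {
  g <- group_performance_test(c(60, 70, 80), chance = 50)
  expect_equal(g$t, 20 / (10 / sqrt(3)), tolerance = 1e-12)
  expect_equal(g$p, pt(g$t, 2, lower.tail = FALSE))
  expect_equal(g$dof, 2)

  flat <- group_performance_test(rep(50, 5), chance = 50)
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 0.5)

  expect_equal(group_performance_test(rnorm(9, 60), 50)$dof, 8)
  expect_error(group_performance_test(55, 50), "at least 2")
})
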