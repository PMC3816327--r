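test_that("default design reproduces the experimental protocol", {
  d <- make_design(seed = 3)
  expect_equal(nrow(d$trials), 720)
  expect_true(all(table(d$trials$trial_type) == 120))
  expect_equal(d$n_runs, 6)
  expect_equal(d$task_per_run,
               rep(c("expression", "gender"), 3))
  for (r in seq_len(6)) {
    on <- d$trials$onset[d$trials$run == r]
    expect_true(all(on >= 0))
    expect_equal(diff(on), rep(4, 119))  # 1 s stimulus + 3 s fixation
  }
  g <- table(d$trials$gender)
  expect_equal(as.vector(g[c("female", "male")]), c(180L, 180L))
})

test_that("design edge cases: empty table, forced onset arithmetic, errors", {
  empty <- make_design(n_runs = 1, trials_per_condition = 0,
                       conditions = c("x", "y"), face_conditions = "x",
                       seed = 1)
  expect_equal(nrow(empty$trials), 0)

  d <- make_design(n_runs = 1, trials_per_condition = 3,
                   conditions = c("A", "B"), face_conditions = character(0),
                   stim_duration = 1, fixation_gap = 3,
                   lead_in_volumes = 0, lead_out_volumes = 0, seed = 5)
  expect_equal(d$trials$onset, seq(0, 20, by = 4))
  tab <- table(d$trials$trial_type)
  expect_equal(as.vector(tab[c("A", "B")]), c(3L, 3L))

  expect_error(make_design(face_conditions = "smirk", seed = 1),
               "unknown condition")
  expect_error(make_design(n_runs = 6, trials_per_condition = 121, seed = 1),
               "divisible")
})

test_that("designs, runs and traces are bit-reproducible for fixed seeds", {
  expect_identical(make_design(seed = 11), make_design(seed = 11))
  expect_false(identical(make_design(seed = 11)$trials$trial_type,
                         make_design(seed = 12)$trials$trial_type))

  reg <- region_truth(n_eye = 3, n_mouth = 3, n_rest = 4, n_outside = 2,
                      seed = 2)
  d <- make_design(n_runs = 2, trials_per_condition = 4, seed = 2)
  pat <- make_pattern_truth(reg, seed = 2)
  nm <- noise_model(sigma = 1, ar1 = 0.3, drift_slope = 0.05, seed = 9)
  h <- double_gamma_hrf()
  expect_identical(simulate_run(d, 1, reg, pat, nm, h),
                   simulate_run(d, 1, reg, pat, nm, h))
  expect_identical(simulate_gaze(seed = 4), simulate_gaze(seed = 4))
})

test_that("region labels partition the voxel set", {
  reg <- region_truth(n_eye = 7, n_mouth = 5, n_rest = 11, n_outside = 3,
                      seed = 1)
  expect_equal(reg$n_voxels, 26)
  expect_equal(sum(reg$counts), reg$n_voxels)
  labs <- c("eye", "mouth", "rest_v1", "outside")
  idx <- lapply(labs, region_voxels, region = reg)
  expect_equal(sort(unlist(idx)), seq_len(26))   # disjoint cover
  expect_true(all(reg$preferred_angle >= 0 & reg$preferred_angle < 360))
})

test_that("forward model is linear in the amplitudes and matches a direct
           convolution oracle", {
  d <- make_design(n_runs = 1, trials_per_condition = 2,
                   conditions = c("happy", "fear"),
                   face_conditions = c("happy", "fear"),
                   lead_in_volumes = 2, lead_out_volumes = 20, seed = 7)
  reg <- region_truth(n_eye = 0, n_mouth = 0, n_rest = 1, n_outside = 0)
  h <- double_gamma_hrf()
  silent <- noise_model(sigma = 0)

  # zero amplitudes -> all-zero matrix
  pat0 <- make_pattern_truth(reg, conditions = d$conditions,
                             tasks = "expression", base_amplitude = 0,
                             mapping = character(0),
                             face_conditions = d$face_conditions)
  run0 <- simulate_run(d, 1, reg, pat0, silent, h)
  expect_equal(max(abs(run0$data)), 0)

  # single trial, amplitude 1: equals the direct-summation convolution
  d1 <- make_design(n_runs = 1, trials_per_condition = 1,
                    conditions = "happy", face_conditions = "happy",
                    lead_in_volumes = 3, lead_out_volumes = 30, seed = 1)
  pat1 <- make_pattern_truth(reg, conditions = "happy",
                             tasks = "expression", base_amplitude = 1,
                             mapping = character(0),
                             face_conditions = "happy")
  run1 <- simulate_run(d1, 1, reg, pat1, silent, h)
  box <- numeric(d1$n_volumes[1])
  box[round(d1$trials$onset) + 1] <- 1
  expect_equal(as.numeric(run1$data), oracle_convolve(box, h$weights),
               tolerance = 1e-10)

  # doubling amplitudes doubles the noise-free signal exactly
  pat2 <- make_pattern_truth(reg, conditions = d$conditions,
                             tasks = "expression", base_amplitude = 2,
                             mapping = character(0),
                             face_conditions = d$face_conditions)
  pat1b <- make_pattern_truth(reg, conditions = d$conditions,
                              tasks = "expression", base_amplitude = 1,
                              mapping = character(0),
                              face_conditions = d$face_conditions)
  expect_equal(simulate_run(d, 1, reg, pat2, silent, h)$data,
               2 * simulate_run(d, 1, reg, pat1b, silent, h)$data)

  # mismatched voxel counts are rejected
  reg2 <- region_truth(n_eye = 0, n_mouth = 0, n_rest = 2, n_outside = 0)
  expect_error(simulate_run(d, 1, reg2, pat1b, silent, h), "voxel count")
})

test_that("checkerboard geometry preserves the eye/mouth area equality", {
  g <- checkerboard_geometry()
  expect_equal(g$mouth_area, 2.8 * 7.2)
  expect_equal(g$eye_area_total, 2 * 2.8 * 3.6)
  expect_equal(g$mouth_area, g$eye_area_total)
  expect_equal(g$vertical_separation, 4.9)
  g3 <- checkerboard_geometry(scale = 3)
  expect_equal(g3$mouth_area, 9 * g$mouth_area)
  expect_equal(g3$mouth_area, g3$eye_area_total)
})

test_that("gaze simulation injects clean square-pulse excursions", {
  flat <- simulate_gaze(duration = 2, rate = 60, fixation_noise_sd = 0,
                        seed = 1)
  expect_equal(max(abs(flat$samples)), 0)
  expect_error(simulate_gaze(rate = 0), "rate")

  sac <- data.frame(onset = 1, amplitude = 2, duration_ms = 200)
  tr <- simulate_gaze(duration = 4, rate = 60, fixation_noise_sd = 0,
                      saccades = sac, seed = 1)
  r <- sqrt(rowSums(tr$samples^2))
  expect_equal(sum(r > 1.5), round(0.2 * 60))
})

test_that("a null pattern truth has identical amplitudes across classes", {
  reg <- region_truth(n_eye = 2, n_mouth = 2, n_rest = 4, n_outside = 1)
  pat <- make_pattern_truth(reg, signal = NULL)
  expect_equal(pat$amplitudes["happy", "expression", ],
               pat$amplitudes["fear", "expression", ])
  # mapping conditions only drive their own region
  eye_amp <- pat$amplitudes["eye_map", "gender", ]
  expect_true(all(eye_amp[region_voxels(reg, "eye")] == 1))
  expect_true(all(eye_amp[-region_voxels(reg, "eye")] == 0))
  # planted signal differentiates classes in the right region only
  sig <- data.frame(condition = "happy", task = "*", region = "rest_v1",
                    delta = 0.5)
  pat2 <- make_pattern_truth(reg, signal = sig, seed = 3)
  diffs <- pat2$amplitudes["happy", "expression", ] -
    pat2$amplitudes["fear", "expression", ]
  expect_true(all(diffs[region_voxels(reg, "rest_v1")] != 0))
  expect_true(all(diffs[-region_voxels(reg, "rest_v1")] == 0))
  expect_gt(pattern_cnr(pat2, noise_model(sigma = 1),
                        c("happy", "fear"), "expression"), 0)
})
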