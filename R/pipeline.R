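#' Configuration for a full simulated experiment
#'
#' Collects every tunable of the end-to-end pipeline, with defaults mirroring
#' the study conditions: nine subjects, six runs of 720/6 trials (120 per
#' condition over six conditions) at 4 s SOA and TR 1 s, alternating
#' expression/gender tasks, 0.006 Hz high-pass plus linear detrending,
#' feature patches thresholded at t = 3.2 (lowered to 1.5 for the
#' dilation-subtraction rest region), responsive-map correction at
#' P < 0.0001 (Bonferroni), 20-bin FIR deconvolution, and sub-sampled
#' leave-one-run-out SVM decoding (C = 1, 30 draws, 15 set sizes up to
#' 160).
#'
#' @param n_subjects Number of independently simulated subjects.
#' @param n_runs,trials_per_condition,conditions,face_conditions,baseline_condition,tasks,tr
#'   Design parameters, see [make_design()].
#' @param region_sizes Named voxel counts (eye, mouth, rest_v1, outside).
#' @param sigma,ar1,drift_slope Noise model, see [noise_model()].
#' @param base_amplitude,mapping_amplitude Ground-truth amplitudes, see
#'   [make_pattern_truth()].
#' @param signal `NULL` for a null cohort, or a planted-signal data frame,
#'   see [make_pattern_truth()].
#' @param highpass_hz,detrend Preprocessing, see [highpass()].
#' @param strict_threshold,lowered_threshold,responsive_alpha POI stage.
#' @param fir_bins FIR deconvolution bins.
#' @param classifications Subset of `"happy_fear"`, `"male_female"`,
#'   `"expression3"`.
#' @param test_modes Subset of `"averaged"`, `"single_trial"`.
#' @param svm_cost SVM cost parameter.
#' @param subsample Use the sub-sampling schedule (30 draws per set size);
#'   turn off for quick runs (full feature set per region).
#' @param n_draws,n_sizes,max_size Sub-sampling schedule parameters.
#' @param run_wedge Also simulate a rotating-wedge run and compute the
#'   phase map per subject.
#' @param gaze_rate,gaze_noise_sd Gaze simulation parameters.
#' @return A list of class `fd_config`.
#' @export
pipeline_config <- function(n_subjects = 9, n_runs = 6,
                            trials_per_condition = 120,
                            conditions = c("happy", "fear", "neutral",
                                           "eye_map", "mouth_map",
                                           "baseline"),
                            face_conditions = c("happy", "fear", "neutral"),
                            baseline_condition = "baseline",
                            tasks = c("expression", "gender"), tr = 1,
                            region_sizes = c(eye = 60, mouth = 60,
                                             rest_v1 = 160, outside = 40),
                            sigma = 1, ar1 = 0, drift_slope = 0.01,
                            base_amplitude = 1, mapping_amplitude = 1,
                            signal = NULL,
                            highpass_hz = 0.006, detrend = TRUE,
                            strict_threshold = 3.2, lowered_threshold = 1.5,
                            responsive_alpha = 1e-4, fir_bins = 20,
                            classifications = c("happy_fear", "male_female",
                                                "expression3"),
                            test_modes = c("averaged", "single_trial"),
                            svm_cost = 1, subsample = TRUE, n_draws = 30,
                            n_sizes = 15, max_size = 160,
                            run_wedge = FALSE,
                            gaze_rate = 60, gaze_noise_sd = 0.05) {
  cfg <- as.list(environment())
  structure(cfg, class = "fd_config")
}

# chance level (%) for a classification cell
.chance_level <- function(classification) {
  if (classification == "expression3") 100 / 3 else 50
}

#' Simulate and analyse one subject
#'
#' Runs the complete single-subject chain on synthetic data: design
#' generation, forward simulation of all runs, detrending and high-pass
#' filtering, a concatenated condition GLM for the feature-mapping and
#' responsive contrasts, POI definition (eye, mouth, rest-of-V1), per-run
#' single-trial GLMs, FIR deconvolution summaries, sub-sampled
#' leave-one-run-out decoding per region, task, classification and test
#' mode, and gaze screening.  Only the synthesis stage sees the ground
#' truth; the analysis stages consume the simulated data plus the V1 mask
#' (the synthetic stand-in for anatomical delineation).
#'
#' @param config An `fd_config` from [pipeline_config()].
#' @param seed Integer seed for this subject.
#' @param subject_id Identifier carried into the results.
#' @return A list with POIs, decoding rows, univariate summaries, gaze
#'   screening results, and (optionally) the wedge phase map.
#' @export
run_subject <- function(config = pipeline_config(), seed = 1,
                        subject_id = 1L) {
  cfg <- config
  design <- make_design(n_runs = cfg$n_runs,
                        trials_per_condition = cfg$trials_per_condition,
                        conditions = cfg$conditions,
                        face_conditions = cfg$face_conditions,
                        baseline_condition = cfg$baseline_condition,
                        tr = cfg$tr, tasks = cfg$tasks,
                        seed = derive_seed(seed, 1))
  region <- region_truth(n_eye = cfg$region_sizes[["eye"]],
                         n_mouth = cfg$region_sizes[["mouth"]],
                         n_rest = cfg$region_sizes[["rest_v1"]],
                         n_outside = cfg$region_sizes[["outside"]],
                         seed = derive_seed(seed, 2))
  pattern <- make_pattern_truth(region, conditions = cfg$conditions,
                                tasks = cfg$tasks,
                                base_amplitude = cfg$base_amplitude,
                                mapping_amplitude = cfg$mapping_amplitude,
                                face_conditions = cfg$face_conditions,
                                baseline_condition = cfg$baseline_condition,
                                signal = cfg$signal,
                                seed = derive_seed(seed, 3))
  noise <- noise_model(sigma = cfg$sigma, ar1 = cfg$ar1,
                       drift_slope = cfg$drift_slope,
                       seed = derive_seed(seed, 4))
  hrf <- double_gamma_hrf(tr = cfg$tr)

  runs <- lapply(seq_len(cfg$n_runs), function(r) {
    run <- simulate_run(design, r, region, pattern, noise, hrf)
    if (cfg$detrend) run <- detrend_linear(run)
    highpass(run, cutoff_hz = cfg$highpass_hz)
  })

  ## --- mapping contrasts on the concatenated condition GLM -------------
  events <- design$trials
  events$subject <- subject_id
  modelled <- setdiff(cfg$conditions, cfg$baseline_condition)
  dm_cond <- fixed_effects_design(events,
                                  n_volumes = design$n_volumes[1],
                                  tr = cfg$tr, conditions = modelled,
                                  hrf = hrf,
                                  baseline_condition = cfg$baseline_condition)
  concat <- do.call(cbind, lapply(runs, function(r) r$data))
  fit_cond <- fit_ols(dm_cond, concat)
  w_em <- ifelse(dm_cond$columns$label == "eye_map", 1,
                 ifelse(dm_cond$columns$label == "mouth_map", -1, 0))
  tmap_em <- t_contrast(fit_cond, dm_cond, w_em, "eye-mouth")
  w_face <- ifelse(dm_cond$columns$label %in% cfg$face_conditions,
                   1 / length(cfg$face_conditions), 0)
  tmap_face <- t_contrast(fit_cond, dm_cond, w_face, "faces-baseline")

  v1_mask <- region_voxels(region, c("eye", "mouth", "rest_v1"))
  responsive <- responsive_map(tmap_face, alpha = cfg$responsive_alpha)
  feats <- define_feature_pois(tmap_em, threshold = cfg$strict_threshold)
  rest <- rest_of_v1(v1_mask, tmap_em,
                     strict_threshold = cfg$strict_threshold,
                     lowered_threshold = cfg$lowered_threshold,
                     responsive = responsive)
  pois <- list(eye = feats$eye, mouth = feats$mouth, rest_v1 = rest)

  ## --- single-trial betas ----------------------------------------------
  st <- lapply(seq_len(cfg$n_runs), function(r) {
    ev <- design$trials[design$trials$run == r, , drop = FALSE]
    dm <- build_single_trial_design(ev, design$n_volumes[r], cfg$tr, hrf,
                                    baseline_condition =
                                      cfg$baseline_condition)
    fit <- fit_ols(dm, runs[[r]])
    keep <- dm$columns$kind == "trial"
    idx <- dm$columns$trial[keep]
    list(betas = fit$betas[keep, , drop = FALSE],
         trial_type = ev$trial_type[idx], gender = ev$gender[idx],
         run = rep(r, sum(keep)), task = rep(design$task_per_run[r],
                                             sum(keep)))
  })
  st_betas <- do.call(rbind, lapply(st, `[[`, "betas"))
  st_info <- data.frame(trial_type = unlist(lapply(st, `[[`, "trial_type")),
                        gender = unlist(lapply(st, `[[`, "gender")),
                        run = unlist(lapply(st, `[[`, "run")),
                        task = unlist(lapply(st, `[[`, "task")),
                        stringsAsFactors = FALSE)

  ## --- FIR deconvolution summaries (eye / mouth univariate analysis) ---
  univariate <- list()
  for (tk in cfg$tasks) {
    task_runs <- which(design$task_per_run == tk)
    bin_sum <- 0
    for (r in task_runs) {
      ev <- design$trials[design$trials$run == r, , drop = FALSE]
      dm <- build_fir_design(ev, design$n_volumes[r], cfg$tr,
                             n_bins = cfg$fir_bins, conditions = modelled,
                             baseline_condition = cfg$baseline_condition)
      fitf <- fit_ols(dm, runs[[r]])
      bin_sum <- bin_sum + fitf$betas[dm$columns$kind == "fir", ,
                                      drop = FALSE]
    }
    bin_mean <- bin_sum / length(task_runs)
    fir_cols <- expand.grid(bin = seq_len(cfg$fir_bins) - 1L,
                            condition = modelled,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
    bin_times <- (seq_len(cfg$fir_bins) - 1) * cfg$tr
    for (rg in c("eye", "mouth")) {
      vox <- pois[[rg]]$voxels
      if (!length(vox)) next
      series <- vapply(cfg$face_conditions, function(cn) {
        rows <- which(fir_cols$condition == cn)
        rowMeans(bin_mean[rows, vox, drop = FALSE])
      }, numeric(cfg$fir_bins))
      pw <- peak_and_window(series, bin_times)
      univariate[[length(univariate) + 1L]] <-
        data.frame(subject = subject_id, task = tk, region = rg,
                   condition = cfg$face_conditions, peak = pw$peak,
                   window_mean = pw$window_mean,
                   peak_time = pw$peak_time, stringsAsFactors = FALSE)
    }
  }
  univariate <- if (length(univariate)) do.call(rbind, univariate) else NULL

  ## --- decoding ---------------------------------------------------------
  face_rows <- st_info$trial_type %in% cfg$face_conditions
  decoding <- list()
  cell <- 0L
  for (tk in cfg$tasks) {
    for (cls in cfg$classifications) {
      keep <- face_rows & st_info$task == tk
      labels <- switch(cls,
                       happy_fear = ifelse(st_info$trial_type %in%
                                             c("happy", "fear"),
                                           st_info$trial_type, NA),
                       male_female = ifelse(face_rows, st_info$gender, NA),
                       expression3 = ifelse(face_rows, st_info$trial_type,
                                            NA),
                       stop("unknown classification: ", cls))
      keep <- keep & !is.na(labels)
      for (rg in names(pois)) {
        cell <- cell + 1L
        vox <- pois[[rg]]$voxels
        for (mode in cfg$test_modes) {
          acc <- NA_real_
          if (length(vox) >= 1 && sum(keep) > 0) {
            pats <- trial_patterns(st_betas[keep, vox, drop = FALSE],
                                   labels[keep], st_info$run[keep],
                                   task = tk)
            sizes <- if (cfg$subsample)
              subsample_schedule(length(vox), cfg$n_sizes, cfg$max_size)
            else NULL
            res <- loro_cv(pats, test_mode = mode, cost = cfg$svm_cost,
                           set_sizes = sizes, n_draws = cfg$n_draws,
                           seed = derive_seed(seed, 100, cell))
            acc <- res$accuracy
          } else {
            warning("empty POI or cell for region ", rg)
          }
          decoding[[length(decoding) + 1L]] <-
            data.frame(subject = subject_id, region = rg, task = tk,
                       classification = cls, test_mode = mode,
                       accuracy = acc,
                       chance = .chance_level(cls),
                       n_features = length(vox),
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  decoding <- do.call(rbind, decoding)

  ## --- gaze screening ---------------------------------------------------
  traces <- lapply(seq_len(cfg$n_runs), function(r)
    simulate_gaze(duration = design$n_volumes[r] * cfg$tr,
                  rate = cfg$gaze_rate,
                  fixation_noise_sd = cfg$gaze_noise_sd,
                  seed = derive_seed(seed, 200, r)))
  n_saccades <- sum(vapply(traces, function(tr)
    nrow(detect_saccades(tr)), numeric(1)))
  by_task <- split(traces, design$task_per_run)
  fixation <- if (length(by_task) == 2 &&
                  all(lengths(by_task) >= 2)) {
    compare_fixation(by_task[[1]], by_task[[2]])
  } else NULL

  phase <- if (cfg$run_wedge) {
    wedge <- simulate_wedge_run(region,
                                noise = noise_model(cfg$sigma,
                                                    seed =
                                                      derive_seed(seed, 5)),
                                hrf = double_gamma_hrf(tr = 1))
    phase_map(wedge, build_phase_reference(hrf = double_gamma_hrf(tr = 1)))
  } else NULL

  list(subject = subject_id, design_seed = derive_seed(seed, 1),
       pois = pois, poi_sizes = vapply(pois, function(p)
         length(p$voxels), numeric(1)),
       decoding = decoding, univariate = univariate,
       n_saccades = n_saccades, fixation = fixation, phase = phase)
}

#' Run the full simulated experiment and group-level analysis
#'
#' Simulates a cohort of independent subjects (distinct derived seeds,
#' shared configuration), runs the complete single-subject chain on each
#' (see [run_subject()]), and aggregates: mean decoding accuracy with
#' one-tailed group t-tests against chance for every region x task x
#' classification x test-mode cell; a repeated-measures ANOVA of the
#' averaged-pattern accuracies (task x region x classification) when both
#' two-class problems are present; a repeated-measures ANOVA of the
#' univariate peak responses (condition x task x region); and pooled gaze
#' screening counts.  Identical master seeds reproduce the report
#' bit-exactly.
#'
#' @param config An `fd_config` from [pipeline_config()].
#' @param seed Master integer seed; all module seeds derive from it.
#' @return An object of class `fd_report`.
#' @export
run_experiment <- function(config = pipeline_config(), seed = 1) {
  cfg <- config
  subjects <- lapply(seq_len(cfg$n_subjects), function(s)
    run_subject(cfg, derive_seed(seed, 17, s), subject_id = s))

  decoding <- do.call(rbind, lapply(subjects, `[[`, "decoding"))
  cells <- unique(decoding[, c("region", "task", "classification",
                               "test_mode")])
  group <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- merge(decoding, cells[i, ])
    acc <- sel$accuracy[is.finite(sel$accuracy)]
    chance <- sel$chance[1]
    out <- cells[i, ]
    out$n <- length(acc)
    out$mean_accuracy <- if (length(acc)) mean(acc) else NA_real_
    out$chance <- chance
    if (length(acc) >= 2) {
      gt <- group_performance_test(acc, chance)
      out$t <- gt$t; out$p <- gt$p; out$dof <- gt$dof
    } else {
      out$t <- NA_real_; out$p <- NA_real_; out$dof <- NA_integer_
    }
    out
  }))
  rownames(group) <- NULL

  mvpa_anova <- NULL
  two_class <- intersect(cfg$classifications,
                         c("happy_fear", "male_female"))
  if (length(two_class) == 2 && cfg$n_subjects >= 2 &&
      "averaged" %in% cfg$test_modes) {
    d <- decoding[decoding$classification %in% two_class &
                    decoding$test_mode == "averaged" &
                    is.finite(decoding$accuracy), ]
    mvpa_anova <- tryCatch(
      rm_anova(d, dv = "accuracy", subject = "subject",
               factors = c("task", "region", "classification")),
      error = function(e) NULL)
  }

  univariate <- do.call(rbind, lapply(subjects, `[[`, "univariate"))
  univariate_anova <- NULL
  if (!is.null(univariate) &&
      all(c("happy", "fear") %in% cfg$face_conditions) &&
      cfg$n_subjects >= 2) {
    u <- univariate[univariate$condition %in% c("happy", "fear"), ]
    univariate_anova <- tryCatch(
      rm_anova(u, dv = "peak", subject = "subject",
               factors = c("condition", "task", "region")),
      error = function(e) NULL)
  }

  gaze <- data.frame(
    subject = vapply(subjects, `[[`, numeric(1), "subject"),
    n_saccades = vapply(subjects, `[[`, numeric(1), "n_saccades"),
    fixation_p_horizontal = vapply(subjects, function(s)
      if (is.null(s$fixation)) NA_real_ else s$fixation$horizontal$p,
      numeric(1)),
    fixation_p_vertical = vapply(subjects, function(s)
      if (is.null(s$fixation)) NA_real_ else s$fixation$vertical$p,
      numeric(1)))

  structure(list(seed = seed, config = cfg, subjects = subjects,
                 decoding = decoding, group = group,
                 mvpa_anova = mvpa_anova,
                 univariate = univariate,
                 univariate_anova = univariate_anova, gaze = gaze),
            class = "fd_report")
}

#' @export
print.fd_report <- function(x, ...) {
  cat("Simulated experiment:", x$config$n_subjects, "subjects, seed",
      x$seed, "\n\nGroup decoding (mean % vs chance):\n")
  print(x$group, digits = 4)
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits the group decoding table, per-subject decoding detail, ANOVA
#' tables, univariate summaries, gaze screening table and a JSON manifest
#' (master seed, subject count, POI sizes).  All outputs are plain
#' TSV/JSON and a rerun with the same master seed reproduces them
#' bit-identically.
#'
#' @param report An `fd_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$group, "decoding_group.tsv")
  wt(report$decoding, "decoding_subjects.tsv")
  if (!is.null(report$mvpa_anova))
    wt(as.data.frame(report$mvpa_anova), "mvpa_anova.tsv")
  if (!is.null(report$univariate)) wt(report$univariate, "univariate.tsv")
  if (!is.null(report$univariate_anova))
    wt(as.data.frame(report$univariate_anova), "univariate_anova.tsv")
  wt(report$gaze, "gaze.tsv")
  manifest <- list(
    seed = report$seed, n_subjects = report$config$n_subjects,
    poi_sizes = lapply(report$subjects, `[[`, "poi_sizes"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
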