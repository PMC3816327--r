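#' Construct a rapid event-related experiment design
#'
#' Builds the trial table for a multi-run event-related design: within each
#' run every condition is presented an equal number of times in random order,
#' trials follow each other at a fixed stimulus-onset asynchrony (stimulus
#' duration plus fixation gap), and the behavioural task alternates across
#' runs (expression vs. gender categorization).  The default configuration is
#' six runs of 120 trials each (720 trials, 120 per condition, six
#' conditions) with 1 s stimuli followed by 3 s fixation at TR = 1 s.
#'
#' Face trials additionally carry a balanced male/female stimulus attribute
#' (`gender`), assigned within run and condition, so that gender
#' classification labels exist alongside the expression conditions.
#'
#' @param n_runs Number of functional runs.
#' @param trials_per_condition Total trials per condition across all runs;
#'   must be divisible by `n_runs`.
#' @param conditions Character vector of condition labels.
#' @param face_conditions Subset of `conditions` that are face stimuli
#'   (receive gender attributes and enter decoding).
#' @param baseline_condition Label of the fixation baseline condition (no
#'   evoked response is modelled for it).
#' @param tr Repetition time in seconds.
#' @param stim_duration Stimulus duration in seconds.
#' @param fixation_gap Post-stimulus fixation period in seconds.
#' @param tasks Task labels cycled across runs.
#' @param lead_in_volumes,lead_out_volumes Silent volumes prepended/appended
#'   to each run.
#' @param seed Integer seed; designs are reproducible bit-for-bit.
#' @return An object of class `fd_design`: a list with the trial table
#'   (`$trials`: onset, duration, trial_type, gender, run, task), per-run
#'   volume counts, condition labels and timing parameters.
#' @examples
#' d <- make_design(seed = 1)
#' nrow(d$trials)            # 720
#' table(d$trials$trial_type)
#' @export
make_design <- function(n_runs = 6, trials_per_condition = 120,
                        conditions = c("happy", "fear", "neutral",
                                       "eye_map", "mouth_map", "baseline"),
                        face_conditions = c("happy", "fear", "neutral"),
                        baseline_condition = "baseline",
                        tr = 1, stim_duration = 1, fixation_gap = 3,
                        tasks = c("expression", "gender"),
                        lead_in_volumes = 10, lead_out_volumes = 10,
                        seed = 1) {
  stopifnot(n_runs >= 1, trials_per_condition >= 0, tr > 0,
            stim_duration > 0, fixation_gap >= 0,
            lead_in_volumes >= 0, lead_out_volumes >= 0)
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions) || any(!nzchar(conditions)))
    stop("condition labels must be unique, non-empty strings")
  unknown <- setdiff(face_conditions, conditions)
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  if (trials_per_condition %% n_runs != 0)
    stop("'trials_per_condition' must be divisible by 'n_runs'")
  per_run <- trials_per_condition %/% n_runs
  soa <- stim_duration + fixation_gap
  task_per_run <- rep(tasks, length.out = n_runs)

  trials <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_runs), function(r) {
      labs <- rep(conditions, each = per_run)
      if (length(labs) > 1) labs <- sample(labs)
      n <- length(labs)
      gender <- rep(NA_character_, n)
      for (fc in face_conditions) {
        idx <- which(labs == fc)
        if (length(idx)) {
          g <- rep(c("male", "female"), length.out = length(idx))
          gender[idx] <- sample(g)
        }
      }
      data.frame(onset = lead_in_volumes * tr + (seq_len(n) - 1) * soa,
                 duration = rep(stim_duration, n),
                 trial_type = labs,
                 gender = gender,
                 run = rep(r, n),
                 task = rep(task_per_run[r], n),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(trials) <- NULL
  n_trial_run <- per_run * length(conditions)
  n_volumes <- lead_in_volumes + ceiling(n_trial_run * soa / tr) +
    lead_out_volumes

  structure(list(n_runs = n_runs, tr = tr, conditions = conditions,
                 face_conditions = face_conditions,
                 baseline_condition = baseline_condition,
                 trials = trials, task_per_run = task_per_run,
                 n_volumes = rep(n_volumes, n_runs), soa = soa,
                 stim_duration = stim_duration, seed = seed),
            class = "fd_design")
}

#' @export
print.fd_design <- function(x, ...) {
  cat("Event-related design:", x$n_runs, "runs,", nrow(x$trials),
      "trials (", nrow(x$trials) / max(1, length(x$conditions)),
      "per condition ),", "SOA", x$soa, "s, TR", x$tr, "s\n")
  cat("tasks:", paste(x$task_per_run, collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth voxel region labels
#'
#' Creates the synthetic stand-in for the manually delineated cortical
#' regions: each voxel is labelled `eye`, `mouth`, `rest_v1` or `outside`,
#' and carries a preferred polar angle (degrees in [0, 360)) used by the
#' rotating-wedge forward model.  Labels partition the voxel set.
#'
#' @param n_eye,n_mouth,n_rest,n_outside Voxel counts per region.
#' @param angle_ranges Named list of `[lo, hi)` polar-angle ranges per label,
#'   in degrees; the eye region sits in the ventral (lower-field) half and
#'   the mouth region in the dorsal half by default.
#' @param seed Integer seed for the preferred-angle draws.
#' @return An object of class `fd_region`: `n_voxels`, `label` (character
#'   vector), `preferred_angle` (degrees).
#' @export
region_truth <- function(n_eye = 60, n_mouth = 60, n_rest = 160,
                         n_outside = 40,
                         angle_ranges = list(eye = c(180, 360),
                                             mouth = c(0, 180),
                                             rest_v1 = c(0, 360),
                                             outside = c(0, 360)),
                         seed = 1) {
  counts <- c(eye = n_eye, mouth = n_mouth, rest_v1 = n_rest,
              outside = n_outside)
  stopifnot(all(counts >= 0))
  label <- rep(names(counts), times = counts)
  angle <- with_seed(seed, {
    unlist(lapply(names(counts), function(lb) {
      rg <- angle_ranges[[lb]] %||% c(0, 360)
      stats::runif(counts[[lb]], rg[1], rg[2]) %% 360
    }), use.names = FALSE)
  })
  structure(list(n_voxels = sum(counts), label = label,
                 preferred_angle = angle, counts = counts, seed = seed),
            class = "fd_region")
}

#' Voxel indices of a labelled region
#' @param region An `fd_region`.
#' @param label Region label(s) to select.
#' @return Integer voxel indices.
#' @export
region_voxels <- function(region, label) which(region$label %in% label)

#' Ground-truth response amplitudes per (condition, task, voxel)
#'
#' Builds the amplitude map that drives the forward model.  By default:
#' the baseline condition evokes nothing; face conditions evoke
#' `base_amplitude` in every V1 voxel (the face covers the mapped visual
#' field) and nothing outside V1; each feature-mapping checkerboard evokes
#' `mapping_amplitude` only in its own region (eye checkerboards in the eye
#' region, mouth checkerboard in the mouth region), which is what makes the
#' eye-vs-mouth localizer contrast work downstream.
#'
#' Class-discriminative signal is opt-in through `signal`: each row plants a
#' condition-specific multivoxel pattern `delta * z_v` (with `z_v` standard
#' normal per voxel, fixed by `seed`) in the voxels of one region, for one
#' task or all tasks.  A map built with no `signal` rows is a null truth:
#' identical amplitudes across the to-be-decoded class labels.
#'
#' @param region An `fd_region`.
#' @param conditions,tasks Condition and task label sets (usually from the
#'   design).
#' @param base_amplitude Face-evoked response amplitude (arbitrary BOLD
#'   units).
#' @param mapping_amplitude Checkerboard-evoked amplitude in the mapped
#'   region.
#' @param mapping Named character vector: mapping condition -> region label.
#' @param face_conditions,baseline_condition As in [make_design()].
#' @param signal `NULL` (null truth) or a data frame with columns
#'   `condition`, `task` (a task label or `"*"`), `region`, `delta`.
#' @param seed Integer seed for the planted patterns.
#' @return An object of class `fd_pattern` with `$amplitudes`, a 3-d array
#'   `condition x task x voxel`, and the signal specification.
#' @export
make_pattern_truth <- function(region,
                               conditions = c("happy", "fear", "neutral",
                                              "eye_map", "mouth_map",
                                              "baseline"),
                               tasks = c("expression", "gender"),
                               base_amplitude = 1,
                               mapping_amplitude = 1,
                               mapping = c(eye_map = "eye",
                                           mouth_map = "mouth"),
                               face_conditions = c("happy", "fear",
                                                   "neutral"),
                               baseline_condition = "baseline",
                               signal = NULL, seed = 1) {
  nv <- region$n_voxels
  amp <- array(0, dim = c(length(conditions), length(tasks), nv),
               dimnames = list(conditions, tasks, NULL))
  v1 <- region$label != "outside"
  for (fc in intersect(face_conditions, conditions))
    amp[fc, , v1] <- base_amplitude
  for (mc in intersect(names(mapping), conditions))
    amp[mc, , region$label == mapping[[mc]]] <- mapping_amplitude
  if (baseline_condition %in% conditions) amp[baseline_condition, , ] <- 0

  if (!is.null(signal) && nrow(signal)) {
    stopifnot(all(c("condition", "task", "region", "delta") %in%
                    names(signal)))
    for (i in seq_len(nrow(signal))) {
      row <- signal[i, ]
      if (!row$condition %in% conditions)
        stop("unknown condition label: ", row$condition)
      vox <- region_voxels(region, row$region)
      if (!length(vox)) next
      z <- with_seed(derive_seed(seed, i), stats::rnorm(length(vox)))
      tk <- if (identical(row$task, "*")) tasks else row$task
      for (t in tk) amp[row$condition, t, vox] <-
          amp[row$condition, t, vox] + row$delta * z
    }
  }
  stopifnot(all(is.finite(amp)))
  structure(list(amplitudes = amp, conditions = conditions, tasks = tasks,
                 signal = signal, seed = seed),
            class = "fd_pattern")
}

#' Contrast-to-noise ratio of a pattern truth
#'
#' Ratio of the across-voxel spread of class-specific amplitudes (standard
#' deviation of the pairwise condition differences) to the noise standard
#' deviation.
#'
#' @param pattern An `fd_pattern`.
#' @param noise An `fd_noise` model (its `sigma` is used).
#' @param conditions Pair of condition labels to compare.
#' @param task Task label.
#' @return CNR (dimensionless).
#' @export
pattern_cnr <- function(pattern, noise, conditions, task) {
  d <- pattern$amplitudes[conditions[1], task, ] -
    pattern$amplitudes[conditions[2], task, ]
  if (noise$sigma == 0) return(Inf)
  stats::sd(d) / noise$sigma
}

#' Noise model for synthetic BOLD runs
#'
#' White Gaussian noise of standard deviation `sigma`, optionally with AR(1)
#' temporal autocorrelation (stationary marginal SD kept at `sigma`), plus a
#' per-volume linear drift added to every voxel.
#'
#' @param sigma Noise standard deviation in BOLD units (>= 0).
#' @param ar1 AR(1) coefficient in [0, 1); 0 = white noise.
#' @param drift_slope Drift in BOLD units per volume.
#' @param seed Integer seed; realizations are reproducible.
#' @return An object of class `fd_noise`.
#' @export
noise_model <- function(sigma = 1, ar1 = 0, drift_slope = 0, seed = 1) {
  stopifnot(sigma >= 0, ar1 >= 0, ar1 < 1)
  structure(list(sigma = sigma, ar1 = ar1, drift_slope = drift_slope,
                 seed = seed), class = "fd_noise")
}

# Draw an n_volumes x n_voxels noise matrix for a given run tag.
.draw_noise <- function(noise, n_volumes, n_voxels, tag) {
  if (noise$sigma == 0)
    return(matrix(0, n_volumes, n_voxels))
  with_seed(derive_seed(noise$seed, tag), {
    e <- matrix(stats::rnorm(n_volumes * n_voxels), n_volumes, n_voxels)
    if (noise$ar1 > 0) {
      e <- apply(e, 2, function(x)
        as.numeric(stats::filter(x * sqrt(1 - noise$ar1^2), noise$ar1,
                                 method = "recursive")))
    }
    e * noise$sigma
  })
}

#' Construct a BOLD run container
#'
#' @param data Numeric matrix, voxels x volumes.
#' @param tr Repetition time in seconds.
#' @param run_id Run label.
#' @return An object of class `fd_bold`.
#' @export
bold_run <- function(data, tr = 1, run_id = 1L) {
  data <- as.matrix(data)
  stopifnot(all(is.finite(data)), tr > 0)
  structure(list(data = data, tr = tr, run_id = run_id), class = "fd_bold")
}

#' @export
print.fd_bold <- function(x, ...) {
  cat("BOLD run", x$run_id, ":", nrow(x$data), "voxels x", ncol(x$data),
      "volumes, TR", x$tr, "s\n")
  invisible(x)
}

# HRF-convolved boxcar regressors, one column per event row.
.trial_regressors <- function(events, n_volumes, tr, hrf) {
  X <- matrix(0, n_volumes, nrow(events))
  if (!nrow(events)) return(X)
  onset_vol <- round(events$onset / tr)
  dur_vol <- pmax(1L, round(events$duration / tr))
  if (any(onset_vol < 0) || any(onset_vol >= n_volumes))
    stop("event onset outside the run's volume range")
  h <- hrf$weights
  for (j in seq_len(nrow(events))) {
    box <- numeric(n_volumes)
    idx <- onset_vol[j] + seq_len(dur_vol[j])
    idx <- idx[idx <= n_volumes]
    box[idx] <- 1
    X[, j] <- convolve_causal(box, h)
  }
  X
}

#' Simulate one event-related BOLD run from the forward model
#'
#' The signal of voxel v is the sum over trials of the HRF-convolved
#' stimulus boxcar scaled by the ground-truth amplitude of that trial's
#' (condition, task) cell for v, plus linear drift and noise.  The output is
#' therefore exactly linear in the amplitude map at zero noise, which is
#' what makes GLM recovery testable to machine precision.
#'
#' @param design An `fd_design`.
#' @param run Run index to simulate.
#' @param region An `fd_region` (defines the voxel population).
#' @param pattern An `fd_pattern`; its amplitude map must cover every
#'   condition occurring in the run.
#' @param noise An `fd_noise`.
#' @param hrf An `fd_hrf` kernel sampled at the design TR (see
#'   [double_gamma_hrf()]).
#' @param trial_amplitudes Optional trials x voxels matrix overriding the
#'   per-trial amplitudes (rows follow the run's trial order).
#' @return An `fd_bold` run (voxels x volumes).
#' @export
simulate_run <- function(design, run, region, pattern, noise, hrf,
                         trial_amplitudes = NULL) {
  stopifnot(inherits(design, "fd_design"), inherits(region, "fd_region"))
  if (abs(hrf$tr - design$tr) > 1e-9)
    stop("HRF kernel must be sampled at the design TR")
  events <- design$trials[design$trials$run == run, , drop = FALSE]
  n_vol <- design$n_volumes[run]
  nv <- region$n_voxels
  X <- .trial_regressors(events, n_vol, design$tr, hrf)

  if (is.null(trial_amplitudes)) {
    if (dim(pattern$amplitudes)[3] != nv)
      stop("pattern truth voxel count does not match the region truth")
    miss <- setdiff(unique(events$trial_type), pattern$conditions)
    if (length(miss))
      stop("amplitude map does not cover condition(s): ",
           paste(miss, collapse = ", "))
    task <- design$task_per_run[run]
    A <- matrix(0, nrow(events), nv)
    for (j in seq_len(nrow(events)))
      A[j, ] <- pattern$amplitudes[events$trial_type[j], task, ]
  } else {
    A <- as.matrix(trial_amplitudes)
    if (nrow(A) != nrow(events) || ncol(A) != nv)
      stop("'trial_amplitudes' must be trials x voxels for this run")
  }

  signal <- if (nrow(events)) X %*% A else matrix(0, n_vol, nv)
  drift <- noise$drift_slope * (seq_len(n_vol) - 1)
  Y <- signal + drift + .draw_noise(noise, n_vol, nv, run)
  bold_run(t(Y), tr = design$tr, run_id = run)
}

#' Simulate a phase-encoded rotating-wedge mapping run
#'
#' Each responsive voxel emits the steady-state periodic response of a wedge
#' stimulus passing through its preferred polar angle: the HRF-convolved
#' reference response (wedge in the first 45 degree sector) circularly
#' delayed by `preferred_angle / 360 * cycle_volumes` volumes.  Voxels
#' outside the responsive labels stay flat (amplitude 0).
#'
#' @param region An `fd_region` supplying preferred angles.
#' @param cycle_volumes Volumes per stimulation cycle; must be divisible
#'   by 8 (45-degree sectors).  Default 32.
#' @param n_cycles Number of cycles in the run.
#' @param noise An `fd_noise`.
#' @param hrf An `fd_hrf` kernel.
#' @param amplitude Response amplitude of responsive voxels.
#' @param respond_labels Region labels that respond to the wedge.
#' @return An `fd_bold` run of length `cycle_volumes * n_cycles`.
#' @export
simulate_wedge_run <- function(region, cycle_volumes = 32, n_cycles = 8,
                               noise = noise_model(), hrf = NULL,
                               amplitude = 1,
                               respond_labels = c("eye", "mouth",
                                                  "rest_v1")) {
  if (cycle_volumes %% 8 != 0)
    stop("'cycle_volumes' must be divisible by 8 (45-degree sectors)")
  if (is.null(hrf)) hrf <- double_gamma_hrf(tr = 1)
  ref <- build_phase_reference(cycle_volumes, cycle_volumes %/% 8,
                               n_cycles, hrf)
  nv <- region$n_voxels
  n_vol <- cycle_volumes * n_cycles
  Y <- matrix(0, n_vol, nv)
  responds <- region$label %in% respond_labels
  shift <- round(region$preferred_angle / 360 * cycle_volumes) %%
    cycle_volumes
  for (v in which(responds)) Y[, v] <- amplitude * circshift(ref, shift[v])
  drift <- noise$drift_slope * (seq_len(n_vol) - 1)
  Y <- Y + drift + .draw_noise(noise, n_vol, nv, 0L)
  bold_run(t(Y), tr = hrf$tr, run_id = "wedge")
}

#' Checkerboard feature-mapping stimulus geometry
#'
#' Rectangle extents (degrees of visual angle) of the mouth and eye mapping
#' checkerboards.  In the default configuration the mouth checkerboard spans
#' 2.8 x 7.2 degrees and each of the two eye checkerboards 2.8 x 3.6
#' degrees, so the total mouth area equals the summed eye area; the vertical
#' separation between the eye boxes and the mouth box is 4.9 degrees.  All
#' extents scale linearly with `scale` (areas with `scale^2`), preserving
#' the area equality.
#'
#' @param scale Linear scale factor applied to all extents.
#' @return A list with `mouth`, `eye` (width/height/count) extents,
#'   `vertical_separation`, and the derived areas.
#' @export
checkerboard_geometry <- function(scale = 1) {
  stopifnot(scale > 0)
  mouth <- list(width = 2.8 * scale, height = 7.2 * scale)
  eye <- list(width = 2.8 * scale, height = 3.6 * scale, count = 2L)
  list(mouth = mouth, eye = eye,
       vertical_separation = 4.9 * scale,
       mouth_area = mouth$width * mouth$height,
       eye_area_total = eye$count * eye$width * eye$height)
}

#' Simulate a gaze trace with injected saccades
#'
#' Fixation is modelled as isotropic Gaussian jitter around the origin;
#' saccades are injected as square-pulse excursions of given amplitude,
#' direction and duration.  This is the fixture generator for the saccade
#' classifier: an excursion above the radius threshold lasting at least the
#' minimum duration should be detected as exactly one saccade.
#'
#' @param duration Trace duration in seconds.
#' @param rate Sampling rate in Hz (> 0).
#' @param fixation_noise_sd SD of fixation jitter, degrees.
#' @param saccades `NULL` or a data frame with columns `onset` (s),
#'   `amplitude` (degrees), `duration_ms`, and optionally `direction_deg`
#'   (default 0 = rightward).
#' @param seed Integer seed.
#' @return An object of class `fd_gaze`: `samples` (n x 2 matrix of x, y in
#'   degrees) and `rate`.
#' @export
simulate_gaze <- function(duration = 10, rate = 60, fixation_noise_sd = 0.05,
                          saccades = NULL, seed = 1) {
  if (rate <= 0) stop("'rate' must be positive")
  n <- round(duration * rate)
  xy <- with_seed(seed, matrix(stats::rnorm(2 * n, 0, fixation_noise_sd),
                               n, 2))
  if (!is.null(saccades) && nrow(saccades)) {
    stopifnot(all(c("onset", "amplitude", "duration_ms") %in%
                    names(saccades)))
    for (i in seq_len(nrow(saccades))) {
      s <- saccades[i, ]
      dir <- (s$direction_deg %||% 0) * pi / 180
      i0 <- floor(s$onset * rate) + 1
      len <- round(s$duration_ms / 1000 * rate)
      idx <- i0:(i0 + len - 1)
      idx <- idx[idx >= 1 & idx <= n]
      xy[idx, 1] <- xy[idx, 1] + s$amplitude * cos(dir)
      xy[idx, 2] <- xy[idx, 2] + s$amplitude * sin(dir)
    }
  }
  colnames(xy) <- c("x", "y")
  structure(list(samples = xy, rate = rate), class = "fd_gaze")
}
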