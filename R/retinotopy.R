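#' Predicted response for the first wedge sector of a stimulation cycle
#'
#' Reference time course for phase-encoded polar-angle mapping: a boxcar
#' active during the first `active_volumes` of each `cycle_volumes`-volume
#' cycle (duty cycle 1/8 with the defaults: 32-volume cycles, 4 active
#' volumes), convolved with the HRF in its periodic steady state, tiled over
#' `n_cycles` cycles.  The steady-state (circular) convolution makes the
#' reference exactly periodic, so circular time shifts of the reference
#' correspond to polar-angle rotations of the wedge.
#'
#' @param cycle_volumes Volumes per cycle.
#' @param active_volumes Active volumes at the start of each cycle; must
#'   divide `cycle_volumes`.
#' @param n_cycles Number of cycles.
#' @param hrf An `fd_hrf` kernel (a delta kernel reproduces the raw
#'   boxcar).
#' @return Numeric vector of length `cycle_volumes * n_cycles`.
#' @export
build_phase_reference <- function(cycle_volumes = 32, active_volumes = 4,
                                  n_cycles = 8, hrf = double_gamma_hrf()) {
  stopifnot(n_cycles >= 1, active_volumes >= 1)
  if (cycle_volumes %% active_volumes != 0)
    stop("'cycle_volumes' must be divisible by 'active_volumes'")
  box <- c(rep(1, active_volumes), rep(0, cycle_volumes - active_volumes))
  warm <- ceiling(length(hrf$weights) / cycle_volumes)
  tiled <- rep(box, n_cycles + warm)
  y <- convolve_causal(tiled, hrf$weights)
  y[(warm * cycle_volumes + 1):((warm + n_cycles) * cycle_volumes)]
}

#' Polar-angle phase map by shifted cross-correlation
#'
#' For every voxel, computes the Pearson correlation of its time course
#' against the reference circularly delayed by k * `shift_step` volumes for
#' k = 0 .. n_shifts - 1 (with the defaults, 8 shifts of 4 volumes = 45
#' degrees each), and records the best-correlating shift and the implied
#' polar angle `k * shift_step * 360 / cycle_volumes`.  Zero-variance
#' voxels get r = 0 and are flagged.
#'
#' @param run An `fd_bold` run whose length equals the reference length.
#' @param reference Reference time course from [build_phase_reference()].
#' @param cycle_volumes Volumes per stimulation cycle.
#' @param shift_step Shift increment in volumes; must divide
#'   `cycle_volumes`.
#' @param r_threshold Correlation regarded as mapping-significant (stored
#'   with the result; voxels below it are marked sub-threshold).
#' @return An object of class `fd_phasemap`: a data frame (voxel,
#'   best_shift, r, angle, flagged, significant) plus `n_shifts` and the
#'   full voxel x shift correlation matrix as attributes.
#' @export
phase_map <- function(run, reference, cycle_volumes = 32, shift_step = 4,
                      r_threshold = 0.25) {
  data <- if (inherits(run, "fd_bold")) run$data else as.matrix(run)
  if (ncol(data) != length(reference))
    stop("run length does not match the reference length")
  if (cycle_volumes %% shift_step != 0)
    stop("'cycle_volumes' must be divisible by 'shift_step'")
  n_shifts <- cycle_volumes %/% shift_step
  refs <- vapply(seq_len(n_shifts) - 1L,
                 function(k) circshift(reference, k * shift_step),
                 numeric(length(reference)))
  r <- safe_cor(t(data), refs)
  flagged <- attr(r, "flagged")
  best <- max.col(r, ties.method = "first") - 1L
  best_r <- r[cbind(seq_len(nrow(r)), best + 1L)]
  tab <- data.frame(voxel = seq_len(nrow(data)), best_shift = best,
                    r = best_r,
                    angle = best * shift_step * 360 / cycle_volumes,
                    flagged = flagged,
                    significant = !flagged & best_r >= r_threshold)
  structure(tab, class = c("fd_phasemap", "data.frame"),
            n_shifts = n_shifts, r_threshold = r_threshold,
            correlations = r)
}
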