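#' Double-gamma haemodynamic response function
#'
#' The canonical two-gamma HRF: the difference of a peak gamma density and a
#' scaled undershoot gamma density, sampled at the TR and peak-normalized to
#' 1.  With the defaults (peak delay 6 s, undershoot delay 16 s, unit
#' dispersions, peak:undershoot ratio 6, 32 s support) the kernel is 0 at
#' t = 0, peaks near 5 s, and has a negative undershoot beyond ~10 s.
#'
#' @param tr Sampling interval in seconds (> 0).
#' @param peak_delay,undershoot_delay Gamma delays in seconds.
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions in
#'   seconds.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param length_s Kernel support in seconds.
#' @return An object of class `fd_hrf`: `weights` (unitless, at TR
#'   spacing), `tr`, `times`, and the parameter list.
#' @examples
#' h <- double_gamma_hrf(tr = 0.1)
#' h$times[which.max(h$weights)]   # ~5 s
#' @export
double_gamma_hrf <- function(tr = 1, peak_delay = 6, undershoot_delay = 16,
                             peak_dispersion = 1, undershoot_dispersion = 1,
                             ratio = 6, length_s = 32) {
  if (tr <= 0) stop("'tr' must be positive")
  if (any(c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, ratio, length_s) <= 0))
    stop("HRF shape parameters must be positive")
  t <- seq(0, length_s, by = tr)
  h <- stats::dgamma(t, shape = peak_delay / peak_dispersion,
                     rate = 1 / peak_dispersion) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_dispersion,
                  rate = 1 / undershoot_dispersion) / ratio
  h <- h / max(h)
  structure(list(weights = h, tr = tr, times = t,
                 params = list(peak_delay = peak_delay,
                               undershoot_delay = undershoot_delay,
                               peak_dispersion = peak_dispersion,
                               undershoot_dispersion = undershoot_dispersion,
                               ratio = ratio, length_s = length_s)),
            class = "fd_hrf")
}

#' Construct an HRF kernel from explicit weights
#'
#' Mostly useful for tests and for the identity (delta) kernel, under which
#' convolution is a no-op.
#'
#' @param weights Numeric kernel weights at TR spacing.
#' @param tr Sampling interval in seconds.
#' @return An `fd_hrf`.
#' @export
hrf_kernel <- function(weights, tr = 1) {
  stopifnot(all(is.finite(weights)), tr > 0)
  structure(list(weights = weights, tr = tr,
                 times = (seq_along(weights) - 1) * tr, params = list()),
            class = "fd_hrf")
}

# internal design-matrix constructor
new_designmat <- function(X, columns) {
  stopifnot(nrow(columns) == ncol(X))
  colnames(X) <- columns$label
  structure(list(X = X, columns = columns), class = "fd_designmat")
}

#' @export
print.fd_designmat <- function(x, ...) {
  cat("Design matrix:", nrow(x$X), "volumes x", ncol(x$X), "predictors (",
      sum(x$columns$kind != "confound"), "stimulus,",
      sum(x$columns$kind == "confound"), "confound )\n")
  invisible(x)
}

#' FIR deconvolution design matrix
#'
#' One stick predictor per condition and post-stimulus time bin: predictor
#' (c, k) carries a 1 at volume v + k for every event of condition c whose
#' onset rounds to volume v (bins running past the run end are truncated).
#' With the default 20 bins of one TR this estimates the response shape over
#' 0-19 s without assuming an HRF; the baseline condition is excluded, so a
#' five-condition design yields 100 stimulus predictors plus the confounds.
#'
#' @param events Event table for one run (columns onset, duration,
#'   trial_type).
#' @param n_volumes Number of retained volumes in the run.
#' @param tr Repetition time in seconds.
#' @param n_bins Number of post-stimulus bins (>= 1), one TR wide.
#' @param conditions Conditions to model, in column order; defaults to the
#'   unique non-baseline trial types in `events`.
#' @param baseline_condition Label excluded from modelling.
#' @param mean_confound Add an all-ones mean confound column.
#' @return An `fd_designmat` with a `columns` table (kind, condition, bin,
#'   label).
#' @export
build_fir_design <- function(events, n_volumes, tr = 1, n_bins = 20,
                             conditions = NULL,
                             baseline_condition = "baseline",
                             mean_confound = TRUE) {
  stopifnot(n_bins >= 1)
  if (is.null(conditions))
    conditions <- setdiff(unique(events$trial_type), baseline_condition)
  ev <- events[events$trial_type %in% conditions, , drop = FALSE]
  onset_vol <- round(ev$onset / tr)
  if (nrow(ev) && (any(onset_vol < 0) || any(onset_vol >= n_volumes)))
    stop("event onset outside the run's volume range")
  cols <- expand.grid(bin = seq_len(n_bins) - 1L, condition = conditions,
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, c("condition", "bin")]
  X <- matrix(0, n_volumes, nrow(cols))
  for (j in seq_len(nrow(cols))) {
    ons <- onset_vol[ev$trial_type == cols$condition[j]]
    rows <- ons + cols$bin[j] + 1L
    rows <- rows[rows <= n_volumes]
    X[rows, j] <- X[rows, j] + 1
  }
  columns <- data.frame(kind = "fir", condition = cols$condition,
                        bin = cols$bin, trial = NA_integer_,
                        label = sprintf("%s:bin%02d", cols$condition,
                                        cols$bin),
                        stringsAsFactors = FALSE)
  if (mean_confound) {
    X <- cbind(X, 1)
    columns <- rbind(columns,
                     data.frame(kind = "confound", condition = NA, bin = NA,
                                trial = NA_integer_, label = "mean",
                                stringsAsFactors = FALSE))
  }
  new_designmat(X, columns)
}

#' Single-trial (beta-series) design matrix
#'
#' One column per trial — the stimulus boxcar at that trial's onset
#' convolved with the HRF — plus one all-ones mean confound, i.e. as many
#' stimulus predictors as trials.  Fitting this design by OLS yields one
#' response-amplitude estimate (beta weight) per trial per voxel, the input
#' patterns for decoding.
#'
#' @param events Event table for one run.
#' @param n_volumes Number of retained volumes.
#' @param tr Repetition time in seconds.
#' @param hrf An `fd_hrf` kernel sampled at `tr`.
#' @param baseline_condition Trials of this condition are not modelled.
#' @return An `fd_designmat`; `columns$trial` maps stimulus columns back to
#'   rows of `events`.
#' @export
build_single_trial_design <- function(events, n_volumes, tr = 1, hrf,
                                      baseline_condition = "baseline") {
  keep <- which(events$trial_type != baseline_condition)
  ev <- events[keep, , drop = FALSE]
  if (anyDuplicated(ev$onset))
    stop("overlapping identical onsets: trials are not separable")
  X <- .trial_regressors(ev, n_volumes, tr, hrf)
  columns <- data.frame(kind = "trial", condition = ev$trial_type,
                        bin = NA_integer_, trial = keep,
                        label = sprintf("trial%03d", keep),
                        stringsAsFactors = FALSE)
  X <- cbind(X, 1)
  columns <- rbind(columns,
                   data.frame(kind = "confound", condition = NA, bin = NA,
                              trial = NA_integer_, label = "mean",
                              stringsAsFactors = FALSE))
  new_designmat(X, columns)
}

#' Ordinary least-squares fit of a design matrix to BOLD data
#'
#' Per-voxel OLS: betas minimize the squared residual; residual variance is
#' RSS / dof with dof = volumes - rank(design).  Rank-deficient designs fall
#' back to the minimum-norm pseudo-inverse solution with a warning.
#'
#' @param design An `fd_designmat` (or plain matrix, volumes x predictors).
#' @param data An `fd_bold` run or a voxels x volumes matrix.
#' @return An object of class `fd_betas`: `betas` (predictors x voxels),
#'   `residual_variance` (per voxel), `dof`, and the design column table.
#' @export
fit_ols <- function(design, data) {
  X <- if (inherits(design, "fd_designmat")) design$X else as.matrix(design)
  columns <- if (inherits(design, "fd_designmat")) design$columns else NULL
  Y <- if (inherits(data, "fd_bold")) t(data$data) else t(as.matrix(data))
  if (nrow(Y) != nrow(X))
    stop("volume count of data does not match the design matrix")
  qrX <- qr(X)
  rank <- qrX$rank
  if (rank < ncol(X)) {
    warning("design matrix is rank deficient; using minimum-norm ",
            "pseudo-inverse")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    betas <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], Y) / sv$d[pos])
  } else {
    betas <- qr.coef(qrX, Y)
  }
  fitted <- X %*% betas
  rss <- colSums((Y - fitted)^2)
  dof <- nrow(X) - rank
  resvar <- if (dof > 0) rss / dof else rep(NA_real_, ncol(Y))
  rownames(betas) <- colnames(X)
  structure(list(betas = betas, residual_variance = resvar, dof = dof,
                 rank = rank, columns = columns),
            class = "fd_betas")
}

#' Per-voxel t statistics for a linear contrast
#'
#' Computes t = (w'beta) / sqrt(sigma^2 * w' (X'X)^-1 w) for each voxel,
#' with the OLS residual variance and degrees of freedom from the fit.
#'
#' @param fit An `fd_betas` from [fit_ols()].
#' @param design The `fd_designmat` (or matrix) used for the fit.
#' @param weights Contrast weight vector, one entry per predictor.
#' @param label Contrast label carried in the result.
#' @return An object of class `fd_tmap`: `t` per voxel, `dof`, `label`.
#' @export
t_contrast <- function(fit, design, weights, label = "") {
  X <- if (inherits(design, "fd_designmat")) design$X else as.matrix(design)
  if (length(weights) != ncol(X))
    stop("'weights' must have one entry per predictor")
  xtx <- crossprod(X)
  xtx_inv <- tryCatch(solve(xtx), error = function(e) {
    warning("singular X'X; using pseudo-inverse")
    sv <- svd(xtx)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  effect <- as.numeric(crossprod(weights, fit$betas))
  wvar <- drop(t(weights) %*% xtx_inv %*% weights)
  se <- sqrt(fit$residual_variance * wvar)
  t <- ifelse(se > 0, effect / se, ifelse(effect == 0, 0, Inf * sign(effect)))
  structure(list(t = t, dof = fit$dof, label = label), class = "fd_tmap")
}

#' One-sided activation p-values for a t map
#'
#' @param tmap An `fd_tmap`.
#' @param alternative `"greater"` (activation), `"less"`, or
#'   `"two.sided"`.
#' @return Vector of p-values.
#' @export
tmap_p <- function(tmap, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  switch(alternative,
         greater = stats::pt(tmap$t, tmap$dof, lower.tail = FALSE),
         less = stats::pt(tmap$t, tmap$dof),
         two.sided = 2 * stats::pt(-abs(tmap$t), tmap$dof))
}

#' Peak and window summaries of a deconvolved time-bin series
#'
#' Summarizes FIR (deconvolution) betas in two ways: the value at the time
#' bin, within the peak window, where the grand-mean response across all
#' series is maximal (an unbiased peak selection shared by every series);
#' and the mean over all bins inside the averaging window (inclusive).
#'
#' @param bin_values Numeric matrix, bins x series (a vector is treated as
#'   one series).
#' @param bin_times Bin times in seconds (post-stimulus).
#' @param peak_window Peak-search window in seconds, default `c(5, 7)`.
#' @param avg_window Averaging window in seconds, default `c(3, 9)`.
#' @return A list with `peak` (per series), `window_mean` (per series), and
#'   `peak_time`.
#' @export
peak_and_window <- function(bin_values, bin_times, peak_window = c(5, 7),
                            avg_window = c(3, 9)) {
  bin_values <- as.matrix(bin_values)
  stopifnot(nrow(bin_values) == length(bin_times))
  in_peak <- bin_times >= peak_window[1] & bin_times <= peak_window[2]
  in_avg <- bin_times >= avg_window[1] & bin_times <= avg_window[2]
  if (!any(in_peak) || !any(in_avg))
    stop("summary window lies outside the available time bins")
  grand <- rowMeans(bin_values)
  peak_idx <- which(in_peak)[which.max(grand[in_peak])]
  list(peak = bin_values[peak_idx, ],
       window_mean = colMeans(bin_values[in_avg, , drop = FALSE]),
       peak_time = bin_times[peak_idx])
}

#' Concatenated fixed-effects design across subjects and runs
#'
#' Builds one design matrix over all (subject, run) blocks with a single
#' predictor per stimulus condition and one intercept confound per block
#' (e.g. 9 subjects x 6 runs = 54 confound columns).  Condition predictors
#' are stimulus boxcars, optionally convolved with an HRF per block.
#'
#' @param events Event table with columns onset, duration, trial_type,
#'   run, subject.
#' @param n_volumes Volumes per block: a single number, or a data frame
#'   with columns subject, run, n_volumes.
#' @param tr Repetition time in seconds.
#' @param conditions Conditions to model; defaults to the unique
#'   non-baseline trial types.
#' @param hrf `NULL` for raw boxcar (stick) predictors, or an `fd_hrf` to
#'   convolve each block's predictors.
#' @param baseline_condition Label excluded from modelling.
#' @return An `fd_designmat`; rows are the concatenated block volumes, and
#'   a `blocks` attribute records the (subject, run, rows) layout.
#' @export
fixed_effects_design <- function(events, n_volumes, tr = 1,
                                 conditions = NULL, hrf = NULL,
                                 baseline_condition = "baseline") {
  if (!all(c("subject", "run") %in% names(events)))
    stop("events must carry 'subject' and 'run' labels")
  if (is.null(conditions))
    conditions <- setdiff(unique(events$trial_type), baseline_condition)
  blocks <- unique(events[, c("subject", "run")])
  blocks <- blocks[order(blocks$subject, blocks$run), , drop = FALSE]
  nb <- nrow(blocks)
  nv <- if (is.data.frame(n_volumes)) {
    key <- paste(blocks$subject, blocks$run)
    lut <- stats::setNames(n_volumes$n_volumes,
                           paste(n_volumes$subject, n_volumes$run))
    as.integer(lut[key])
  } else rep(as.integer(n_volumes), nb)
  if (anyNA(nv)) stop("missing volume count for some (subject, run) block")

  total <- sum(nv)
  Xc <- matrix(0, total, length(conditions))
  Xi <- matrix(0, total, nb)
  offset <- 0L
  block_rows <- vector("list", nb)
  for (b in seq_len(nb)) {
    rows <- offset + seq_len(nv[b])
    block_rows[[b]] <- rows
    ev <- events[events$subject == blocks$subject[b] &
                   events$run == blocks$run[b], , drop = FALSE]
    for (ci in seq_along(conditions)) {
      e <- ev[ev$trial_type == conditions[ci], , drop = FALSE]
      box <- numeric(nv[b])
      if (nrow(e)) {
        onset_vol <- round(e$onset / tr)
        if (any(onset_vol < 0) || any(onset_vol >= nv[b]))
          stop("event onset outside the block's volume range")
        for (j in seq_len(nrow(e))) {
          idx <- onset_vol[j] + seq_len(max(1L, round(e$duration[j] / tr)))
          idx <- idx[idx <= nv[b]]
          box[idx] <- box[idx] + 1
        }
      }
      if (!is.null(hrf)) box <- convolve_causal(box, hrf$weights)
      Xc[rows, ci] <- box
    }
    Xi[rows, b] <- 1
    offset <- offset + nv[b]
  }
  columns <- rbind(
    data.frame(kind = "condition", condition = conditions, bin = NA,
               trial = NA_integer_, label = conditions,
               stringsAsFactors = FALSE),
    data.frame(kind = "confound", condition = NA, bin = NA,
               trial = NA_integer_,
               label = sprintf("s%s_r%s", blocks$subject, blocks$run),
               stringsAsFactors = FALSE))
  dm <- new_designmat(cbind(Xc, Xi), columns)
  attr(dm, "blocks") <- cbind(blocks, n_volumes = nv)
  dm
}
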