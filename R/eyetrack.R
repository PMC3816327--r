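#' Detect saccades in a gaze trace
#'
#' Applies the screening rule for fixation compliance: after per-run linear
#' detrending of both gaze axes and centring on the run's median position,
#' every maximal contiguous stretch of samples whose radius (Euclidean
#' distance from fixation) exceeds the threshold for at least the minimum
#' duration is classified as one saccade.  The rule is rotation-invariant
#' (radius-based) and, through the detrending, insensitive to slow drifts
#' of the trace.  The duration criterion is inclusive: a stretch lasting
#' exactly the minimum duration counts.
#'
#' @param trace An `fd_gaze`, or an n x 2 matrix of (x, y) samples in
#'   degrees (then `rate` must be given).
#' @param radius_threshold Radius threshold in degrees, default 1.5.
#' @param min_duration_ms Minimum duration in milliseconds, default 150;
#'   must span at least 2 samples at the trace's sampling rate.
#' @param rate Sampling rate in Hz when `trace` is a plain matrix.
#' @param detrend Linearly detrend each axis first (default TRUE).
#' @return Data frame with one row per saccade: `onset_sample`,
#'   `offset_sample`, `duration_ms`, `peak_radius`.
#' @export
detect_saccades <- function(trace, radius_threshold = 1.5,
                            min_duration_ms = 150, rate = NULL,
                            detrend = TRUE) {
  if (inherits(trace, "fd_gaze")) {
    xy <- trace$samples
    rate <- trace$rate
  } else {
    xy <- as.matrix(trace)
    if (is.null(rate)) stop("'rate' is required for plain matrices")
  }
  stopifnot(ncol(xy) == 2, rate > 0, radius_threshold > 0)
  min_samples <- ceiling(min_duration_ms / 1000 * rate)
  if (min_samples < 2)
    stop("'min_duration_ms' spans fewer than 2 samples at this rate")
  if (detrend && nrow(xy) >= 3) xy <- t(detrend_linear(t(xy)))
  xy <- sweep(xy, 2, apply(xy, 2, stats::median))
  radius <- sqrt(rowSums(xy^2))

  runs <- rle(radius > radius_threshold)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_samples
  data.frame(onset_sample = starts[keep], offset_sample = ends[keep],
             duration_ms = runs$lengths[keep] / rate * 1000,
             peak_radius = vapply(which(keep), function(i)
               max(radius[starts[i]:ends[i]]), numeric(1)))
}

#' Compare mean fixation position between two task conditions
#'
#' Per-axis comparison of per-run mean gaze position across tasks: a paired
#' t-test when the two trace sets pair up (equal counts, e.g. alternating
#' runs), otherwise a two-sample Welch test with a warning.  Identical
#' trace sets give t = 0, p = 1.
#'
#' @param traces_a,traces_b Lists of `fd_gaze` traces (one per run), at
#'   least 2 each.
#' @return A list with `horizontal` and `vertical` components, each
#'   `(t, p, dof)`, plus `paired`.
#' @export
compare_fixation <- function(traces_a, traces_b) {
  mean_pos <- function(tr) colMeans(tr$samples)
  a <- t(vapply(traces_a, mean_pos, numeric(2)))
  b <- t(vapply(traces_b, mean_pos, numeric(2)))
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("at least 2 traces per task are required")
  paired <- nrow(a) == nrow(b)
  if (!paired)
    warning("unequal run counts; falling back to a two-sample test")
  axis_test <- function(x, y) {
    if (paired) {
      d <- x - y
      if (stats::sd(d) == 0) {
        t <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
        return(list(t = t, p = if (t == 0) 1 else 0, dof = length(d) - 1))
      }
      tt <- stats::t.test(x, y, paired = TRUE)
    } else {
      tt <- stats::t.test(x, y)
    }
    list(t = unname(tt$statistic), p = tt$p.value,
         dof = unname(tt$parameter))
  }
  list(horizontal = axis_test(a[, 1], b[, 1]),
       vertical = axis_test(a[, 2], b[, 2]),
       paired = paired)
}
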