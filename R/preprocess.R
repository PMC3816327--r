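#' Per-voxel linear trend removal
#'
#' Removes the least-squares best-fit line from every voxel time course and
#' adds the voxel mean back, so the operator is mean-preserving: a pure ramp
#' becomes a constant at its own mean, a constant series is unchanged.  The
#' operator is an orthogonal projection, hence linear and idempotent.
#'
#' @param run An `fd_bold` run, or a voxels x volumes matrix.
#' @return Same type as the input, detrended.
#' @export
detrend_linear <- function(run) {
  data <- if (inherits(run, "fd_bold")) run$data else as.matrix(run)
  n <- ncol(data)
  if (n < 3) stop("detrending requires at least 3 volumes")
  t <- seq_len(n)
  tc <- t - mean(t)
  # slope per voxel; removing slope * tc keeps the mean untouched
  slope <- as.numeric(data %*% tc) / sum(tc^2)
  out <- data - outer(slope, tc)
  if (inherits(run, "fd_bold")) bold_run(out, run$tr, run$run_id) else out
}

#' Temporal high-pass filter (harmonic drift regression)
#'
#' Removes slow drifts by regressing each voxel time course against
#' sine/cosine harmonic pairs at every run frequency below the cutoff,
#' then keeping the residual plus the voxel mean.  This is GLM-style drift
#' removal: exactly linear, zero phase shift, and mean-preserving.  Using
#' both phases per frequency means a slow sinusoid of any phase is
#' attenuated, while components well above the cutoff pass essentially
#' unchanged.
#'
#' @param run An `fd_bold` run, or a voxels x volumes matrix.
#' @param cutoff_hz Cutoff frequency in Hz (default 0.006); must lie below
#'   the Nyquist frequency `0.5 / tr`.
#' @param tr Repetition time in seconds; taken from the run when it is an
#'   `fd_bold`.
#' @return Same type as the input, filtered.
#' @export
highpass <- function(run, cutoff_hz = 0.006, tr = NULL) {
  is_bold <- inherits(run, "fd_bold")
  data <- if (is_bold) run$data else as.matrix(run)
  tr <- if (is_bold) run$tr else (tr %||% 1)
  stopifnot(cutoff_hz > 0)
  if (cutoff_hz >= 0.5 / tr)
    stop("'cutoff_hz' must be below the Nyquist frequency 0.5/TR")
  n <- ncol(data)
  B <- drift_basis(n, tr, cutoff_hz)
  out <- if (is.null(B)) data else {
    # project out the drift basis (orthonormal columns)
    coef <- data %*% B
    data - coef %*% t(B)
  }
  if (is_bold) bold_run(out, tr, run$run_id) else out
}

# Harmonic drift basis: sine/cosine pairs at run frequencies j / (n tr),
# j = 1 .. J, strictly below the cutoff; orthonormalized and orthogonal to
# the constant.  NULL when no run frequency falls below the cutoff.
drift_basis <- function(n, tr, cutoff_hz) {
  j_max <- ceiling(n * tr * cutoff_hz) - 1
  if (j_max < 1) return(NULL)
  t <- seq_len(n) - 1
  B <- do.call(cbind, lapply(seq_len(j_max), function(j) {
    w <- 2 * pi * j * t / n
    cbind(cos(w), sin(w))
  }))
  B <- sweep(B, 2, colMeans(B))
  qr.Q(qr(B))
}
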