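# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  seed = NULL evaluates as-is.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Folds a master seed and any number of integer tags (subject index, run,
#' fold, draw, ...) into a single seed below 2^31, so that every source of
#' randomness in a multi-stage simulation is a pure function of the master
#' seed and its position in the pipeline.
#'
#' @param seed Master integer seed.
#' @param ... Further integer tags identifying the consumer.
#' @return A single integer seed in [0, 2147483646].
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  acc <- 0
  for (k in ks) acc <- (acc * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(acc)
}

# Causal discrete convolution of x with kernel h, truncated to length(x).
convolve_causal <- function(x, h) {
  n <- length(x)
  if (length(h) == 1L) return(x * h)
  stats::convolve(x, rev(h), type = "open")[seq_len(n)]
}

# Circular shift: y[t] = x[t - k] with wrap-around (delay by k samples).
circshift <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) return(x)
  x[((seq_len(n) - 1 - k) %% n) + 1]
}

# Column-wise Pearson correlation that returns 0 (not NA) for zero-variance
# columns of `x`; x: n x p, y: n x q -> p x q matrix, plus a "flagged"
# attribute marking degenerate columns of x.
safe_cor <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  sx <- apply(x, 2, stats::sd)
  sy <- apply(y, 2, stats::sd)
  flagged <- sx == 0
  xs <- sweep(x, 2, colMeans(x))
  ys <- sweep(y, 2, colMeans(y))
  r <- crossprod(xs, ys) / (nrow(x) - 1)
  r <- sweep(r, 1, ifelse(sx > 0, sx, 1), "/")
  r <- sweep(r, 2, ifelse(sy > 0, sy, 1), "/")
  r[flagged, ] <- 0
  r[, sy == 0] <- 0
  r <- pmin(pmax(r, -1), 1)
  attr(r, "flagged") <- flagged
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
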