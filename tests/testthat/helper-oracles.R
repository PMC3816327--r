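# Independent oracles used across test files.  Each is a deliberately naive
# implementation (direct summation, normal equations, grid search) kept
# separate from the code paths it checks.

# direct-summation causal convolution: y[t] = sum_k x[k] h[t - k + 1]
oracle_convolve <- function(x, h) {
  n <- length(x)
  y <- numeric(n)
  for (t in seq_len(n)) {
    for (k in seq_len(t)) {
      j <- t - k + 1
      if (j <= length(h)) y[t] <- y[t] + x[k] * h[j]
    }
  }
  y
}

# OLS by explicit normal equations
oracle_ols <- function(X, y) solve(crossprod(X), crossprod(X, y))

# maximum margin of a linearly separable 2-d set by grid search over unit
# normals; returns the best (geometric) margin found
oracle_max_margin_2d <- function(X, y, n_angles = 7200) {
  y <- ifelse(y == sort(unique(y))[1], -1, 1)
  best <- -Inf
  for (a in seq(0, pi, length.out = n_angles)) {
    w <- c(cos(a), sin(a))
    proj <- X %*% w
    for (s in c(1, -1)) {
      lo <- min(s * proj[y == 1])
      hi <- max(s * proj[y == -1])
      best <- max(best, (lo - hi) / 2)
    }
  }
  best
}

# hand-executed BH step-up rule
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  if (k == 0) integer(0) else sort(o[seq_len(k)])
}

# hand-executed Holm step-down rule
oracle_holm <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  rejected <- integer(0)
  for (i in seq_len(m)) {
    if (ps[i] <= alpha / (m - i + 1)) rejected <- c(rejected, o[i])
    else break
  }
  sort(rejected)
}

# quick null trial-pattern set: pure-noise betas with balanced labels
null_patterns <- function(seed, n_runs = 6, per_class = 20, n_feat = 40,
                          classes = c("a", "b")) {
  n <- n_runs * per_class * length(classes)
  set.seed(seed)
  trial_patterns(matrix(rnorm(n * n_feat), n, n_feat),
                 rep(rep(classes, each = per_class), n_runs),
                 rep(seq_len(n_runs), each = per_class * length(classes)))
}

# separable two-class pattern set: class means +/- delta on every feature
separable_patterns <- function(seed, n_runs = 4, per_class = 6,
                               n_feat = 10, delta = 3, noise = 1) {
  n <- n_runs * per_class * 2
  set.seed(seed)
  labels <- rep(rep(c("a", "b"), each = per_class), n_runs)
  mu <- ifelse(labels == "a", delta, -delta)
  betas <- matrix(rnorm(n * n_feat, sd = noise), n, n_feat) + mu
  trial_patterns(betas, labels,
                 rep(seq_len(n_runs), each = per_class * 2))
}
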