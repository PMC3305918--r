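# Independent oracles used by the unit and acceptance tests. Each one
# re-derives the target quantity by a different route (explicit loops,
# enumeration, closed forms) and must stay independent of the package's
# production code paths.

# Approximate entropy by exhaustive pairwise evaluation: per-pair max-norm
# template distance, counts with self-matches, condition d <= r.
apen_oracle <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x)
    K <- n - mm + 1L
    C <- numeric(K)
    for (i in seq_len(K)) {
      cnt <- 0L
      for (j in seq_len(K)) {
        d <- max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)]))
        if (d <= r) cnt <- cnt + 1L
      }
      C[i] <- cnt / K
    }
    mean(log(C))
  }
  phi(m) - phi(m + 1L)
}

# Correlation sums by explicit ordered-pair counting (self-pairs included),
# Euclidean distance accumulated component-wise.
corr_sum_oracle <- function(x, m, radii) {
  K <- length(x) - m + 1L
  d <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    s <- 0
    for (k in seq_len(m) - 1L) s <- s + (x[i + k] - x[j + k])^2
    d[i, j] <- sqrt(s)
  }
  vapply(radii, function(r) sum(d <= r) / K^2, numeric(1))
}

# Recurrence quantification by an explicit matrix walk: loops build the
# thresholded distance matrix, then every off-main diagonal is scanned
# point by point for runs of recurrences.
rqa_oracle <- function(x, m, tau, r, l_min = 2L) {
  N <- length(x)
  K <- N - (m - 1L) * tau
  M2 <- matrix(FALSE, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    s <- 0
    for (k in seq_len(m) - 1L) s <- s + (x[i + k * tau] - x[j + k * tau])^2
    M2[i, j] <- sqrt(s) < r
  }
  total <- sum(M2)
  lens <- integer(0)
  for (d in seq_len(K - 1L)) {
    run <- 0L
    for (i in seq_len(K - d)) {
      if (M2[i, i + d]) run <- run + 1L
      else { if (run > 0L) lens <- c(lens, run); run <- 0L }
    }
    if (run > 0L) lens <- c(lens, run)
  }
  lens <- rep(lens, 2L)           # symmetric matrix: lower triangle mirrors
  counted <- lens[lens >= l_min]
  if (length(counted) == 0L)
    return(list(rec = total / K^2, det = 0, shen = 0, l_mean = 0, l_max = 0))
  hist <- table(counted)
  nl <- as.numeric(hist) / sum(hist)
  list(rec = total / K^2,
       det = sum(counted) / total,
       shen = -sum(nl * log(nl)),
       l_mean = mean(counted),
       l_max = max(counted))
}

# Exact two-sided signed-rank p-value by bitmask enumeration of all 2^n
# sign assignments (independent of the expand.grid path in the package).
wsr_exact_oracle <- function(d) {
  nz <- d[d != 0]
  n <- length(nz)
  rk <- rank(abs(nz))
  W <- sum(rk[nz > 0])
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  W_all <- vapply(0:(2^n - 1L), function(mask) sum(rk[bitwAnd(mask, bits) != 0L]),
                  numeric(1))
  min(1, 2 * min(mean(W_all <= W), mean(W_all >= W)))
}

# Order-statistic quantiles by hand (type-7 linear interpolation).
quantile7_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Angle in degrees between two direction vectors (sign-insensitive).
angle_deg <- function(a, b) {
  ca <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, ca)) * 180 / pi
}

# Small paired feature frame used by the classifier tests: n subjects with
# controllable per-feature class separation.
make_toy_features <- function(n_subjects, shifts, noise = 1, seed = 1) {
  feats <- names(shifts)
  with_seed_t(seed, {
    rows <- lapply(seq_len(n_subjects), function(i) {
      base <- stats::rnorm(length(shifts), 0, noise)
      rest <- base + stats::rnorm(length(shifts), 0, noise)
      stress <- base + unlist(shifts) + stats::rnorm(length(shifts), 0, noise)
      rbind(
        data.frame(subject_id = sprintf("S%02d", i), session = "rest",
                   as.data.frame(as.list(stats::setNames(rest, feats)))),
        data.frame(subject_id = sprintf("S%02d", i), session = "stress",
                   as.data.frame(as.list(stats::setNames(stress, feats))))
      )
    })
    do.call(rbind, rows)
  })
}

# Seed scoping for test fixtures (kept separate from the package internal).
with_seed_t <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
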