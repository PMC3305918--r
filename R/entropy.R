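# Approximate entropy and its three tolerance choices.
#
# ApEn(m, r, N) = Phi^m(r) - Phi^{m+1}(r), where
#   C_i^m(r) = #{ j : d[X_i, X_j] <= r } / (N - m + 1)   (self-match included)
#   Phi^m(r) = mean_i ln C_i^m(r)
# with d the maximum absolute component difference between the length-m
# template vectors X_i = (x_i, ..., x_{i+m-1}).

# Max-norm template distance matrix for embedding dimension m (tau = 1),
# built by a rolling pmax over the scalar distance matrix.
maxnorm_dists <- function(x, m) {
  n <- length(x)
  K <- n - m + 1L
  D1 <- abs(outer(x, x, "-"))
  D <- D1[seq_len(K), seq_len(K), drop = FALSE]
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      idx <- (1L + k):(K + k)
      D <- pmax(D, D1[idx, idx, drop = FALSE])
    }
  }
  D
}

# Precompute both template distance matrices once; ApEn at any tolerance is
# then a cheap threshold-and-count, which makes the 81-point r_max grid viable.
apen_engine <- function(x, m) {
  n <- length(x)
  if (n < m + 2L) stop_validation("series too short for ApEn with m = ", m)
  Dm <- maxnorm_dists(x, m)
  Dm1 <- maxnorm_dists(x, m + 1L)
  K1 <- n - m + 1L
  K2 <- n - m
  function(r) {
    c1 <- rowSums(Dm <= r) / K1
    c2 <- rowSums(Dm1 <= r) / K2
    # self-matches guarantee c1, c2 > 0
    mean(log(c1)) - mean(log(c2))
  }
}

#' Approximate entropy of an NN series
#'
#' Regularity statistic of the beat-interval series: the negative average
#' log-likelihood that template vectors close (within tolerance `r`, maximum
#' absolute component distance, condition `d <= r`, self-matches included)
#' for `m` beats remain close for `m + 1`. Lower values mean more regular
#' dynamics; a constant series has ApEn exactly 0.
#'
#' @param nn An `nn_series` or numeric vector (seconds).
#' @param m Template length (default 2).
#' @param r Tolerance in seconds, > 0. Conventionally `0.2 * SDNN`; see
#'   [chon_threshold()] and [max_entropy_threshold()] for the two data-driven
#'   alternatives.
#' @return Approximate entropy (dimensionless, >= 0 up to floating error).
#' @examples
#' x <- c(1, 2, 1, 2, 1, 2, 1, 2)
#' approximate_entropy(x, m = 2, r = 0.5)
#' @export
approximate_entropy <- function(nn, m = 2L, r) {
  x <- nn_intervals(nn)
  if (missing(r)) stop_validation("tolerance r must be supplied")
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0)
    stop_validation("tolerance r must be a single positive number")
  apen_engine(x, as.integer(m))(r)
}

#' Chon tolerance for approximate entropy
#'
#' Data-driven tolerance from the regression formula
#' \deqn{r_{chon} = \frac{-0.036 + 0.26\sqrt{SDDS/SDNN}}{(N/1000)^{1/4}}}
#' where SDDS is the (population) standard deviation of the first-difference
#' sequence and SDNN that of the series itself. The formula's output is a
#' tolerance expressed in units of SDNN: [extract_all_features()] applies it
#' as `r = r_chon * SDNN` by default (Chon's published usage, and the only
#' reading consistent with En(rchon) tracking En(0.2*SDNN) on real data); a
#' `"literal"` mode applying the raw value as seconds is also available there.
#'
#' @param nn An `nn_series` or numeric vector (seconds), length >= 2 with
#'   non-zero SDNN.
#' @return The formula value (dimensionless multiplier of SDNN).
#' @export
chon_threshold <- function(nn) {
  x <- nn_intervals(nn)
  n <- length(x)
  if (n < 2L) stop_validation("need at least 2 intervals")
  sdnn <- sd_pop(x)
  if (sdnn == 0) stop_validation("degenerate series: SDNN is zero")
  sdds <- sd_pop(diff(x))
  (-0.036 + 0.26 * sqrt(sdds / sdnn)) / (n / 1000)^0.25
}

#' Entropy-maximising tolerance
#'
#' Searches an evenly spaced 81-point grid over `[0.1*SDNN, 0.9*SDNN]`
#' (step `0.01*SDNN`, endpoints included) for the tolerance maximising
#' ApEn(m, r); ties go to the smaller r.
#'
#' @param nn An `nn_series` or numeric vector (seconds).
#' @param m Template length (default 2).
#' @return List with `r_max` (seconds), `en_rmax` (the maximised ApEn),
#'   `grid` and `values` (the profile searched).
#' @export
max_entropy_threshold <- function(nn, m = 2L) {
  x <- nn_intervals(nn)
  sdnn <- sd_pop(x)
  if (sdnn == 0) stop_validation("degenerate series: SDNN is zero")
  engine <- apen_engine(x, as.integer(m))
  grid <- seq(0.1, 0.9, by = 0.01) * sdnn
  values <- vapply(grid, engine, numeric(1))
  i <- which.max(values)  # first maximum: ties break toward smaller r
  list(r_max = grid[[i]], en_rmax = values[[i]], grid = grid, values = values)
}
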