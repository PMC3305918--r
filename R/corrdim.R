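# Correlation dimension (Grassberger-Procaccia style, fixed embedding).

#' Correlation dimension D2
#'
#' Embeds the series in dimension `m` (lag 1), computes the correlation sum
#' \deqn{C^m(r) = \frac{1}{K}\sum_i \frac{\#\{j : \|X_i - X_j\| \le r\}}{K}}
#' (Euclidean distance, self-matches included) over a grid of `n_radii`
#' log-spaced radii between the 1st and 99th percentiles of the positive
#' pairwise distances, and estimates D2 as the least-squares slope of
#' `log C` on `log r` over the widest contiguous sub-range where
#' `C` lies strictly inside `(1/K^2, 0.95)`. Negative slopes are clipped to 0.
#'
#' @param nn An `nn_series` or numeric vector (seconds).
#' @param m Embedding dimension (default 10).
#' @param n_radii Number of radii on the log grid (default 50).
#' @return D2 estimate (>= 0) with attribute `"fit"`: a list with the radii,
#'   correlation sums, and the indices of the fitted sub-range.
#' @export
correlation_dimension <- function(nn, m = 10L, n_radii = 50L) {
  x <- nn_intervals(nn)
  m <- as.integer(m)
  n <- length(x)
  if (n < m + 10L)
    stop_validation("series too short for correlation dimension with m = ", m)
  emb <- embed_rows(x, m, 1L)
  K <- nrow(emb)
  D <- as.matrix(stats::dist(emb))
  pd <- D[upper.tri(D)]
  pos <- pd[pd > 0]
  if (length(pos) == 0L) {
    # all embedded vectors identical: C^m(r) = 1 for every r > 0, slope 0
    out <- 0
    attr(out, "fit") <- list(radii = numeric(0), corr_sum = numeric(0),
                             fit_idx = integer(0), degenerate = TRUE)
    return(out)
  }
  qs <- stats::quantile(pos, c(0.01, 0.99), names = FALSE, type = 7)
  radii <- exp(seq(log(qs[[1]]), log(qs[[2]]), length.out = n_radii))
  total <- vapply(radii, function(r) sum(D <= r), numeric(1))
  corr_sum <- total / K^2
  ok <- corr_sum > 1 / K^2 & corr_sum < 0.95
  runs <- rle(ok)
  if (!any(runs$values)) stop_validation("no usable radii for the D2 regression")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  w <- which(runs$values)
  best <- w[which.max(runs$lengths[w])]
  fit_idx <- starts[best]:ends[best]
  if (length(fit_idx) < 3L)
    stop_validation("fewer than 3 usable points for the D2 regression")
  lx <- log(radii[fit_idx])
  ly <- log(corr_sum[fit_idx])
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  out <- max(slope, 0)
  attr(out, "fit") <- list(radii = radii, corr_sum = corr_sum,
                           fit_idx = fit_idx, degenerate = FALSE)
  out
}
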