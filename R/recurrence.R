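# Recurrence plot quantification.
#
# Conventions (fixed, recorded in output):
#  * recurrence condition is strict, d < r (distance exactly r maps to 0);
#  * REC sums the full matrix including the line of identity (LOI);
#  * diagonal lines are counted OFF the LOI only, with minimum length 2;
#  * DET = sum(l * N_l, l >= 2) / sum(M2) with the full-matrix denominator;
#  * ShEn = -sum(n_l ln n_l) over the line-length distribution (fractions,
#    natural log), the sign chosen so the entropy is non-negative.

#' Recurrence quantification of an NN series
#'
#' Embeds the series (dimension `m`, lag `tau`), thresholds the Euclidean
#' distance matrix at radius `r` and quantifies the binary recurrence matrix:
#' recurrence rate REC, determinism DET, Shannon entropy ShEn of the diagonal
#' line-length distribution, and mean/maximal diagonal line length.
#'
#' @param nn An `nn_series` or numeric vector (seconds).
#' @param m Embedding dimension (default 10).
#' @param tau Embedding lag in beats (default 1).
#' @param radius_mode `"sqrt_m"` (default): `r = sqrt(m) * SDNN`, the Kubios
#'   convention; `"literal"`: `r = m * SDNN`. Ignored when `r` is given.
#' @param r Explicit radius in seconds (overrides `radius_mode`).
#' @param l_min Minimum diagonal line length counted (default 2).
#' @param keep_matrix Keep the K x K recurrence matrix in the result
#'   (default `FALSE`; it is O(K^2) memory).
#' @return Object of class `rqa`: list with `rec`, `det`, `shen`, `l_mean`,
#'   `l_max` (REC/DET as fractions in \[0, 1\], lengths in beats), plus `K`,
#'   `r`, `radius_mode`, `n_lines`, `line_histogram` (a table of counted line
#'   lengths), `no_lines` flag, and optionally `matrix`.
#' @export
recurrence_measures <- function(nn, m = 10L, tau = 1L,
                                radius_mode = c("sqrt_m", "literal"),
                                r = NULL, l_min = 2L, keep_matrix = FALSE) {
  x <- nn_intervals(nn)
  m <- as.integer(m); tau <- as.integer(tau)
  radius_mode <- match.arg(radius_mode)
  N <- length(x)
  K <- N - (m - 1L) * tau
  if (K < 10L)
    stop_validation("series too short for recurrence analysis (need N >= (m-1)*tau + 10)")
  if (is.null(r)) {
    sdnn <- sd_pop(x)
    r <- switch(radius_mode, sqrt_m = sqrt(m) * sdnn, literal = m * sdnn)
  } else {
    radius_mode <- "explicit"
  }
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0)
    stop_validation("radius r must be a single non-negative number")
  emb <- embed_rows(x, m, tau)
  D <- as.matrix(stats::dist(emb))
  M2 <- D < r
  total <- sum(M2)
  rec <- total / K^2

  # run lengths of recurrent points along each off-LOI diagonal; symmetric
  # matrix, so count the upper triangle and double
  lengths_upper <- integer(0)
  for (d in seq_len(K - 1L)) {
    i <- seq_len(K - d)
    v <- M2[cbind(i, i + d)]
    rl <- rle(v)
    lens <- rl$lengths[rl$values]
    if (length(lens)) lengths_upper <- c(lengths_upper, lens)
  }
  all_lengths <- rep(lengths_upper, 2L)
  counted <- all_lengths[all_lengths >= l_min]

  if (length(counted) == 0L) {
    warning("no off-diagonal line of length >= ", l_min,
            "; DET, ShEn, l_mean, l_max reported as 0", call. = FALSE)
    out <- list(rec = rec, det = 0, shen = 0, l_mean = 0, l_max = 0,
                K = K, r = r, radius_mode = radius_mode, l_min = l_min,
                n_lines = 0L, line_histogram = table(integer(0)),
                no_lines = TRUE)
  } else {
    hist <- table(counted)
    nl <- as.numeric(hist) / sum(hist)
    out <- list(
      rec = rec,
      det = sum(counted) / total,
      shen = -sum(nl * log(nl)),
      l_mean = mean(counted),
      l_max = max(counted),
      K = K, r = r, radius_mode = radius_mode, l_min = l_min,
      n_lines = length(counted), line_histogram = hist,
      no_lines = FALSE
    )
  }
  if (keep_matrix) out$matrix <- M2
  class(out) <- "rqa"
  out
}

#' @export
print.rqa <- function(x, ...) {
  cat(sprintf(
    "RQA (K = %d, r = %.4g [%s]): REC = %.4f, DET = %.4f, ShEn = %.3f, l_mean = %.2f, l_max = %d\n",
    x$K, x$r, x$radius_mode, x$rec, x$det, x$shen, x$l_mean, as.integer(x$l_max)))
  invisible(x)
}
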