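# Detrended fluctuation analysis.

#' Detrended fluctuation analysis of an NN series
#'
#' The mean-centred series is integrated, `y(k) = sum_{j<=k}(x_j - mean(x))`;
#' for each box size `n` the integrated profile is split into
#' `floor(N/n)` non-overlapping segments (trailing remainder dropped), a
#' least-squares line is fitted in each, and
#' \deqn{F(n) = \sqrt{\frac{1}{n\lfloor N/n\rfloor}\sum (y(k)-y_n(k))^2}}
#' over the covered samples. The scaling exponents are the slopes of
#' `log F(n)` on `log n`: `alpha1` over box sizes 4-16 (short-term) and
#' `alpha2` over 16-64 (long-term); n = 16 belongs to both ranges.
#'
#' @param nn An `nn_series` or numeric vector (seconds); N >= 8 required,
#'   N >= 64 recommended (larger boxes are skipped when they do not fit).
#' @return Object of class `dfa_profile`: list with `box_sizes`,
#'   `fluctuations`, `alpha1`, `alpha2`.
#' @export
detrended_fluctuation <- function(nn) {
  x <- nn_intervals(nn)
  N <- length(x)
  if (N < 8L) stop_validation("series too short for DFA (need N >= 8)")
  y <- cumsum(x - mean(x))
  ns <- 4:64
  ns <- ns[ns <= N]
  Fn <- vapply(ns, function(n) {
    nseg <- N %/% n
    L <- nseg * n
    Y <- matrix(y[seq_len(L)], nrow = n)
    t1 <- seq_len(n)
    St <- sum(t1); Stt <- sum(t1^2)
    den <- n * Stt - St^2
    Sy <- colSums(Y)
    Sty <- as.numeric(crossprod(t1, Y))
    b <- (n * Sty - St * Sy) / den
    a <- (Sy - b * St) / n
    res <- Y - (rep(t1, nseg) * rep(b, each = n) + rep(a, each = n))
    sqrt(sum(res^2) / L)
  }, numeric(1))
  if (any(Fn == 0)) {
    n_bad <- ns[which(Fn == 0)[1L]]
    stop_validation("DFA fluctuation is zero at box size n = ", n_bad,
                    " (perfectly piecewise-linear profile); slope undefined")
  }
  slope_over <- function(lo, hi) {
    sel <- ns >= lo & ns <= hi
    if (sum(sel) < 2L) return(NA_real_)
    lx <- log(ns[sel]); ly <- log(Fn[sel])
    sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  }
  structure(
    list(box_sizes = ns, fluctuations = Fn,
         alpha1 = slope_over(4L, 16L), alpha2 = slope_over(16L, 64L)),
    class = "dfa_profile"
  )
}

#' @export
print.dfa_profile <- function(x, ...) {
  cat(sprintf("DFA profile: n in [%d, %d], alpha1 = %.3f, alpha2 = %.3f\n",
              min(x$box_sizes), max(x$box_sizes), x$alpha1, x$alpha2))
  invisible(x)
}
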