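# Poincare plot descriptors.

#' Poincare plot descriptors SD1 and SD2
#'
#' The Poincare plot scatters `RR[j+1]` against `RR[j]`. SD1 and SD2 are the
#' standard deviations of the cloud perpendicular to and along the line of
#' identity. They are computed by the rotated-coordinate closed form
#' (the fitted ellipse is a visualization of the same quantities):
#' \deqn{SD1^2 = Var((RR_{j+1} - RR_j)/\sqrt 2), \quad
#'       SD2^2 = Var((RR_{j+1} + RR_j)/\sqrt 2)}
#' with the population (divide-by-N) variance, so that
#' `SD1^2 + SD2^2` equals the total variance of the lag-1 point cloud exactly.
#'
#' @param nn An `nn_series` or numeric vector of NN intervals (seconds),
#'   length >= 3.
#' @return Named numeric vector `c(SD1 = ..., SD2 = ...)`, both in seconds.
#' @examples
#' poincare_descriptors(c(0.8, 0.9, 0.8, 0.9, 0.8))
#' @export
poincare_descriptors <- function(nn) {
  x <- nn_intervals(nn)
  n <- length(x)
  if (n < 3L) stop_validation("degenerate series: need at least 3 intervals for SD1/SD2")
  d <- (x[-1L] - x[-n]) / sqrt(2)  # perpendicular to identity line
  s <- (x[-1L] + x[-n]) / sqrt(2)  # along identity line
  c(SD1 = sd_pop(d), SD2 = sd_pop(s))
}
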