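# The 13-measure nonlinear feature vector.

#' Names of the 13 nonlinear HRV features
#'
#' Canonical column order used throughout the package: SD1, SD2 (seconds),
#' En02, EnRmax, EnRchon (approximate entropy at r = 0.2*SDNN, the
#' entropy-maximising r, and the Chon formula), D2, alpha1, alpha2, lmean,
#' lmax (beats), REC, DET (fractions), ShEn.
#'
#' @return Character vector of length 13.
#' @export
hrv_feature_names <- function() {
  c("SD1", "SD2", "En02", "EnRmax", "EnRchon", "D2",
    "alpha1", "alpha2", "lmean", "lmax", "REC", "DET", "ShEn")
}

#' Extract all 13 nonlinear HRV features from an NN series
#'
#' Computes [poincare_descriptors()], approximate entropy with m = 2 at the
#' three tolerances (`0.2*SDNN`; the entropy-maximising r of
#' [max_entropy_threshold()]; the Chon formula of [chon_threshold()]),
#' [correlation_dimension()] with m = 10, [detrended_fluctuation()] slopes,
#' and [recurrence_measures()] with m = 10, tau = 1. Deterministic for a
#' fixed input.
#'
#' @param nn An `nn_series` or numeric vector of NN intervals (seconds).
#' @param rp_radius_mode Recurrence radius convention, `"sqrt_m"` (default)
#'   or `"literal"`; see [recurrence_measures()].
#' @param chon_mode How the Chon formula value is applied as an ApEn
#'   tolerance: `"sdnn_scaled"` (default, `r = r_chon * SDNN`, Chon's usage)
#'   or `"literal"` (the raw formula value taken as seconds).
#' @return Named numeric vector of length 13 (order of
#'   [hrv_feature_names()]), with attribute `"params"` recording SDNN, the r
#'   values used, and the radius/tolerance conventions.
#' @export
extract_all_features <- function(nn,
                                 rp_radius_mode = c("sqrt_m", "literal"),
                                 chon_mode = c("sdnn_scaled", "literal")) {
  rp_radius_mode <- match.arg(rp_radius_mode)
  chon_mode <- match.arg(chon_mode)
  x <- nn_intervals(nn)
  sdnn <- sd_pop(x)
  if (sdnn == 0) stop_validation("degenerate series: SDNN is zero")

  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_validation("feature '", name, "': ", conditionMessage(e)))
  }

  pp <- step("SD1/SD2", poincare_descriptors(x))
  engine <- step("ApEn", apen_engine(x, 2L))
  r02 <- 0.2 * sdnn
  en02 <- step("En02", engine(r02))
  mx <- step("EnRmax", max_entropy_threshold(x, m = 2L))
  rchon_val <- step("EnRchon", chon_threshold(x))
  rchon <- if (chon_mode == "sdnn_scaled") rchon_val * sdnn else rchon_val
  if (rchon <= 0)
    stop_validation("feature 'EnRchon': Chon tolerance is non-positive (",
                    format(rchon), ")")
  enchon <- step("EnRchon", engine(rchon))
  d2 <- step("D2", correlation_dimension(x, m = 10L))
  dfa <- step("alpha1/alpha2", detrended_fluctuation(x))
  rq <- step("RQA", recurrence_measures(x, m = 10L, tau = 1L,
                                        radius_mode = rp_radius_mode))

  out <- c(SD1 = unname(pp[["SD1"]]), SD2 = unname(pp[["SD2"]]),
           En02 = en02, EnRmax = mx$en_rmax, EnRchon = enchon,
           D2 = as.numeric(d2),
           alpha1 = dfa$alpha1, alpha2 = dfa$alpha2,
           lmean = rq$l_mean, lmax = as.numeric(rq$l_max),
           REC = rq$rec, DET = rq$det, ShEn = rq$shen)
  attr(out, "params") <- list(
    n = length(x), sdnn = sdnn,
    r_02 = r02, r_max = mx$r_max, r_chon_value = rchon_val,
    r_chon_applied = rchon, chon_mode = chon_mode,
    rp_radius = rq$r, rp_radius_mode = rp_radius_mode,
    d2_fit = attr(d2, "fit")[c("fit_idx")],
    shen_sign = "negated (entropy reported non-negative)"
  )
  out
}

#' Extract features for every record of a cohort
#'
#' Applies the NN filter and reliability criterion to each RR record, then
#' [extract_all_features()]; returns a tidy one-row-per-record data frame.
#'
#' @param records List of `rr_series`.
#' @param reliability_threshold NN/RR threshold (default 0.90); records below
#'   it are excluded (with a message) rather than analysed.
#' @param ... Passed to [extract_all_features()].
#' @return `data.frame` with columns `subject_id`, `session`, `nn_rr_ratio`
#'   and the 13 features.
#' @export
extract_cohort_features <- function(records, reliability_threshold = 0.90, ...) {
  stopifnot(is.list(records))
  rows <- lapply(records, function(rr) {
    nn <- to_nn(rr)
    if (!reliability_check(nn, reliability_threshold)) {
      message(sprintf("excluding %s/%s: NN/RR = %.3f < %.2f",
                      rr$subject_id, rr$session, nn$nn_rr_ratio,
                      reliability_threshold))
      return(NULL)
    }
    fv <- extract_all_features(nn, ...)
    cbind(data.frame(subject_id = as.character(rr$subject_id),
                     session = as.character(rr$session),
                     nn_rr_ratio = nn$nn_rr_ratio,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop_validation("no records passed the reliability criterion")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
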