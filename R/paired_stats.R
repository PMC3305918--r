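# Paired rest-vs-stress statistics: per-session descriptives, within-subject
# differences, and the Wilcoxon signed-rank test.

#' Descriptive statistics of a feature
#'
#' Mean, standard deviation (N-1 denominator; 0 for a single value by
#' convention), median and the 25th/75th percentiles (linear interpolation
#' between order statistics, quantile type 7).
#'
#' @param values Numeric vector, length >= 1.
#' @return Named numeric vector `mean`, `sd`, `median`, `q25`, `q75`.
#' @export
describe_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values))
    stop_validation("values must be non-empty and non-missing")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else 0,
    median = q[[2]], q25 = q[[1]], q75 = q[[3]])
}

# Validates the paired layout: every subject exactly one rest and one stress
# record. Returns subject ids in order of first appearance.
check_paired <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("subject_id", "session") %in% names(features)))
  subjects <- unique(features$subject_id)
  for (s in subjects) {
    ses <- features$session[features$subject_id == s]
    if (!(sum(ses == "rest") == 1L && sum(ses == "stress") == 1L))
      stop_validation("subject '", s, "' does not have exactly one rest and one stress record")
  }
  if (length(subjects) < 2L) stop_validation("need at least 2 subjects")
  subjects
}

#' Within-subject stress-minus-rest differences for one feature
#'
#' @param features Feature data frame (one row per record, columns
#'   `subject_id`, `session`, and the feature), e.g. from
#'   [extract_cohort_features()].
#' @param feature Feature column name.
#' @return List with `differences` (stress - rest, in subject order of first
#'   appearance; negative values mean the feature decreased under stress),
#'   `subjects`, and `summary` (from [describe_values()]).
#' @export
paired_differences <- function(features, feature) {
  subjects <- check_paired(features)
  if (!feature %in% names(features))
    stop_validation("unknown feature '", feature, "'")
  d <- vapply(subjects, function(s) {
    rows <- features[features$subject_id == s, ]
    rows[rows$session == "stress", feature][[1]] -
      rows[rows$session == "rest", feature][[1]]
  }, numeric(1))
  list(differences = unname(d), subjects = subjects,
       summary = describe_values(d))
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are discarded (Wilcoxon's original rule) and ties among
#' absolute values receive average ranks. The two-sided p-value is exact —
#' full enumeration of all `2^n` sign assignments of the observed ranks,
#' `p = min(1, 2 * min(P(W <= w), P(W >= w)))` — when the number of non-zero
#' differences is at most `exact_max`; otherwise the normal approximation
#' with tie correction and a 0.5 continuity correction is used.
#'
#' @param differences Numeric vector of paired differences.
#' @param exact_max Largest `n_effective` for which the exact enumeration is
#'   used (default 12).
#' @return Object of class `wsr_test`: list with `statistic` (W, the sum of
#'   ranks of positive differences), `p_value`, `n_effective`, `exact`
#'   (logical), and `degenerate` (`TRUE` when every difference is zero, in
#'   which case p = 1).
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 12L) {
  d <- as.numeric(differences)
  if (length(d) == 0L || anyNA(d))
    stop_validation("differences must be non-empty and non-missing")
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L) {
    return(structure(list(statistic = 0, p_value = 1, n_effective = 0L,
                          exact = TRUE, degenerate = TRUE),
                     class = "wsr_test"))
  }
  rk <- rank(abs(nz))
  W <- sum(rk[nz > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_all <- as.numeric(signs %*% rk)
    p <- min(1, 2 * min(mean(W_all <= W), mean(W_all >= W)))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- if (W == mu) 0 else (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = W, p_value = p, n_effective = n,
                 exact = exact, degenerate = FALSE),
            class = "wsr_test")
}

#' @export
print.wsr_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank: W = %.1f, n_eff = %d, p = %s (%s)%s\n",
              x$statistic, x$n_effective, format_p(x$p_value),
              if (x$exact) "exact" else "normal approx.",
              if (x$degenerate) " [all differences zero]" else ""))
  invisible(x)
}

# Display convention for p-values: below 0.01 printed as "<0.01",
# otherwise two decimals.
format_p <- function(p) ifelse(p < 0.01, "<0.01", sprintf("%.2f", p))

#' Per-session descriptive table for a feature cohort
#'
#' One row per feature with mean/sd/median/q25/q75 for each session.
#'
#' @param features Feature data frame (see [paired_differences()]).
#' @param feature_names Features to summarise (default the 13 of
#'   [hrv_feature_names()]).
#' @return `data.frame`, 10 statistic columns prefixed `rest_` / `stress_`.
#' @export
session_summary_table <- function(features, feature_names = hrv_feature_names()) {
  check_paired(features)
  rows <- lapply(feature_names, function(f) {
    rest <- describe_values(features[features$session == "rest", f])
    stress <- describe_values(features[features$session == "stress", f])
    names(rest) <- paste0("rest_", names(rest))
    names(stress) <- paste0("stress_", names(stress))
    cbind(data.frame(feature = f, stringsAsFactors = FALSE),
          as.data.frame(as.list(c(rest, stress))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired-difference table with Wilcoxon p-values
#'
#' One row per feature: descriptives of the stress-minus-rest differences and
#' the two-sided signed-rank p-value (numeric plus display form, values below
#' 0.01 shown as `"<0.01"`).
#'
#' @inheritParams session_summary_table
#' @return `data.frame` with columns `feature`, `mean`, `sd`, `median`,
#'   `q25`, `q75`, `p_value`, `p_display`.
#' @export
difference_table <- function(features, feature_names = hrv_feature_names()) {
  rows <- lapply(feature_names, function(f) {
    pd <- paired_differences(features, f)
    w <- wilcoxon_signed_rank(pd$differences)
    cbind(data.frame(feature = f, stringsAsFactors = FALSE),
          as.data.frame(as.list(pd$summary)),
          data.frame(p_value = w$p_value, p_display = format_p(w$p_value),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
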