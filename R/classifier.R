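# Linear discriminant stress classifier: training, prediction, binary
# performance measures, subject-wise k-fold cross-validation, and exhaustive
# feature-subset search.
#
# Rule convention throughout: score = intercept + sum(weight * feature);
# score > 0 => "stress" (score exactly 0 => "rest", strict inequality).

# Pooled within-class moments of a labelled feature matrix.
lda_moments <- function(X, y) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  i_r <- which(y == "rest"); i_s <- which(y == "stress")
  if (length(i_r) == 0L || length(i_s) == 0L)
    stop_validation("both classes must be present to train LDA")
  Xr <- X[i_r, , drop = FALSE]; Xs <- X[i_s, , drop = FALSE]
  mu_r <- colMeans(Xr); mu_s <- colMeans(Xs)
  n_r <- nrow(Xr); n_s <- nrow(Xs)
  Cr <- crossprod(sweep(Xr, 2, mu_r))
  Cs <- crossprod(sweep(Xs, 2, mu_s))
  S <- (Cr + Cs) / (n_r + n_s - 2)
  list(mu_rest = mu_r, mu_stress = mu_s, S = S, n_rest = n_r, n_stress = n_s)
}

# Fisher direction w = S^-1 (mu_stress - mu_rest) with a ridge fallback
# (epsilon on the diagonal) when S is singular; intercept puts the boundary
# at the midpoint of the class means (equal priors).
lda_from_moments <- function(mo, ridge = 1e-8) {
  delta <- mo$mu_stress - mo$mu_rest
  w <- tryCatch(solve(mo$S, delta), error = function(e) {
    warning("singular pooled covariance; applying ridge ", ridge,
            " on the diagonal", call. = FALSE)
    solve(mo$S + diag(ridge, nrow(mo$S)), delta)
  })
  b <- -sum(w * (mo$mu_stress + mo$mu_rest) / 2)
  list(weights = w, intercept = b)
}

#' Train a linear discriminant stress rule
#'
#' Two-class LDA with equal priors: weights are the Fisher direction
#' `S^-1 (mu_stress - mu_rest)` with `S` the pooled within-class covariance,
#' and the intercept places the decision boundary at the midpoint of the
#' class means. A singular covariance (e.g. a duplicated feature) triggers a
#' ridge fallback (1e-8 on the diagonal) with a warning.
#'
#' @param features `data.frame` of records (one per row) containing the
#'   feature columns and a `session` column, or a numeric matrix plus
#'   `labels`.
#' @param subset Character vector of feature names to use (defaults to all
#'   of [hrv_feature_names()] present).
#' @param labels Character vector `"rest"`/`"stress"` (required when
#'   `features` is a matrix; defaults to `features$session`).
#' @return Object of class `linear_rule`: list with `feature_names`,
#'   `weights`, `intercept`. The rule reads: stress if
#'   `intercept + sum(weights * x) > 0`.
#' @export
train_lda <- function(features, subset = NULL, labels = NULL) {
  if (is.data.frame(features)) {
    if (is.null(labels)) labels <- features$session
    if (is.null(subset))
      subset <- intersect(hrv_feature_names(), names(features))
    X <- as.matrix(features[, subset, drop = FALSE])
  } else {
    X <- as.matrix(features)
    if (is.null(subset)) subset <- colnames(X)
    if (is.null(subset)) subset <- paste0("x", seq_len(ncol(X)))
    colnames(X) <- subset
    X <- X[, subset, drop = FALSE]
  }
  if (length(subset) == 0L) stop_validation("subset must be non-empty")
  if (is.null(labels)) stop_validation("labels are required")
  fit <- lda_from_moments(lda_moments(X, labels))
  structure(list(feature_names = subset,
                 weights = stats::setNames(as.numeric(fit$weights), subset),
                 intercept = fit$intercept),
            class = "linear_rule")
}

#' Decision scores of a linear rule
#'
#' @param rule A `linear_rule`.
#' @param newdata `data.frame`, matrix, or single named vector supplying
#'   every feature named in the rule.
#' @return Numeric vector of scores (`> 0` means stress).
#' @export
rule_scores <- function(rule, newdata) {
  stopifnot(inherits(rule, "linear_rule"))
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  missing_f <- setdiff(rule$feature_names, colnames(newdata))
  if (length(missing_f))
    stop_validation("missing feature(s): ", paste(missing_f, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[, rule$feature_names, drop = FALSE])
  as.numeric(X %*% rule$weights) + rule$intercept
}

#' Predict rest/stress labels from a linear rule
#'
#' @param object A `linear_rule`.
#' @param newdata Records to classify (see [rule_scores()]).
#' @param ... Unused.
#' @return Character vector `"rest"`/`"stress"`; a score of exactly 0
#'   classifies as rest (strict `> 0` for stress).
#' @export
predict.linear_rule <- function(object, newdata, ...) {
  ifelse(rule_scores(object, newdata) > 0, "stress", "rest")
}

#' @export
print.linear_rule <- function(x, ...) {
  cat("Linear rule: classified as stress if\n  ", rule_text(x), "\n")
  invisible(x)
}

#' Human-readable form of a linear rule
#'
#' Multi-feature rules print in the `intercept + sum(w * x) > 0` form; a
#' single-feature rule is reduced to a scalar threshold with its direction
#' (`"feature < t"` when the stress-class side is below the boundary).
#'
#' @param rule A `linear_rule`.
#' @param digits Significant digits (default 6).
#' @return A character string.
#' @export
rule_text <- function(rule, digits = 6) {
  stopifnot(inherits(rule, "linear_rule"))
  if (length(rule$feature_names) == 1L && rule$weights[[1]] != 0) {
    thr <- -rule$intercept / rule$weights[[1]]
    dir <- if (rule$weights[[1]] > 0) ">" else "<"
    return(sprintf("%s %s %s", rule$feature_names, dir, format(thr, digits = digits)))
  }
  terms <- paste(sprintf("%s*%s", format(rule$weights, digits = digits),
                         rule$feature_names), collapse = " + ")
  sprintf("%s + %s > 0", format(rule$intercept, digits = digits), terms)
}

#' Binary classification performance measures
#'
#' Accuracy, sensitivity, specificity, positive and negative predictive
#' value, with `"stress"` as the positive class. PPV (no predicted
#' positives) or NPV (no predicted negatives) that are undefined are
#' reported as `NA` with the `"undefined"` attribute listing them — never
#' silently 0.
#'
#' @param truth,predictions Character vectors `"rest"`/`"stress"`, equal
#'   length >= 1.
#' @return Named numeric vector `ACC, SEN, SPE, PPV, NPV` with attribute
#'   `"counts"` (TP, TN, FP, FN) and `"undefined"`.
#' @export
classification_performance <- function(truth, predictions) {
  if (length(truth) != length(predictions))
    stop_validation("truth and predictions must have equal length")
  if (length(truth) == 0L) stop_validation("need at least one record")
  tp <- sum(truth == "stress" & predictions == "stress")
  tn <- sum(truth == "rest" & predictions == "rest")
  fp <- sum(truth == "rest" & predictions == "stress")
  fn <- sum(truth == "stress" & predictions == "rest")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(ACC = (tp + tn) / length(truth),
           SEN = safe(tp, tp + fn), SPE = safe(tn, tn + fp),
           PPV = safe(tp, tp + fp), NPV = safe(tn, tn + fn))
  attr(out, "counts") <- c(TP = tp, TN = tn, FP = fp, FN = fn)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Subject-wise fold assignment
#'
#' Randomly partitions subjects (not records) into `k` folds whose sizes
#' differ by at most one, so both records of a subject always share a fold
#' (person-independent testing). Deterministic for a fixed seed.
#'
#' @param subjects Character vector of unique subject ids, or a paired
#'   feature `data.frame` with a `subject_id` column.
#' @param k Number of folds (default 10); must not exceed the number of
#'   subjects.
#' @param seed Integer seed.
#' @return Named integer vector: fold index (1..k) per subject, with
#'   attributes `"k"` and `"seed"`.
#' @export
make_subject_folds <- function(subjects, k = 10L, seed = 1L) {
  if (is.data.frame(subjects)) subjects <- unique(subjects$subject_id)
  subjects <- as.character(subjects)
  n <- length(subjects)
  k <- as.integer(k)
  if (k < 2L) stop_validation("k must be at least 2")
  if (k > n) stop_validation("k = ", k, " exceeds the number of subjects (", n, ")")
  perm <- with_seed(seed, sample(subjects))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- rep(seq_len(k), times = sizes)
  out <- stats::setNames(integer(n), subjects)
  out[perm] <- fold
  attr(out, "k") <- k
  attr(out, "seed") <- as.integer(seed)
  out
}

# Per-fold training moments on the full feature matrix; subset fits reuse
# the relevant sub-blocks, so the exhaustive search costs O(p^3) per
# subset-fold instead of a data pass.
fold_moments <- function(X, y, record_fold, k) {
  lapply(seq_len(k), function(f) lda_moments(X[record_fold != f, , drop = FALSE],
                                             y[record_fold != f]))
}

cv_from_moments <- function(X, y, record_fold, k, subset_idx, moments) {
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    mo <- moments[[f]]
    mo_sub <- list(mu_rest = mo$mu_rest[subset_idx],
                   mu_stress = mo$mu_stress[subset_idx],
                   S = mo$S[subset_idx, subset_idx, drop = FALSE])
    fit <- lda_from_moments(mo_sub)
    test <- which(record_fold == f)
    scores <- as.numeric(X[test, subset_idx, drop = FALSE] %*% fit$weights) +
      fit$intercept
    pred <- ifelse(scores > 0, "stress", "rest")
    per_fold[[f]] <- classification_performance(y[test], pred)
  }
  per_fold
}

summarise_folds <- function(per_fold) {
  M <- do.call(rbind, per_fold)
  avg <- colMeans(M, na.rm = TRUE)   # undefined PPV/NPV folds excluded
  excl <- colSums(is.na(M))
  list(averages = avg, excluded_folds = excl, fold_metrics = M)
}

#' Subject-wise cross-validation of an LDA feature subset
#'
#' For each fold: train on the remaining folds, predict the held-out
#' records, compute the binary performance measures; report per-fold metrics
#' and their unweighted means. Folds in which PPV or NPV is undefined are
#' excluded from that metric's average, with the exclusion count reported.
#'
#' @param features Paired feature `data.frame` (columns `subject_id`,
#'   `session`, features).
#' @param subset Non-empty character vector of feature names.
#' @param folds Fold assignment from [make_subject_folds()].
#' @return Object of class `cv_report`: list with `subset`, `folds`
#'   (per-fold data frame of counts and metrics), `averages`,
#'   `excluded_folds`, `k`, `seed`.
#' @export
cross_validate <- function(features, subset, folds) {
  if (length(subset) == 0L) stop_validation("subset must be non-empty")
  check_paired(features)
  k <- attr(folds, "k")
  y <- features$session
  X <- as.matrix(features[, subset, drop = FALSE])
  record_fold <- unname(folds[features$subject_id])
  if (anyNA(record_fold)) stop_validation("folds do not cover every subject")
  per_fold <- vector("list", k)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    train <- which(record_fold != f)
    test <- which(record_fold == f)
    rule <- train_lda(as.data.frame(X[train, , drop = FALSE]),
                      subset = subset, labels = y[train])
    pred <- predict(rule, as.data.frame(X[test, , drop = FALSE]))
    perf <- classification_performance(y[test], pred)
    per_fold[[f]] <- perf
    fold_rows[[f]] <- data.frame(fold = f, t(attr(perf, "counts")), t(unclass(perf)))
  }
  s <- summarise_folds(per_fold)
  structure(list(subset = subset,
                 folds = do.call(rbind, fold_rows),
                 averages = s$averages,
                 excluded_folds = s$excluded_folds,
                 k = k, seed = attr(folds, "seed")),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold subject-wise CV of {%s}:\n", x$k,
              paste(x$subset, collapse = ", ")))
  print(round(x$averages, 4))
  if (any(x$excluded_folds > 0))
    cat("folds excluded from averages (undefined metric):",
        paste(sprintf("%s=%d", names(x$excluded_folds)[x$excluded_folds > 0],
                      x$excluded_folds[x$excluded_folds > 0]), collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate all feature subsets
#'
#' All `2^p` subsets of `feature_names` (including the empty subset, which is
#' enumerated but carries no classifier).
#'
#' @param feature_names Character vector (default the 13 features).
#' @return List of character vectors, length `2^p`; element 1 is the empty
#'   subset.
#' @export
enumerate_subsets <- function(feature_names = hrv_feature_names()) {
  p <- length(feature_names)
  lapply(seq_len(2^p) - 1L, function(mask)
    feature_names[bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L])
}

#' Exhaustive feature-subset search
#'
#' Cross-validates every non-empty subset of the features under one shared
#' fold assignment (so rankings are comparable) and ranks by averaged ACC;
#' ties break toward fewer features, then higher averaged SEN, then
#' lexicographic subset order.
#'
#' @param features Paired feature `data.frame`.
#' @param folds Fold assignment from [make_subject_folds()].
#' @param feature_names Features to search over (default all 13).
#' @return `data.frame`, one row per evaluated subset, ranked; columns
#'   `rank`, `subset` (comma-separated), `size`, `ACC`, `SEN`, `SPE`, `PPV`,
#'   `NPV`. Attributes: `"n_enumerated"` (includes the empty subset),
#'   `"n_evaluated"`.
#' @export
exhaustive_search <- function(features, folds, feature_names = hrv_feature_names()) {
  check_paired(features)
  k <- attr(folds, "k")
  y <- features$session
  X <- as.matrix(features[, feature_names, drop = FALSE])
  record_fold <- unname(folds[features$subject_id])
  moments <- fold_moments(X, y, record_fold, k)
  subsets <- enumerate_subsets(feature_names)
  eval_idx <- which(lengths(subsets) > 0L)
  rows <- vector("list", length(eval_idx))
  for (i in seq_along(eval_idx)) {
    sub <- subsets[[eval_idx[i]]]
    subset_idx <- match(sub, feature_names)
    s <- summarise_folds(cv_from_moments(X, y, record_fold, k, subset_idx, moments))
    rows[[i]] <- data.frame(subset = paste(sub, collapse = ","),
                            size = length(sub), t(s$averages),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$ACC, out$size, -out$SEN, out$subset)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "n_enumerated") <- length(subsets)
  attr(out, "n_evaluated") <- length(eval_idx)
  out
}

#' Final classification rule on the full dataset
#'
#' Refits the LDA on all records (the cross-validation only estimates
#' performance; the reported rule uses the whole cohort). Single-feature
#' rules are additionally reduced to a scalar threshold with direction.
#'
#' @param features Paired feature `data.frame`.
#' @param subset Non-empty character vector of feature names.
#' @return A `linear_rule` with extra fields `text` (human-readable rule)
#'   and, for single features, `threshold` and `direction`.
#' @export
final_rule <- function(features, subset) {
  if (length(subset) == 0L) stop_validation("subset must be non-empty")
  check_paired(features)
  rule <- train_lda(features, subset = subset)
  rule$text <- rule_text(rule)
  if (length(subset) == 1L && rule$weights[[1]] != 0) {
    rule$threshold <- -rule$intercept / rule$weights[[1]]
    rule$direction <- if (rule$weights[[1]] > 0) ">" else "<"
  }
  rule
}
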