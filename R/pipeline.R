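# End-to-end study pipeline: cohort -> features -> paired statistics ->
# classification tables, with full provenance of every setting used.

#' Study configuration
#'
#' @param input Either a directory of RR records (see [read_cohort()]) or a
#'   [synthetic_params()] object.
#' @param reliability_threshold NN/RR reliability threshold (default 0.90).
#' @param rp_radius_mode Recurrence radius convention (default `"sqrt_m"`).
#' @param chon_mode Chon tolerance application (default `"sdnn_scaled"`).
#' @param k Cross-validation folds (default 10).
#' @param cv_seed Seed of the shared fold assignment (default 17).
#' @param search `"exhaustive"` (default) to rank every feature subset, or
#'   `"single"` to evaluate only the 13 single-feature rules (plus the best
#'   of them); `"none"` skips classification.
#' @param skip_invalid Drop records failing validation instead of aborting.
#' @param out_dir Optional directory: when given, [run_study()] writes the
#'   CSV tables, rule JSON, and a plain-text run log there.
#' @return Object of class `study_config`.
#' @export
study_config <- function(input, reliability_threshold = 0.90,
                         rp_radius_mode = c("sqrt_m", "literal"),
                         chon_mode = c("sdnn_scaled", "literal"),
                         k = 10L, cv_seed = 17L,
                         search = c("exhaustive", "single", "none"),
                         skip_invalid = FALSE, out_dir = NULL) {
  structure(list(input = input,
                 reliability_threshold = reliability_threshold,
                 rp_radius_mode = match.arg(rp_radius_mode),
                 chon_mode = match.arg(chon_mode),
                 k = as.integer(k), cv_seed = as.integer(cv_seed),
                 search = match.arg(search),
                 skip_invalid = isTRUE(skip_invalid), out_dir = out_dir),
            class = "study_config")
}

#' Run the full stress-detection study
#'
#' Ingests (or synthesises) a paired cohort, applies the NN filter and
#' reliability criterion, extracts the 13 nonlinear features per record, and
#' produces: per-session descriptives, paired stress-minus-rest differences
#' with signed-rank p-values, single-feature classification rules, and (for
#' `search = "exhaustive"`) the best subset-wise cross-validated rule.
#' Statistics and classification are computed from the same feature table
#' (no recomputation drift). Deterministic for a fixed configuration.
#'
#' @param config A [study_config()].
#' @return Object of class `study_report`: list with `features`,
#'   `descriptives`, `differences`, `classification` (single-feature table +
#'   best subset + rules), `config`, `log` (character vector of every
#'   resolved setting).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  log <- c(sprintf("hrvstress run: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("reliability_threshold = %.2f", config$reliability_threshold),
           sprintf("rp_radius_mode = %s", config$rp_radius_mode),
           sprintf("chon_mode = %s", config$chon_mode),
           sprintf("cv: k = %d, seed = %d", config$k, config$cv_seed),
           sprintf("search = %s", config$search),
           "conventions: population SD; ApEn d <= r; RP d < r; ShEn negated; l_min = 2; LOI excluded from lines; equal LDA priors")

  records <- if (inherits(config$input, "synthetic_params")) {
    log <- c(log, sprintf("input: synthetic cohort (n_subjects = %d, seed = %d)",
                          config$input$n_subjects, config$input$seed))
    generate_cohort(config$input)
  } else {
    log <- c(log, sprintf("input: directory %s", config$input))
    read_cohort(config$input)
  }

  extract_one <- function(rr) {
    tryCatch({
      nn <- to_nn(rr)
      if (!reliability_check(nn, config$reliability_threshold))
        return(sprintf("excluded %s/%s: NN/RR = %.3f below threshold",
                       rr$subject_id, rr$session, nn$nn_rr_ratio))
      fv <- extract_all_features(nn, rp_radius_mode = config$rp_radius_mode,
                                 chon_mode = config$chon_mode)
      cbind(data.frame(subject_id = rr$subject_id, session = rr$session,
                       nn_rr_ratio = nn$nn_rr_ratio, stringsAsFactors = FALSE),
            as.data.frame(as.list(fv)))
    }, error = function(e) sprintf("invalid %s/%s: %s", rr$subject_id,
                                   rr$session, conditionMessage(e)))
  }
  rows <- lapply(records, extract_one)
  bad <- vapply(rows, is.character, logical(1))
  if (any(bad)) {
    msgs <- unlist(rows[bad])
    log <- c(log, msgs)
    if (!config$skip_invalid)
      stop_validation("record(s) failed validation:\n  ",
                      paste(msgs, collapse = "\n  "))
  }
  features <- do.call(rbind, rows[!bad])
  if (is.null(features) || nrow(features) == 0L)
    stop_validation("empty cohort after reliability filtering")
  rownames(features) <- NULL

  # drop incomplete subject pairs only under skip_invalid; otherwise fatal
  tab <- table(features$subject_id)
  partial <- names(tab)[tab != 2L]
  if (length(partial)) {
    if (!config$skip_invalid)
      stop_validation("partial subject pairs: ", paste(partial, collapse = ", "))
    log <- c(log, sprintf("dropped partial subject(s): %s",
                          paste(partial, collapse = ", ")))
    features <- features[!features$subject_id %in% partial, , drop = FALSE]
  }
  check_paired(features)
  n_sub <- length(unique(features$subject_id))
  log <- c(log, sprintf("%d records / %d subjects analysed", nrow(features), n_sub))
  if (config$k > n_sub)
    stop_validation("k = ", config$k, " folds exceed the ", n_sub, " subjects")

  descriptives <- session_summary_table(features)
  differences <- difference_table(features)

  classification <- NULL
  if (config$search != "none") {
    folds <- make_subject_folds(features, k = config$k, seed = config$cv_seed)
    singles <- lapply(hrv_feature_names(), function(f) {
      cv <- cross_validate(features, f, folds)
      rule <- final_rule(features, f)
      data.frame(subset = f, size = 1L, t(cv$averages),
                 rule = rule$text, stringsAsFactors = FALSE)
    })
    single_table <- do.call(rbind, singles)
    single_table <- single_table[order(-single_table$ACC), , drop = FALSE]
    rownames(single_table) <- NULL

    if (config$search == "exhaustive") {
      ranking <- exhaustive_search(features, folds)
      best_subset <- strsplit(ranking$subset[[1]], ",", fixed = TRUE)[[1]]
      log <- c(log, sprintf("exhaustive search: %d subsets enumerated, %d evaluated",
                            attr(ranking, "n_enumerated"), attr(ranking, "n_evaluated")))
    } else {
      ranking <- NULL
      best_subset <- single_table$subset[[1]]
    }
    best_cv <- cross_validate(features, best_subset, folds)
    best_rule <- final_rule(features, best_subset)
    log <- c(log, sprintf("best subset {%s}: averaged ACC = %.3f",
                          paste(best_subset, collapse = ", "),
                          best_cv$averages[["ACC"]]))
    classification <- list(single_features = single_table, ranking = ranking,
                           best_subset = best_subset, best_cv = best_cv,
                           best_rule = best_rule, folds = folds)
  }

  report <- structure(list(features = features, descriptives = descriptives,
                           differences = differences,
                           classification = classification,
                           config = config, log = log),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' Write a study report bundle to disk
#'
#' CSV tables (`features.csv`, `descriptives.csv`, `differences.csv`,
#' `single_features.csv`, `ranking.csv`), `best_rule.json`, and `run.log`.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  wcsv(report$features, "features.csv")
  wcsv(report$descriptives, "descriptives.csv")
  wcsv(report$differences, "differences.csv")
  cls <- report$classification
  if (!is.null(cls)) {
    wcsv(cls$single_features, "single_features.csv")
    if (!is.null(cls$ranking)) wcsv(cls$ranking, "ranking.csv")
    rule <- cls$best_rule
    jsonlite::write_json(
      list(subset = rule$feature_names,
           weights = as.list(rule$weights), intercept = rule$intercept,
           text = rule$text,
           cv_averages = as.list(cls$best_cv$averages)),
      file.path(dir, "best_rule.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d records, %d subjects\n", nrow(x$features),
              length(unique(x$features$subject_id))))
  cat("\nPaired differences (stress - rest):\n")
  print(cbind(x$differences[, c("feature", "median")],
              p = x$differences$p_display), row.names = FALSE)
  if (!is.null(x$classification)) {
    cat(sprintf("\nBest subset {%s}:\n",
                paste(x$classification$best_subset, collapse = ", ")))
    print(round(x$classification$best_cv$averages, 3))
    cat("Rule: stress if", x$classification$best_rule$text, "\n")
  }
  invisible(x)
}
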