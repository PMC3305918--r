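# RR-interval input, the normal-beat (NN) filter, and the NN/RR reliability
# criterion. All downstream features operate on the NN series in seconds.

#' Construct an RR-interval series
#'
#' An `rr_series` holds one session's beat-to-beat intervals (seconds) with a
#' per-beat annotation. Any label other than `"N"` (case-insensitive; `"normal"`
#' is also accepted) marks a non-normal beat.
#'
#' @param intervals Numeric vector of beat-to-beat durations in seconds,
#'   strictly positive, length >= 2.
#' @param labels Character vector of per-beat annotations, recycled `"N"` if
#'   `NULL`.
#' @param subject_id Opaque subject identifier.
#' @param session `"rest"`, `"stress"`, or `NA`.
#' @return An object of class `rr_series`.
#' @examples
#' rr <- rr_series(c(0.80, 0.82, 0.45), labels = c("N", "N", "V"))
#' to_nn(rr_series(rep(0.8, 10)))
#' @export
rr_series <- function(intervals, labels = NULL, subject_id = NA_character_,
                      session = NA_character_) {
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2L)
    stop_validation("an RR series needs at least 2 intervals")
  if (anyNA(intervals) || any(intervals <= 0))
    stop_validation("RR intervals must be strictly positive and non-missing")
  if (is.null(labels)) labels <- rep("N", length(intervals))
  labels <- as.character(labels)
  if (length(labels) != length(intervals))
    stop_validation("labels and intervals must have equal length")
  if (!is.na(session) && !session %in% c("rest", "stress"))
    stop_validation("session must be 'rest', 'stress' or NA")
  structure(
    list(intervals = intervals, labels = labels,
         subject_id = subject_id, session = session),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series: %d beats (%.1f s), %d non-normal, subject=%s session=%s\n",
              length(x$intervals), sum(x$intervals),
              sum(!is_normal_label(x$labels)),
              as.character(x$subject_id), as.character(x$session)))
  invisible(x)
}

is_normal_label <- function(labels) toupper(labels) %in% c("N", "NORMAL")

#' Read an RR-interval record from a text file
#'
#' Two formats are supported: a two-column CSV `interval,label` and a
#' single-column text file with one interval per line (labels default to
#' normal). Input order is preserved.
#'
#' @param path Path to the file.
#' @param format `"auto"` (default; sniff for a comma), `"two-column-csv"` or
#'   `"single-column-text"`.
#' @param unit `"s"` (default) or `"ms"`; milliseconds are divided by 1000 on
#'   input. The internal unit is always seconds.
#' @param subject_id,session Passed to [rr_series()].
#' @return An `rr_series`.
#' @export
read_rr <- function(path, format = c("auto", "two-column-csv", "single-column-text"),
                    unit = c("s", "ms"),
                    subject_id = NA_character_, session = NA_character_) {
  format <- match.arg(format)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop_validation("no data lines in ", path)
  if (format == "auto")
    format <- if (grepl(",", lines[[1L]], fixed = TRUE)) "two-column-csv" else "single-column-text"

  if (format == "two-column-csv") {
    parts <- strsplit(lines, ",", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
      stop_validation("malformed line ", lineno[bad[1L]], " in ", path,
                      ": expected 'interval,label'")
    vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
    labels <- trimws(vapply(parts, `[[`, "", 2L))
  } else {
    vals <- suppressWarnings(as.numeric(lines))
    labels <- NULL
  }
  bad <- which(is.na(vals))
  if (length(bad))
    stop_validation("malformed line ", lineno[bad[1L]], " in ", path,
                    ": not a number")
  bad <- which(vals <= 0)
  if (length(bad))
    stop_validation("non-positive duration on line ", lineno[bad[1L]], " in ", path)
  if (unit == "ms") vals <- vals / 1000
  rr_series(vals, labels, subject_id = subject_id, session = session)
}

#' Write an RR-interval record
#'
#' Writes the two-column CSV format of [read_rr()] (or single-column when the
#' series carries no non-normal beats and `format = "single-column-text"`).
#' Numbers are printed with 17 significant digits so a read/write/read
#' round-trip is bit-identical.
#'
#' @param rr An `rr_series`.
#' @param path Output path.
#' @param format Output format, as in [read_rr()].
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path, format = c("two-column-csv", "single-column-text")) {
  format <- match.arg(format)
  stopifnot(inherits(rr, "rr_series"))
  num <- formatC(rr$intervals, format = "g", digits = 17)
  lines <- if (format == "two-column-csv") paste0(num, ",", rr$labels) else num
  writeLines(lines, path)
  invisible(path)
}

#' Filter an RR series to its normal-to-normal (NN) intervals
#'
#' Non-normal beats are removed (not interpolated); the NN/RR ratio — the
#' fraction of intervals labelled normal — is retained as the record's
#' reliability measure.
#'
#' @param rr An `rr_series`.
#' @return An object of class `nn_series` with fields `intervals`,
#'   `nn_rr_ratio`, `subject_id`, `session`.
#' @export
to_nn <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  normal <- is_normal_label(rr$labels)
  ratio <- mean(normal)
  ints <- rr$intervals[normal]
  if (length(ints) < 2L)
    stop_validation("degenerate series: fewer than 2 normal intervals after filtering")
  structure(
    list(intervals = ints, nn_rr_ratio = ratio,
         subject_id = rr$subject_id, session = rr$session),
    class = "nn_series"
  )
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("NN series: %d intervals, NN/RR = %.3f, subject=%s session=%s\n",
              length(x$intervals), x$nn_rr_ratio,
              as.character(x$subject_id), as.character(x$session)))
  invisible(x)
}

#' NN/RR reliability criterion
#'
#' A record is reliable when the fraction of intervals labelled normal is at
#' least `threshold`; records with a ratio *less than* the threshold are to be
#' excluded, so a ratio exactly at the boundary is kept.
#'
#' @param nn An `nn_series`.
#' @param threshold Fraction in \[0, 1\] (default 0.90).
#' @return `TRUE` if the record passes.
#' @export
reliability_check <- function(nn, threshold = 0.90) {
  stopifnot(inherits(nn, "nn_series"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop_validation("threshold must be a single value in [0, 1]")
  nn$nn_rr_ratio >= threshold
}

# Accept either an nn_series or a bare numeric vector in feature functions;
# keeps oracles and property tests free of wrapper boilerplate.
nn_intervals <- function(nn) {
  if (inherits(nn, "nn_series")) return(nn$intervals)
  if (inherits(nn, "rr_series"))
    stop_validation("pass an nn_series (use to_nn()) or a numeric vector, not an rr_series")
  as.numeric(nn)
}
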