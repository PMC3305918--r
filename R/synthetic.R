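# Synthetic paired rest/stress RR cohorts.
#
# One 5-minute record is modelled as
#   RR_i = mean_rr + A_LF sin(2 pi 0.1 t_i + phi1)
#                  + A_HF sin(2 pi f_resp t_i + phi2) + z_i,
# with z an AR(1) process (per-session coefficient and innovation sd) and
# t_i the cumulative time of beat i; beats are appended until the cumulative
# time reaches the requested duration. Stress sessions have a shorter mean
# RR, a much smaller LF amplitude (less long-term spread => lower SD2), a
# higher AR coefficient and smaller innovations (more regular => lower
# entropy/complexity, more recurrence). Each beat is independently marked
# non-normal with probability ectopic_rate and perturbed by +/-30%.
# Per-subject phases and multiplicative amplitude jitter are shared between
# a subject's two sessions, so within-subject pairing is real.

#' Parameters of the synthetic paired-cohort generator
#'
#' Defaults emulate 5-minute paired recordings of a young adult cohort:
#' rest mean RR 0.85 s (~71 bpm) vs stress 0.70 s (~86 bpm); LF (0.1 Hz)
#' amplitude 0.04 s at rest vs 0.015 s under stress; respiratory (0.25 Hz)
#' amplitude 0.02 s; AR(1) coefficient 0.3 (rest) vs 0.8 (stress) with
#' innovation sd 0.02 vs 0.008 s; 1% ectopic beats; 15% multiplicative
#' between-subject jitter on all amplitudes.
#'
#' @param n_subjects Number of subjects (default 42).
#' @param duration Record length in seconds (default 300, a 5-minute window).
#' @param rest_mean_rr,stress_mean_rr Mean RR per session (seconds).
#' @param lf_amplitude_rest,lf_amplitude_stress 0.1 Hz oscillation amplitude
#'   (seconds), the long-term-spread (SD2) control.
#' @param hf_amplitude Respiratory oscillation amplitude (seconds).
#' @param respiratory_freq Respiratory frequency (Hz).
#' @param ar_coeff_rest,ar_coeff_stress AR(1) coefficient in \[0, 1); higher
#'   is more regular.
#' @param noise_sd_rest,noise_sd_stress AR(1) innovation sd (seconds).
#' @param ectopic_rate Per-beat probability of a non-normal beat, in
#'   \[0, 0.1\].
#' @param between_subject_sd Log-sd of the subject-level multiplicative
#'   jitter applied to all amplitudes (default 0.15).
#' @param seed Master integer seed; per-subject, per-session substreams are
#'   derived from it by counter-based splitting, so adding subjects never
#'   perturbs existing ones.
#' @return Object of class `synthetic_params` (validated list).
#' @export
synthetic_params <- function(n_subjects = 42L, duration = 300,
                             rest_mean_rr = 0.85, stress_mean_rr = 0.70,
                             lf_amplitude_rest = 0.04, lf_amplitude_stress = 0.015,
                             hf_amplitude = 0.02, respiratory_freq = 0.25,
                             ar_coeff_rest = 0.3, ar_coeff_stress = 0.8,
                             noise_sd_rest = 0.02, noise_sd_stress = 0.008,
                             ectopic_rate = 0.01, between_subject_sd = 0.15,
                             seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects), duration = duration,
            rest_mean_rr = rest_mean_rr, stress_mean_rr = stress_mean_rr,
            lf_amplitude_rest = lf_amplitude_rest,
            lf_amplitude_stress = lf_amplitude_stress,
            hf_amplitude = hf_amplitude, respiratory_freq = respiratory_freq,
            ar_coeff_rest = ar_coeff_rest, ar_coeff_stress = ar_coeff_stress,
            noise_sd_rest = noise_sd_rest, noise_sd_stress = noise_sd_stress,
            ectopic_rate = ectopic_rate, between_subject_sd = between_subject_sd,
            seed = as.integer(seed))
  with(p, {
    if (n_subjects < 1L) stop_validation("n_subjects must be >= 1")
    if (duration <= 0) stop_validation("duration must be positive")
    if (rest_mean_rr <= 0 || stress_mean_rr <= 0)
      stop_validation("mean RR values must be positive")
    amps <- c(lf_amplitude_rest, lf_amplitude_stress, hf_amplitude,
              noise_sd_rest, noise_sd_stress, between_subject_sd)
    if (any(amps < 0)) stop_validation("amplitudes and sds must be >= 0")
    if (ar_coeff_rest < 0 || ar_coeff_rest >= 1 ||
        ar_coeff_stress < 0 || ar_coeff_stress >= 1)
      stop_validation("AR coefficients must lie in [0, 1)")
    if (ectopic_rate < 0 || ectopic_rate > 0.1)
      stop_validation("ectopic_rate must lie in [0, 0.1]")
    if (respiratory_freq <= 0) stop_validation("respiratory_freq must be positive")
  })
  structure(p, class = "synthetic_params")
}

# Subject-level draws (shared by both sessions): two phases and one
# multiplicative jitter factor per amplitude-like parameter.
subject_draws <- function(params, subject_index) {
  with_seed(substream_seed(params$seed, subject_index, 0L), {
    list(phi1 = stats::runif(1, 0, 2 * pi),
         phi2 = stats::runif(1, 0, 2 * pi),
         jitter = exp(stats::rnorm(3, 0, params$between_subject_sd)))
  })
}

#' Generate one synthetic RR session
#'
#' Fully deterministic given `(params$seed, subject_index, session)`;
#' see [synthetic_params()] for the signal model.
#'
#' @param params A `synthetic_params` object.
#' @param subject_index Zero-based subject counter.
#' @param session `"rest"` or `"stress"`.
#' @return An [rr_series()] with subject id `"S<index>"`.
#' @export
generate_session <- function(params, subject_index, session = c("rest", "stress")) {
  stopifnot(inherits(params, "synthetic_params"))
  session <- match.arg(session)
  sd_draws <- subject_draws(params, subject_index)
  mean_rr <- if (session == "rest") params$rest_mean_rr else params$stress_mean_rr
  a_lf <- sd_draws$jitter[[1]] *
    (if (session == "rest") params$lf_amplitude_rest else params$lf_amplitude_stress)
  a_hf <- sd_draws$jitter[[2]] * params$hf_amplitude
  phi <- if (session == "rest") params$ar_coeff_rest else params$ar_coeff_stress
  innov_sd <- sd_draws$jitter[[3]] *
    (if (session == "rest") params$noise_sd_rest else params$noise_sd_stress)

  sess_code <- if (session == "rest") 1L else 2L
  with_seed(substream_seed(params$seed, subject_index, sess_code), {
    n_guess <- ceiling(params$duration / mean_rr) + 64L
    intervals <- numeric(0)
    labels <- character(0)
    t <- 0
    z <- stats::rnorm(1, 0, if (phi < 1) innov_sd / sqrt(1 - phi^2) else innov_sd)
    while (t < params$duration) {
      rr <- mean_rr +
        a_lf * sin(2 * pi * 0.1 * t + sd_draws$phi1) +
        a_hf * sin(2 * pi * params$respiratory_freq * t + sd_draws$phi2) +
        z
      lab <- "N"
      if (params$ectopic_rate > 0 && stats::runif(1) < params$ectopic_rate) {
        lab <- "V"
        rr <- rr * (1 + 0.3 * sample(c(-1, 1), 1))
      }
      rr <- max(rr, 0.05)  # positivity guard; never binds at default scales
      intervals <- c(intervals, rr)
      labels <- c(labels, lab)
      t <- t + rr
      z <- phi * z + stats::rnorm(1, 0, innov_sd)
    }
    rr_series(intervals, labels,
              subject_id = sprintf("S%02d", subject_index), session = session)
  })
}

#' Generate a paired synthetic cohort
#'
#' One rest and one stress record per subject; the two sessions share the
#' subject's phases and amplitude jitter, so within-subject pairing is real
#' (as the signed-rank design assumes).
#'
#' @param params A `synthetic_params` object.
#' @return List of `2 * n_subjects` [rr_series()] (rest then stress per
#'   subject), with attribute `"params"`.
#' @examples
#' cohort <- generate_cohort(synthetic_params(n_subjects = 3, seed = 1))
#' length(cohort)
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  records <- vector("list", 2L * params$n_subjects)
  for (i in seq_len(params$n_subjects)) {
    records[[2L * i - 1L]] <- generate_session(params, i - 1L, "rest")
    records[[2L * i]] <- generate_session(params, i - 1L, "stress")
  }
  attr(records, "params") <- params
  records
}

#' Write a synthetic cohort to per-record CSV files
#'
#' One `two-column-csv` file per record (readable by [read_rr()]) plus a
#' `manifest.json` with the generator parameters and file/subject/session
#' table.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(cohort, function(rr) {
    f <- sprintf("%s_%s.csv", rr$subject_id, rr$session)
    write_rr(rr, file.path(dir, f))
    f
  }, character(1))
  manifest <- list(
    params = unclass(attr(cohort, "params")),
    records = data.frame(
      file = files,
      subject_id = vapply(cohort, `[[`, "", "subject_id"),
      session = vapply(cohort, `[[`, "", "session"),
      n_beats = vapply(cohort, function(r) length(r$intervals), numeric(1))
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing per-record CSVs and `manifest.json` (or,
#'   without a manifest, files named `<subject>_<session>.csv`).
#' @return List of `rr_series`.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    recs <- manifest$records
  } else {
    files <- list.files(dir, pattern = "\\.csv$")
    if (length(files) == 0L) stop_validation("no CSV records in ", dir)
    parts <- regmatches(files, regexec("^(.*)_(rest|stress)\\.csv$", files))
    if (any(lengths(parts) != 3L))
      stop_validation("cannot infer subject/session from file names in ", dir)
    recs <- data.frame(file = files,
                       subject_id = vapply(parts, `[[`, "", 2L),
                       session = vapply(parts, `[[`, "", 3L))
  }
  lapply(seq_len(nrow(recs)), function(i)
    read_rr(file.path(dir, recs$file[[i]]),
            subject_id = recs$subject_id[[i]], session = recs$session[[i]]))
}
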