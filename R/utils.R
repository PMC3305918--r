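# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers never perturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Population (divide-by-N) standard deviation. One convention everywhere:
# SDNN feeds every tolerance threshold, so SDNN, SDDS, SD1 and SD2 must share it.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# Deterministic substream seeds: a small LCG step keeps products < 2^53 so
# double arithmetic stays exact, and the result stays below 2^31 - 1.
# Counter-based: adding subjects never perturbs existing subjects' streams.
substream_seed <- function(master, subject_index, session_code) {
  s <- (as.numeric(master) %% 2147483647)
  s <- (s * 48271) %% 2147483647
  s <- (s + subject_index * 2654435 + session_code * 40503 + 1) %% 2147483647
  s <- (s * 48271) %% 2147483647
  as.integer(s)
}

# Delay-embedding: row i is (x[i], x[i+tau], ..., x[i+(m-1)*tau]),
# i = 1, ..., N - (m-1)*tau.
embed_rows <- function(x, m, tau = 1L) {
  n <- length(x)
  K <- n - (m - 1L) * tau
  stopifnot(K >= 1L)
  idx <- outer(seq_len(K), (0:(m - 1L)) * tau, "+")
  matrix(x[idx], nrow = K, ncol = m)
}

stop_validation <- function(...) stop(..., call. = FALSE)
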