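#' Specify a synthetic self-paced reading benchmark
#'
#' Reading times are generated as an affine function of per-word surprisal
#' plus Gaussian noise, with a configurable fraction of artifact trials
#' injected outside the plausible [100, 3000] ms range (drawn uniformly from
#' [0, 100) or (3000, 5000], half on each side in expectation) so that
#' downstream range filtering is exercised on both sides.
#'
#' @param intercept_ms Baseline reading time in milliseconds.
#' @param slope_ms_per_bit Increase in reading time per bit of surprisal.
#' @param noise_sd_ms Gaussian noise standard deviation (ms), nonnegative.
#' @param outlier_fraction Probability that a word's RT is replaced by an
#'   out-of-range artifact value; in [0, 1).
#' @param n_participants Number of simulated participants.
#' @param seed Integer seed.
#' @return An object of class `behavioral_spec`.
#' @export
behavioral_spec <- function(intercept_ms = 300, slope_ms_per_bit = 20,
                            noise_sd_ms = 50, outlier_fraction = 0.05,
                            n_participants = 5L, seed = 1L) {
  assert_number(intercept_ms, "intercept_ms")
  assert_number(slope_ms_per_bit, "slope_ms_per_bit")
  assert_number(noise_sd_ms, "noise_sd_ms", min = 0)
  assert_number(outlier_fraction, "outlier_fraction", min = 0, max = 1 - 1e-12)
  assert_count(n_participants, "n_participants")
  structure(
    list(intercept_ms = intercept_ms, slope_ms_per_bit = slope_ms_per_bit,
         noise_sd_ms = noise_sd_ms, outlier_fraction = outlier_fraction,
         n_participants = as.integer(n_participants), seed = as.integer(seed)),
    class = "behavioral_spec"
  )
}

#' Generate synthetic word-level reading times from surprisal
#'
#' For every participant and word,
#' `RT = intercept + slope * surprisal + noise`; a Bernoulli
#' (`outlier_fraction`) subset of trials is then replaced by values outside
#' the [100, 3000] ms range. Generation is bit-identical under a fixed seed.
#'
#' @param spec A [behavioral_spec()].
#' @param surprisal Data frame with one row per word token and columns
#'   `story`, `sentence`, `word_index`, `word`, `surprisal` (bits); or a bare
#'   numeric vector of surprisal values (indexing columns are then
#'   synthesized as a single story/sentence).
#' @return A tibble of class `behavioral_benchmark` with columns
#'   `participant`, `story`, `sentence`, `word_index`, `word`, `word_id` (an
#'   index identifying the word occurrence across participants, usable as a
#'   row index into a word-representation matrix), `rt_ms`, plus the
#'   generating `surprisal` and a logical `outlier` ground-truth column.
#'   The `ceiling` attribute carries the benchmark noise ceiling
#'   `sqrt(var(signal) / var(RT))` computed from the generating parameters.
#' @export
generate_reading_times <- function(spec, surprisal) {
  assert_that(inherits(spec, "behavioral_spec"), "`spec` must be a behavioral_spec")
  if (is.numeric(surprisal)) {
    surprisal <- tibble::tibble(
      story = 1L, sentence = 1L,
      word_index = seq_along(surprisal),
      word = paste0("w", seq_along(surprisal)),
      surprisal = as.numeric(surprisal)
    )
  }
  assert_that(all(c("story", "sentence", "word_index", "word", "surprisal")
                  %in% names(surprisal)),
              "`surprisal` must have story/sentence/word_index/word/surprisal columns")
  assert_that(all(is.finite(surprisal$surprisal)), "surprisal values must be finite")
  surprisal$word_id <- seq_len(nrow(surprisal))

  n <- nrow(surprisal)
  out <- with_seed(spec$seed, {
    purrr::map_dfr(seq_len(spec$n_participants), function(p) {
      rt <- spec$intercept_ms + spec$slope_ms_per_bit * surprisal$surprisal +
        rnorm(n, sd = spec$noise_sd_ms)
      is_out <- runif(n) < spec$outlier_fraction
      n_out <- sum(is_out)
      if (n_out > 0) {
        low <- runif(n_out) < 0.5
        rt[is_out] <- ifelse(low, runif(n_out, 0, 100), runif(n_out, 3000, 5000))
      }
      dplyr::mutate(surprisal, participant = p, rt_ms = rt, outlier = is_out,
                    .before = 1)
    })
  })
  sig_var <- spec$slope_ms_per_bit^2 * var(surprisal$surprisal)
  ceiling <- if (sig_var + spec$noise_sd_ms^2 > 0) {
    sqrt(sig_var / (sig_var + spec$noise_sd_ms^2))
  } else 1
  structure(
    tibble::as_tibble(out),
    ceiling = ceiling,
    class = c("behavioral_benchmark", class(tibble::tibble()))
  )
}
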