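#' Filter reading times to the plausible range
#'
#' Retains records with reading times inside [100, 3000] ms (boundaries
#' inclusive; only values strictly outside the range are excluded). The
#' number of removed records is reported as a message and carried in the
#' `n_removed` attribute. Filtering is idempotent.
#'
#' @param benchmark A behavioral benchmark tibble with an `rt_ms` column.
#' @param lower,upper Range boundaries in ms.
#' @return The filtered tibble (attributes, including any `ceiling`,
#'   preserved), with attribute `n_removed`.
#' @export
filter_rts <- function(benchmark, lower = 100, upper = 3000) {
  assert_that(is.data.frame(benchmark) && "rt_ms" %in% names(benchmark),
              "`benchmark` must be a data frame with an `rt_ms` column")
  keep <- benchmark$rt_ms >= lower & benchmark$rt_ms <= upper
  out <- benchmark[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(sprintf("filter_rts: removed %d of %d records outside [%g, %g] ms",
                    n_removed, length(keep), lower, upper))
  }
  attr(out, "ceiling") <- attr(benchmark, "ceiling", exact = TRUE)
  attr(out, "n_removed") <- n_removed
  out
}

#' Constrained word-level cross-validation folds
#'
#' Assigns every word occurrence of one participant's records to one of `k`
#' folds under two constraints: repeated occurrences of the same word type
#' within a sentence always share a fold (so a word type never spans the
#' train/test boundary within a sentence), and within each sentence the
#' occurrences are spread across folds as evenly as possible. Assignment is
#' greedy — word types are placed largest-group first into the fold with the
#' smallest load within the sentence, breaking ties by global fold load and
#' then by a seeded random draw — and is deterministic under a fixed seed.
#'
#' @param records Data frame of one participant's word occurrences with
#'   columns `story`, `sentence`, `word_index`, `word`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for tie-breaking.
#' @return A `fold_spec` over the rows of `records`.
#' @export
word_folds <- function(records, k = 5L, seed = 1L) {
  assert_that(is.data.frame(records) &&
                all(c("story", "sentence", "word_index", "word") %in% names(records)),
              "`records` must have story/sentence/word_index/word columns")
  n <- nrow(records)
  assert_count(k, "k")
  assert_that(n >= k, "fewer word occurrences than folds")
  sent_id <- paste(records$story, records$sentence, sep = "\x1f")
  assignment <- integer(n)
  global_load <- numeric(k)
  with_seed(seed, {
    for (sid in unique(sent_id)) {
      rows <- which(sent_id == sid)
      types <- split(rows, records$word[rows])
      ord <- order(-vapply(types, length, integer(1)),
                   vapply(types, min, integer(1)))
      sent_load <- numeric(k)
      for (g in types[ord]) {
        key <- rank(sent_load, ties.method = "min") * k^2 +
          rank(global_load, ties.method = "min") * k +
          sample.int(k)
        f <- which.min(key)
        assignment[g] <- f
        sent_load[f] <- sent_load[f] + length(g)
        global_load[f] <- global_load[f] + length(g)
      }
    }
  })
  structure(list(n_items = n, k = as.integer(k), assignment = assignment),
            class = "fold_spec")
}

#' Reading-time predictivity from word representations
#'
#' For every participant: regresses filtered reading times on word
#' representations (from the last model layer, by convention) with
#' constrained word-level cross-validation, averages the held-out Pearson
#' correlations across folds, and divides by the benchmark ceiling.
#'
#' @param benchmark A (filtered) behavioral benchmark tibble with columns
#'   `participant`, `story`, `sentence`, `word_index`, `word`, `rt_ms`, and
#'   `word_id` (row index into `features`).
#' @param features Numeric matrix of word representations, one row per
#'   distinct word occurrence (indexed by `word_id`).
#' @param ceiling Noise ceiling; defaults to the benchmark's `ceiling`
#'   attribute.
#' @param k Number of folds.
#' @param seed Seed for fold construction.
#' @param ridge Ridge penalty forwarded to [fit_linear_map()].
#' @return An object of class `rt_predictivity`: `participant_scores`
#'   (tibble: participant, raw, normalized), `ceiling`, and `summary`.
#' @export
rt_predictivity <- function(benchmark, features, ceiling = NULL, k = 5L,
                            seed = 1L, ridge = 0) {
  assert_that(is.data.frame(benchmark) &&
                all(c("participant", "word_id", "rt_ms") %in% names(benchmark)),
              "`benchmark` must have participant/word_id/rt_ms columns")
  assert_that(is.matrix(features) && all(is.finite(features)),
              "`features` must be a finite numeric matrix")
  assert_that(all(benchmark$word_id >= 1 & benchmark$word_id <= nrow(features)),
              "`word_id` must index rows of `features`")
  ceiling <- ceiling %||% attr(benchmark, "ceiling", exact = TRUE)
  assert_that(is.numeric(ceiling) && length(ceiling) == 1 && ceiling > 0,
              "`ceiling` must be a positive number (supply it or use a benchmark carrying one)")

  rows <- purrr::map_dfr(split(benchmark, benchmark$participant), function(rec) {
    folds <- word_folds(rec, k = k, seed = seed)
    X <- features[rec$word_id, , drop = FALSE]
    y <- rec$rt_ms
    sizes <- tabulate(folds$assignment, nbins = folds$k)
    assert_that(all(sizes >= 3),
                "every test fold needs at least 3 word occurrences")
    r <- mean(vapply(seq_len(folds$k), function(f) {
      test <- folds$assignment == f
      fit <- fit_linear_map(X[!test, , drop = FALSE], y[!test], ridge = ridge)
      safe_cor(drop(predict(fit, X[test, , drop = FALSE])), y[test])
    }, numeric(1)))
    tibble::tibble(participant = rec$participant[1], raw = r,
                   normalized = r / ceiling)
  })
  structure(
    list(participant_scores = rows, ceiling = ceiling,
         summary = summarize_scores(rows$normalized)),
    class = "rt_predictivity"
  )
}

#' @export
print.rt_predictivity <- function(x, ...) {
  cat(sprintf("<rt_predictivity> %d participants, ceiling %.3f; normalized score median %.3f (MAD %.3f)\n",
              nrow(x$participant_scores), x$ceiling,
              x$summary$median, x$summary$mad))
  invisible(x)
}

#' @export
tidy.rt_predictivity <- function(x, ...) x$participant_scores

#' @export
glance.rt_predictivity <- function(x, ...) {
  tibble::tibble(median_normalized = x$summary$median,
                 mad_normalized = x$summary$mad,
                 n_participants = x$summary$n,
                 ceiling = x$ceiling)
}
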