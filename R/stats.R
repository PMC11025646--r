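#' Independent two-sample t test with optional Bonferroni correction
#'
#' Classic pooled-variance Student's t by default (Welch available via
#' `var_equal = FALSE`), two-sided. When the pooled variance is zero and the
#' means are equal the test degenerates to `t = 0, p = 1`; zero variance
#' with unequal means is a degenerate input and raises an error.
#'
#' @param scores_a,scores_b Numeric vectors, each of length at least 2.
#' @param n_comparisons Number of comparisons in the family; the corrected
#'   p-value is `min(1, p * n_comparisons)`.
#' @param var_equal If `TRUE` (default), pooled-variance Student's t;
#'   otherwise Welch.
#' @return An object of class `ttest_result` with `t_statistic`, `df`,
#'   `p_value`, `p_corrected`, `n_comparisons`, `mean_diff`, `method`.
#' @export
two_sample_ttest <- function(scores_a, scores_b, n_comparisons = 1L,
                             var_equal = TRUE) {
  assert_that(is.numeric(scores_a) && length(scores_a) >= 2 && all(is.finite(scores_a)),
              "`scores_a` must be a finite numeric vector of length >= 2")
  assert_that(is.numeric(scores_b) && length(scores_b) >= 2 && all(is.finite(scores_b)),
              "`scores_b` must be a finite numeric vector of length >= 2")
  assert_count(n_comparisons, "n_comparisons")
  na <- length(scores_a); nb <- length(scores_b)
  ma <- mean(scores_a); mb <- mean(scores_b)
  if (var_equal) {
    s2 <- ((na - 1) * var(scores_a) + (nb - 1) * var(scores_b)) / (na + nb - 2)
    if (s2 == 0) {
      assert_that(ma == mb,
                  "zero pooled variance with unequal means: t test undefined")
      t_stat <- 0; df <- na + nb - 2; p <- 1
    } else {
      t_stat <- (ma - mb) / sqrt(s2 * (1 / na + 1 / nb))
      df <- na + nb - 2
      p <- 2 * pt(-abs(t_stat), df)
    }
    method <- "pooled"
  } else {
    va <- var(scores_a) / na; vb <- var(scores_b) / nb
    if (va + vb == 0) {
      assert_that(ma == mb,
                  "zero variance with unequal means: t test undefined")
      t_stat <- 0; df <- na + nb - 2; p <- 1
    } else {
      t_stat <- (ma - mb) / sqrt(va + vb)
      df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
      p <- 2 * pt(-abs(t_stat), df)
    }
    method <- "welch"
  }
  structure(
    list(t_statistic = t_stat, df = df, p_value = p,
         p_corrected = bonferroni(p, n_comparisons),
         n_comparisons = as.integer(n_comparisons),
         mean_diff = ma - mb, method = method),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<ttest_result> t = %.4f, df = %.3g, p = %.4g (corrected for %d: %.4g) [%s]\n",
              x$t_statistic, x$df, x$p_value, x$n_comparisons, x$p_corrected,
              x$method))
  invisible(x)
}

#' @export
tidy.ttest_result <- function(x, ...) {
  tibble::tibble(t_statistic = x$t_statistic, df = x$df,
                 p_value = x$p_value, p_corrected = x$p_corrected,
                 n_comparisons = x$n_comparisons, mean_diff = x$mean_diff,
                 method = x$method)
}

#' Bonferroni correction
#'
#' @param p A p-value in [0, 1].
#' @param m Number of comparisons.
#' @return `min(1, p * m)`.
#' @export
bonferroni <- function(p, m) {
  assert_that(is.numeric(p) && all(p >= 0 & p <= 1), "`p` must lie in [0, 1]")
  assert_count(m, "m")
  p.adjust(p, method = "bonferroni", n = max(m, length(p)))
}

#' Median and median absolute deviation of participant scores
#'
#' The MAD is unscaled (no 1.4826 consistency factor): it is used as an
#' error bar across participants, not a standard-deviation estimate.
#' Even-count medians are the mean of the central pair.
#'
#' @param scores Numeric vector, length at least 1.
#' @return A one-row tibble with `median`, `mad`, `n`.
#' @export
summarize_scores <- function(scores) {
  assert_that(is.numeric(scores) && length(scores) >= 1 && all(is.finite(scores)),
              "`scores` must be a non-empty finite numeric vector")
  tibble::tibble(median = median(scores),
                 mad = mad(scores, constant = 1),
                 n = length(scores))
}

#' Compare each condition's participant scores to a reference condition
#'
#' Runs independent two-sample t tests of every condition against the
#' reference scores, Bonferroni-correcting for the number of comparisons
#' (the number of non-reference conditions).
#'
#' @param scores Tibble with columns `condition` and `score` (one row per
#'   participant per condition).
#' @param reference_scores Numeric vector of reference participant scores.
#' @param var_equal Passed to [two_sample_ttest()].
#' @return A tibble with one row per condition: t statistic, df, raw and
#'   corrected p-values.
#' @export
compare_to_reference <- function(scores, reference_scores, var_equal = TRUE) {
  assert_that(is.data.frame(scores) &&
                all(c("condition", "score") %in% names(scores)),
              "`scores` must have condition/score columns")
  conds <- unique(scores$condition)
  m <- length(conds)
  purrr::map_dfr(conds, function(cond) {
    tt <- two_sample_ttest(scores$score[scores$condition == cond],
                           reference_scores, n_comparisons = m,
                           var_equal = var_equal)
    dplyr::mutate(tidy(tt), condition = cond, .before = 1)
  })
}
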