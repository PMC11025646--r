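#' Scorers: next-token probability functions
#'
#' A *scorer* is a function that takes a token window (integer vector) and
#' returns a matrix with one row per window position and one column per
#' vocabulary item, where row `t` is the probability distribution of the
#' token at position `t + 1` given the window up to `t`. [lm_scorer()] wraps
#' a trained or untrained [init_lm()] model; [uniform_scorer()] assigns
#' `1 / vocab_size` everywhere (its perplexity is exactly the vocabulary
#' size); [source_scorer()] scores with the true synthetic source.
#'
#' @param model A `transformer_lm`.
#' @return A scorer function.
#' @export
lm_scorer <- function(model) {
  assert_that(inherits(model, "transformer_lm"), "`model` must be a transformer_lm")
  function(window) exp(forward_logits(model, window))
}

#' @rdname lm_scorer
#' @param vocab_size Vocabulary size for the uniform scorer.
#' @export
uniform_scorer <- function(vocab_size) {
  assert_count(vocab_size, "vocab_size")
  function(window) matrix(1 / vocab_size, length(window), vocab_size)
}

#' Sliding-window perplexity
#'
#' Computes `PPL = 2^H` with `H = -(1/N) * sum(log2 P(x_i | context))`, using
#' overlapping windows: the first window scores every token after the first;
#' each subsequent window advances by `stride` tokens and scores only the
#' `stride` newly entered positions, so every token after the first is scored
#' exactly once, always with at least `context_size - stride` tokens of
#' context. Logarithms are base 2 throughout.
#'
#' @param scorer A scorer function (see [lm_scorer()]).
#' @param tokens Integer token vector, length at least 2.
#' @param context_size Window length in tokens.
#' @param stride Window advance in tokens; must not exceed `context_size`.
#' @return An object of class `perplexity_result`: a list with `H` (bits per
#'   token), `PPL`, `N` (number of scored tokens), `context_size`, `stride`,
#'   and `zero_prob` (`TRUE` if any scored token had probability 0, in which
#'   case `H` and `PPL` are `Inf`).
#' @export
sliding_window_perplexity <- function(scorer, tokens, context_size = 1024L,
                                      stride = 512L) {
  assert_that(is.function(scorer), "`scorer` must be a function")
  assert_count(context_size, "context_size")
  assert_count(stride, "stride")
  assert_that(stride <= context_size, "`stride` must not exceed `context_size`")
  tokens <- as.integer(tokens)
  T <- length(tokens)
  assert_that(T >= 2, "`tokens` must contain at least 2 tokens")

  probs <- numeric(T - 1L)
  e <- min(context_size, T)
  P <- scorer(tokens[1:e])
  pos <- 2:e
  probs[pos - 1L] <- P[cbind(pos - 1L, tokens[pos])]
  prev_e <- e
  while (prev_e < T) {
    e <- min(prev_e + stride, T)
    b <- max(1L, e - context_size + 1L)
    P <- scorer(tokens[b:e])
    pos <- (prev_e + 1L):e
    probs[pos - 1L] <- P[cbind(pos - b, tokens[pos])]
    prev_e <- e
  }

  N <- T - 1L
  zero_prob <- any(probs == 0)
  H <- if (zero_prob) Inf else -mean(log2(probs))
  structure(
    list(H = H, PPL = 2^H, N = N, context_size = as.integer(context_size),
         stride = as.integer(stride), zero_prob = zero_prob),
    class = "perplexity_result"
  )
}

#' @export
print.perplexity_result <- function(x, ...) {
  cat(sprintf("<perplexity_result> PPL %.4g (H %.4g bits/token) over %d tokens (context %d, stride %d)%s\n",
              x$PPL, x$H, x$N, x$context_size, x$stride,
              if (x$zero_prob) " [zero-probability token encountered]" else ""))
  invisible(x)
}

#' @export
glance.perplexity_result <- function(x, ...) {
  tibble::tibble(H = x$H, PPL = x$PPL, N = x$N,
                 context_size = x$context_size, stride = x$stride,
                 zero_prob = x$zero_prob)
}
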