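#' Specify a synthetic token source
#'
#' Defines a random token source with an analytically known entropy rate,
#' used to produce training and evaluation corpora for controlled
#' language-model experiments. Two source families are supported: a
#' memoryless (unigram) source, and a first-order Markov chain.
#'
#' @param vocab_size Number of distinct token types (positive integer).
#' @param source_order 0 for a unigram source, 1 for a first-order Markov
#'   source.
#' @param distribution For `source_order = 0`, a probability vector of length
#'   `vocab_size`; for `source_order = 1`, a `vocab_size` x `vocab_size`
#'   row-stochastic transition matrix. Defaults to the uniform distribution /
#'   uniform transition matrix.
#' @param total_tokens Number of tokens to emit (positive integer).
#' @param seed Integer seed; generation is bit-identical under a fixed seed.
#'
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(vocab_size, source_order = 0L,
                        distribution = NULL, total_tokens = 1000L,
                        seed = 1L) {
  assert_count(vocab_size, "vocab_size")
  assert_that(source_order %in% c(0L, 1L), "`source_order` must be 0 or 1")
  assert_count(total_tokens, "total_tokens")
  if (is.null(distribution)) {
    distribution <- if (source_order == 0L) {
      rep(1 / vocab_size, vocab_size)
    } else {
      matrix(1 / vocab_size, vocab_size, vocab_size)
    }
  }
  if (source_order == 0L) {
    assert_that(length(distribution) == vocab_size,
                "`distribution` must have length `vocab_size`")
    assert_prob_vector(distribution, "distribution")
  } else {
    assert_that(is.matrix(distribution) && all(dim(distribution) == vocab_size),
                "`distribution` must be a vocab_size x vocab_size matrix")
    assert_stochastic_matrix(distribution, "distribution")
  }
  structure(
    list(vocab_size = as.integer(vocab_size),
         source_order = as.integer(source_order),
         distribution = distribution,
         total_tokens = as.integer(total_tokens),
         seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Computed from the left eigenvector of the transition matrix associated
#' with eigenvalue 1, normalized to sum to one.
#'
#' @param T Row-stochastic square matrix.
#' @return Probability vector over states.
#' @export
stationary_distribution <- function(T) {
  assert_stochastic_matrix(T, "T")
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  assert_that(all(v >= -1e-10), "transition matrix has no valid stationary distribution")
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Entropy rate of a synthetic source, in bits per token
#'
#' For a unigram source this is the Shannon entropy of the emission
#' distribution; for a first-order Markov source it is the stationary-weighted
#' conditional entropy \eqn{-\sum_i \pi_i \sum_j T_{ij} \log_2 T_{ij}}.
#'
#' @param spec A [corpus_spec()].
#' @return Entropy rate in bits/token.
#' @export
entropy_rate <- function(spec) {
  assert_that(inherits(spec, "corpus_spec"), "`spec` must be a corpus_spec")
  xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)
  if (spec$source_order == 0L) {
    -sum(xlog2x(spec$distribution))
  } else {
    pi <- stationary_distribution(spec$distribution)
    row_H <- -rowSums(xlog2x(spec$distribution))
    sum(pi * row_H)
  }
}

#' Generate a synthetic token corpus
#'
#' Draws `total_tokens` tokens from the specified source. For a Markov source
#' the first token is drawn from the stationary distribution, so the emitted
#' stream is stationary from the start.
#'
#' @param spec A [corpus_spec()].
#' @return A list with `tokens` (integer vector in `1:vocab_size`),
#'   `entropy_rate` (bits/token), and the `spec`.
#' @export
generate_corpus <- function(spec) {
  assert_that(inherits(spec, "corpus_spec"), "`spec` must be a corpus_spec")
  H <- entropy_rate(spec)
  tokens <- with_seed(spec$seed, {
    n <- spec$total_tokens
    if (spec$source_order == 0L) {
      sample.int(spec$vocab_size, n, replace = TRUE, prob = spec$distribution)
    } else {
      T <- spec$distribution
      cum <- t(apply(T, 1, cumsum))
      pi <- stationary_distribution(T)
      out <- integer(n)
      out[1] <- sample.int(spec$vocab_size, 1, prob = pi)
      if (n > 1) {
        u <- runif(n - 1)
        for (i in 2:n) {
          out[i] <- findInterval(u[i - 1], cum[out[i - 1], ]) + 1L
        }
      }
      out
    }
  })
  list(tokens = tokens, entropy_rate = H, spec = spec)
}

#' Next-token probabilities under the true source model
#'
#' Returns the scorer for the generating source itself, in the form consumed
#' by [sliding_window_perplexity()]: a function mapping a token window to a
#' matrix whose row `t` is the distribution of the token at position `t + 1`
#' given the window so far.
#'
#' @param spec A [corpus_spec()].
#' @return A scorer function.
#' @export
source_scorer <- function(spec) {
  assert_that(inherits(spec, "corpus_spec"), "`spec` must be a corpus_spec")
  if (spec$source_order == 0L) {
    p <- spec$distribution
    function(window) {
      matrix(p, nrow = length(window), ncol = length(p), byrow = TRUE)
    }
  } else {
    T <- spec$distribution
    function(window) T[window, , drop = FALSE]
  }
}
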