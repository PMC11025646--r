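#' PTB-style tokenization
#'
#' Splits text on whitespace, emits punctuation marks as separate tokens, and
#' splits contractions at the apostrophe, discarding the apostrophe itself
#' (`"they're"` becomes `they`, `re`). No lowercasing is applied.
#'
#' @param text A character string (or vector; elements are tokenized
#'   independently and concatenated).
#' @return Character vector of tokens; empty input yields `character(0)`.
#' @export
ptb_tokenize <- function(text) {
  assert_that(is.character(text), "`text` must be character")
  if (length(text) == 0) return(character(0))
  text <- paste(text, collapse = " ")
  text <- gsub("’", "'", text)
  # punctuation (other than the apostrophe) becomes stand-alone tokens
  text <- gsub("([^[:alnum:]'[:space:]])", " \\1 ", text)
  # contractions: split at the apostrophe, dropping it
  text <- gsub("'", " ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Unique n-gram counts for a token stream
#'
#' Counts unique n-grams for `n = 1..max_n` by direct enumeration of all
#' contiguous windows, plus the percentage of unique tokens relative to the
#' total token count.
#'
#' @param tokens Character (or integer) token vector.
#' @param max_n Largest n-gram order (default 4).
#' @return An object of class `corpus_stats`: `total_tokens`,
#'   `unique_ngrams` (named integer vector `"1"`..`"max_n"`), and
#'   `unique_token_fraction` (percent).
#' @export
ngram_stats <- function(tokens, max_n = 4L) {
  assert_count(max_n, "max_n")
  tokens <- as.character(tokens)
  n_tok <- length(tokens)
  counts <- vapply(seq_len(max_n), function(n) {
    if (n > n_tok) return(0L)
    if (n == 1L) return(length(unique(tokens)))
    grams <- tokens[seq_len(n_tok - n + 1L)]
    for (j in seq_len(n - 1L)) {
      grams <- paste(grams, tokens[(1L + j):(n_tok - n + 1L + j)], sep = "\x1f")
    }
    length(unique(grams))
  }, integer(1))
  names(counts) <- as.character(seq_len(max_n))
  structure(
    list(total_tokens = n_tok, unique_ngrams = counts,
         unique_token_fraction = if (n_tok > 0) 100 * counts[["1"]] / n_tok else NA_real_),
    class = "corpus_stats"
  )
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("<corpus_stats> %s tokens; unique n-grams: %s; %.2f%% unique tokens\n",
              format(x$total_tokens, big.mark = ","),
              paste(sprintf("%s-grams %s", names(x$unique_ngrams),
                            format(x$unique_ngrams, big.mark = ",", trim = TRUE)),
                    collapse = ", "),
              x$unique_token_fraction))
  invisible(x)
}

#' @export
tidy.corpus_stats <- function(x, ...) {
  tibble::tibble(
    n = as.integer(names(x$unique_ngrams)),
    unique_ngrams = as.integer(x$unique_ngrams),
    total_tokens = x$total_tokens,
    unique_token_fraction = x$unique_token_fraction
  )
}

#' Check whether benchmark sentences occur in a training corpus
#'
#' A sentence counts as contaminated when its tokenized form occurs as a
#' contiguous token subsequence of the corpus token stream. Matching is
#' exact and case-sensitive on tokenized forms.
#'
#' @param benchmark_sentences Character vector of sentences.
#' @param corpus Either a character scalar of raw text (tokenized with
#'   [ptb_tokenize()]) or an already tokenized character vector.
#' @return A tibble with columns `sentence` and `matched` (logical).
#' @export
contamination_check <- function(benchmark_sentences, corpus) {
  assert_that(is.character(benchmark_sentences), "`benchmark_sentences` must be character")
  corpus_tokens <- if (length(corpus) == 1L) ptb_tokenize(corpus) else as.character(corpus)
  hay <- paste0("\x1f", paste(corpus_tokens, collapse = "\x1f"), "\x1f")
  matched <- vapply(benchmark_sentences, function(s) {
    toks <- ptb_tokenize(s)
    if (length(toks) == 0) return(FALSE)
    needle <- paste0("\x1f", paste(toks, collapse = "\x1f"), "\x1f")
    grepl(needle, hay, fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
  tibble::tibble(sentence = benchmark_sentences, matched = matched)
}
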