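# On-disk formats: benchmarks travel as plain-text tables (long-format CSV
# plus a JSON sidecar for benchmark-level metadata), corpora as UTF-8 text
# or whitespace-separated integer tokens. These formats are deliberately
# simple and diff-able; response matrices are reassembled on read.

#' Write / read a neural benchmark
#'
#' The benchmark is stored as `<path>.csv` (long format: participant,
#' sentence, voxel, voxel_group, experiment, response) plus `<path>.json`
#' carrying the ceiling.
#'
#' @param benchmark A `neural_benchmark`.
#' @param path Path prefix (without extension).
#' @return `write_neural_benchmark()` invisibly returns the paths written;
#'   `read_neural_benchmark()` returns a `neural_benchmark`.
#' @export
write_neural_benchmark <- function(benchmark, path) {
  assert_that(inherits(benchmark, "neural_benchmark"),
              "`benchmark` must be a neural_benchmark")
  csv <- paste0(path, ".csv"); json <- paste0(path, ".json")
  utils::write.csv(tidy.neural_benchmark(benchmark), csv, row.names = FALSE)
  jsonlite::write_json(list(ceiling = benchmark$ceiling), json,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' @rdname write_neural_benchmark
#' @export
read_neural_benchmark <- function(path) {
  tbl <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  n_sent <- max(tbl$sentence); n_vox <- max(tbl$voxel)
  responses <- lapply(sort(unique(tbl$participant)), function(p) {
    sub <- tbl[tbl$participant == p, ]
    m <- matrix(NA_real_, n_sent, n_vox)
    m[cbind(sub$sentence, sub$voxel)] <- sub$response
    m
  })
  first <- tbl[tbl$participant == tbl$participant[1], ]
  voxel_groups <- first$voxel_group[match(seq_len(n_vox), first$voxel)]
  experiments <- first$experiment[match(seq_len(n_sent), first$sentence)]
  neural_benchmark(responses, voxel_groups, experiments,
                   ceiling = meta$ceiling)
}

#' Write / read a behavioral benchmark
#'
#' Stored as a single CSV; the noise ceiling travels in a `ceiling` column
#' (constant across rows) so the file is self-contained.
#'
#' @param benchmark A behavioral benchmark tibble (with `ceiling` attribute).
#' @param path CSV file path.
#' @return `write_behavioral_benchmark()` invisibly returns `path`;
#'   `read_behavioral_benchmark()` returns the tibble with its `ceiling`
#'   attribute restored.
#' @export
write_behavioral_benchmark <- function(benchmark, path) {
  assert_that(is.data.frame(benchmark), "`benchmark` must be a data frame")
  out <- as.data.frame(benchmark)
  ceiling <- attr(benchmark, "ceiling", exact = TRUE)
  if (!is.null(ceiling)) out$ceiling <- ceiling
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavioral_benchmark
#' @export
read_behavioral_benchmark <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  ceiling <- if ("ceiling" %in% names(tbl)) tbl$ceiling[1] else NULL
  tbl$ceiling <- NULL
  out <- tibble::as_tibble(tbl)
  attr(out, "ceiling") <- ceiling
  out
}

#' Write / read an integer token corpus as plain text
#'
#' Tokens are written whitespace-separated, 20 per line.
#'
#' @param tokens Integer token vector (or a [generate_corpus()] result).
#' @param path File path.
#' @return `write_token_corpus()` invisibly returns `path`;
#'   `read_token_corpus()` returns an integer vector.
#' @export
write_token_corpus <- function(tokens, path) {
  if (is.list(tokens) && !is.null(tokens$tokens)) tokens <- tokens$tokens
  tokens <- as.integer(tokens)
  lines <- tapply(tokens, (seq_along(tokens) - 1L) %/% 20L,
                  function(x) paste(x, collapse = " "))
  writeLines(unname(lines), path)
  invisible(path)
}

#' @rdname write_token_corpus
#' @export
read_token_corpus <- function(path) {
  as.integer(scan(path, what = integer(), quiet = TRUE))
}
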