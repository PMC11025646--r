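#' Assemble score, perplexity, and test tables for a set of runs
#'
#' Collects per-condition evaluation results into deterministic, export-ready
#' tables: a long score table (one row per condition, layer, and
#' participant), a perplexity-versus-score table (one row per condition,
#' pairing each condition's perplexity with its participant-median
#' normalized score), and, optionally, a statistical comparison table.
#' Row ordering is fully determined by the inputs, so re-running on
#' unchanged inputs reproduces byte-identical files.
#'
#' @param runs A named list: each element represents one condition (a model
#'   or checkpoint) and is itself a list with elements `sweep` (a
#'   [layer_sweep()] result) or `result` (a single `predictivity_result`),
#'   and optionally `ppl` (a `perplexity_result`).
#' @param tests Optional tibble of test results (e.g.,
#'   [compare_to_reference()] output).
#' @return An object of class `run_report`: list of tibbles `scores`,
#'   `layer_scores`, `ppl_scores`, `tests`.
#' @export
report <- function(runs, tests = NULL) {
  assert_that(is.list(runs) && length(runs) >= 1 && !is.null(names(runs)) &&
                all(nzchar(names(runs))),
              "`runs` must be a non-empty named list (one element per condition)")

  condition_tables <- lapply(names(runs), function(nm) {
    run <- runs[[nm]]
    assert_that(!is.null(run$sweep) || !is.null(run$result),
                sprintf("run '%s' has neither a `sweep` nor a `result`", nm))
    if (!is.null(run$sweep)) {
      results <- attr(run$sweep, "results")
      scores <- purrr::imap_dfr(results, function(res, i) {
        dplyr::mutate(res$participant_scores, layer = i - 1L, .before = 1)
      })
      best <- best_layer(run$sweep)
      layer_tbl <- dplyr::mutate(tibble::as_tibble(run$sweep),
                                 condition = nm, .before = 1)
    } else {
      scores <- dplyr::mutate(run$result$participant_scores, layer = NA_integer_,
                              .before = 1)
      best <- NA_integer_
      layer_tbl <- tibble::tibble(
        condition = nm, layer = NA_integer_,
        median_normalized = run$result$summary$median,
        mad_normalized = run$result$summary$mad)
    }
    list(
      scores = dplyr::mutate(scores, condition = nm, .before = 1),
      layers = layer_tbl,
      ppl = tibble::tibble(
        condition = nm,
        ppl = if (!is.null(run$ppl)) run$ppl$PPL else NA_real_,
        best_layer = best,
        median_normalized = if (!is.null(run$sweep)) {
          attr(run$sweep, "results")[[best + 1L]]$summary$median
        } else run$result$summary$median)
    )
  })

  out <- list(
    scores = dplyr::bind_rows(lapply(condition_tables, `[[`, "scores")),
    layer_scores = dplyr::bind_rows(lapply(condition_tables, `[[`, "layers")),
    ppl_scores = dplyr::bind_rows(lapply(condition_tables, `[[`, "ppl")),
    tests = tests
  )
  structure(out, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d conditions, %d score rows%s\n",
              nrow(x$ppl_scores), nrow(x$scores),
              if (!is.null(x$tests)) sprintf(", %d tests", nrow(x$tests)) else ""))
  print(x$ppl_scores)
  invisible(x)
}

#' Write a run report to CSV tables plus a JSON manifest
#'
#' @param x A [report()] result.
#' @param dir Output directory (created if absent).
#' @param manifest Optional named list of run metadata (seeds, configs) to
#'   embed in the JSON manifest alongside package version and table names.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(x, dir, manifest = list()) {
  assert_that(inherits(x, "run_report"), "`x` must be a run_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("scores", "layer_scores", "ppl_scores", "tests")) {
    tbl <- x[[nm]]
    if (is.null(tbl)) next
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tbl, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    c(list(package = "lmencode",
           version = as.character(utils::packageVersion("lmencode")),
           tables = basename(paths)),
      manifest),
    manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, manifest_path))
}
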