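#' Plot layer-wise predictivity
#'
#' Participant-median normalized score per layer, with unscaled-MAD error
#' bars; the best layer is highlighted.
#'
#' @param object A [layer_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.layer_sweep <- function(object, ...) {
  tbl <- tibble::as_tibble(object)
  best <- best_layer(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$layer, y = .data$median_normalized)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$median_normalized - .data$mad_normalized,
                                      ymax = .data$median_normalized + .data$mad_normalized),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = tbl[tbl$layer == best, ], color = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = tbl$layer) +
    ggplot2::labs(x = "layer (0 = embedding)", y = "normalized predictivity",
                  title = "Layer-wise encoding performance",
                  subtitle = sprintf("best layer: %d", best)) +
    ggplot2::theme_minimal()
}

#' Plot a training trajectory
#'
#' Validation perplexity at each checkpoint against tokens seen
#' (log-scaled x axis; the step-0 checkpoint is shown at the position of the
#' first nonzero checkpoint's tokens divided by 10).
#'
#' @param object An [train_lm()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lm_training <- function(object, ...) {
  h <- object$history
  x <- h$tokens_seen
  if (any(x == 0) && any(x > 0)) x[x == 0] <- min(x[x > 0]) / 10
  h$tokens_plotted <- x
  ggplot2::ggplot(h, ggplot2::aes(x = .data$tokens_plotted, y = .data$val_ppl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "tokens seen", y = "validation perplexity",
                  title = "Training trajectory") +
    ggplot2::theme_minimal()
}

#' Plot perplexity against predictivity across conditions
#'
#' One point per condition (model or checkpoint), pairing its evaluation
#' perplexity with its participant-median normalized score.
#'
#' @param report_or_tbl A [report()] result or its `ppl_scores` tibble.
#' @return A ggplot object.
#' @export
plot_ppl_vs_score <- function(report_or_tbl) {
  tbl <- if (inherits(report_or_tbl, "run_report")) {
    report_or_tbl$ppl_scores
  } else {
    report_or_tbl
  }
  assert_that(is.data.frame(tbl) && all(c("ppl", "median_normalized") %in% names(tbl)),
              "need a table with `ppl` and `median_normalized` columns")
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$ppl, y = .data$median_normalized,
                                    label = .data$condition)) +
    ggplot2::geom_path(color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "perplexity (log scale)", y = "normalized predictivity",
                  title = "Next-token prediction vs. alignment") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
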