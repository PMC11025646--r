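#' Sentence representations from layer activations
#'
#' The representation of a sentence is the activation of the last word; when
#' that word spans several tokens, the token vectors are averaged (trailing
#' punctuation attached to the word participates in the average).
#'
#' @param activations List with one `tokens x units` activation matrix per
#'   sentence (a single layer).
#' @param last_word_tokens List of integer vectors giving, per sentence, the
#'   token positions of the final word; defaults to the last token of each
#'   sentence.
#' @return A `sentences x units` matrix.
#' @export
sentence_representation <- function(activations, last_word_tokens = NULL) {
  assert_that(is.list(activations) && length(activations) >= 1,
              "`activations` must be a non-empty list of matrices")
  if (is.null(last_word_tokens)) {
    last_word_tokens <- lapply(activations, function(m) nrow(m))
  }
  assert_that(length(last_word_tokens) == length(activations),
              "`last_word_tokens` must match `activations` in length")
  out <- vapply(seq_along(activations), function(i) {
    m <- activations[[i]]
    assert_that(is.matrix(m) && nrow(m) >= 1, "each activation must be a non-empty matrix")
    span <- as.integer(last_word_tokens[[i]])
    assert_that(length(span) >= 1 && all(span >= 1 & span <= nrow(m)),
                "last-word token span out of range")
    colMeans(m[span, , drop = FALSE])
  }, numeric(ncol(activations[[1]])))
  t(out)
}

#' Extract per-layer sentence features from a model
#'
#' Runs the model on each sentence in isolation and returns, for every layer
#' (0 = embedding through `n_layers`), the matrix of last-word sentence
#' representations.
#'
#' @param model A `transformer_lm`.
#' @param sentences List of integer token vectors.
#' @param last_word_tokens Optional list of last-word token spans (see
#'   [sentence_representation()]).
#' @return List of `sentences x d_model` matrices, one per layer; names
#'   `"layer0"`, `"layer1"`, ...
#' @export
extract_sentence_features <- function(model, sentences, last_word_tokens = NULL) {
  assert_that(is.list(sentences) && length(sentences) >= 1,
              "`sentences` must be a non-empty list of token vectors")
  acts <- lapply(sentences, function(s) layer_activations(model, s))
  n_layers <- model$config$n_layers
  feats <- lapply(seq_len(n_layers + 1L), function(l) {
    sentence_representation(lapply(acts, `[[`, l), last_word_tokens)
  })
  names(feats) <- paste0("layer", 0:n_layers)
  feats
}

#' Split items into near-equal contiguous cross-validation folds
#'
#' Items are assigned to `k` contiguous batches in stimulus order; when
#' `n_items` is not divisible by `k`, the remainder `r` is distributed as one
#' extra item to each of the last `r` folds (so 243 items in 5 folds gives
#' sizes 48, 48, 49, 49, 49).
#'
#' @param n_items Number of items; must be at least `k`.
#' @param k Number of folds (default 5).
#' @return An object of class `fold_spec`: `n_items`, `k`, and `assignment`
#'   (integer fold index per item).
#' @export
make_folds <- function(n_items, k = 5L) {
  assert_count(n_items, "n_items")
  assert_count(k, "k")
  assert_that(n_items >= k, "`n_items` must be at least `k`")
  base <- n_items %/% k
  r <- n_items %% k
  sizes <- rep(base, k) + c(rep(0L, k - r), rep(1L, r))
  structure(
    list(n_items = as.integer(n_items), k = as.integer(k),
         assignment = rep(seq_len(k), times = sizes)),
    class = "fold_spec"
  )
}

#' Minimum-norm least-squares linear map with intercept
#'
#' Fits `Y ~ X` by ordinary least squares on centered data; when the system
#' is underdetermined (more predictors than training rows) the SVD
#' pseudoinverse yields the minimum-norm solution. An optional ridge penalty
#' is available.
#'
#' @param X Numeric `items x units` predictor matrix.
#' @param Y Numeric `items x voxels` response matrix (or vector).
#' @param ridge Nonnegative ridge penalty (default 0, i.e., plain least
#'   squares).
#' @return An object of class `linear_map` with `W` (`units x voxels`) and
#'   `intercept` (length `voxels`); use [predict()] to apply it.
#' @export
fit_linear_map <- function(X, Y, ridge = 0) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  assert_that(is.matrix(X) && all(is.finite(X)), "`X` must be a finite numeric matrix")
  assert_that(all(is.finite(Y)), "`Y` must be finite")
  assert_that(nrow(X) == nrow(Y), "`X` and `Y` must have equal row counts")
  assert_that(nrow(X) >= 2, "need at least 2 training rows")
  assert_number(ridge, "ridge", min = 0)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean)
  Yc <- sweep(Y, 2, y_mean)
  W <- if (ridge > 0) {
    solve(crossprod(Xc) + diag(ridge, ncol(Xc)), crossprod(Xc, Yc))
  } else {
    pinv(Xc) %*% Yc
  }
  structure(list(W = W, intercept = y_mean - drop(crossprod(W, x_mean))),
            class = "linear_map")
}

#' @export
predict.linear_map <- function(object, newdata, ...) {
  assert_that(is.matrix(newdata) && ncol(newdata) == nrow(object$W),
              "`newdata` must have one column per fitted unit")
  add_bias(newdata %*% object$W, object$intercept)
}

#' Cross-validated per-voxel predictivity
#'
#' For each fold, fits a linear map on the complementary items, predicts the
#' held-out items, and computes the per-voxel Pearson correlation between
#' predicted and observed responses; correlations are then averaged across
#' folds.
#'
#' @param X `items x units` feature matrix.
#' @param Y `items x voxels` response matrix.
#' @param folds A [make_folds()] fold specification over the items.
#' @param ridge Ridge penalty forwarded to [fit_linear_map()].
#' @return Numeric vector of fold-averaged Pearson correlations, one per
#'   voxel.
#' @export
cross_validated_predictivity <- function(X, Y, folds, ridge = 0) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  assert_that(inherits(folds, "fold_spec"), "`folds` must be a fold_spec")
  assert_that(nrow(X) == folds$n_items && nrow(Y) == folds$n_items,
              "`folds` must cover exactly the rows of `X` and `Y`")
  sizes <- tabulate(folds$assignment, nbins = folds$k)
  assert_that(all(sizes >= 3),
              "every test fold needs at least 3 items for a defined correlation")
  r_folds <- vapply(seq_len(folds$k), function(f) {
    test <- folds$assignment == f
    fit <- fit_linear_map(X[!test, , drop = FALSE], Y[!test, , drop = FALSE],
                          ridge = ridge)
    pred <- predict(fit, X[test, , drop = FALSE])
    obs <- Y[test, , drop = FALSE]
    vapply(seq_len(ncol(Y)), function(v) safe_cor(pred[, v], obs[, v]),
           numeric(1))
  }, numeric(ncol(Y)))
  if (is.vector(r_folds)) r_folds <- matrix(r_folds, nrow = 1)
  rowMeans(r_folds)
}

#' Participant score: median predictivity over a voxel group
#'
#' @param per_voxel_r Fold-averaged per-voxel correlations.
#' @param group Optional logical mask or index vector selecting voxels;
#'   defaults to all voxels. Even-count medians are the mean of the central
#'   pair.
#' @return Median Pearson correlation over the selected voxels.
#' @export
participant_score <- function(per_voxel_r, group = NULL) {
  r <- if (is.null(group)) per_voxel_r else per_voxel_r[group]
  assert_that(length(r) >= 1, "voxel group must be non-empty")
  median(r)
}

#' Combine experiment-block scores and normalize by the noise ceiling
#'
#' @param scores Numeric vector of per-block participant scores.
#' @param ceiling Noise ceiling, strictly positive.
#' @return `mean(scores) / ceiling`.
#' @export
combine_and_normalize <- function(scores, ceiling) {
  assert_that(is.numeric(scores) && length(scores) >= 1 && all(is.finite(scores)),
              "`scores` must be finite")
  assert_that(is.numeric(ceiling) && length(ceiling) == 1 && is.finite(ceiling) &&
                ceiling > 0, "`ceiling` must be a positive number")
  mean(scores) / ceiling
}

#' Score a neural benchmark with a feature matrix
#'
#' The full encoding pipeline for one layer: for every participant and
#' experiment block, features are mapped to voxel responses by
#' cross-validated least squares; per-voxel correlations are fold-averaged,
#' the participant score is the median over voxels, block scores are averaged
#' and divided by the benchmark ceiling. A per-voxel-group breakdown is
#' included.
#'
#' @param features `sentences x units` feature matrix aligned with the
#'   benchmark's sentence order.
#' @param benchmark A `neural_benchmark`.
#' @param k Number of cross-validation folds (default 5).
#' @param ridge Ridge penalty forwarded to [fit_linear_map()].
#' @return An object of class `predictivity_result` with `participant_scores`
#'   (tibble: participant, raw, normalized), `group_scores`,
#'   `per_voxel` (tibble: participant, block, voxel, voxel_group, r),
#'   `ceiling`, and `summary` (median, unscaled MAD, n over participants of
#'   the normalized score).
#' @export
score_neural_benchmark <- function(features, benchmark, k = 5L, ridge = 0) {
  assert_that(inherits(benchmark, "neural_benchmark"),
              "`benchmark` must be a neural_benchmark")
  assert_that(is.matrix(features) && nrow(features) == nrow(benchmark$responses[[1]]),
              "`features` rows must match the benchmark's sentence count")
  blocks <- unique(benchmark$experiments)
  groups <- benchmark$voxel_groups
  n_vox <- ncol(benchmark$responses[[1]])

  per_voxel <- list(); p_rows <- list(); g_rows <- list()
  for (p in seq_along(benchmark$responses)) {
    Y <- benchmark$responses[[p]]
    block_scores <- numeric(length(blocks))
    block_group <- matrix(NA_real_, length(blocks), length(unique(groups)),
                          dimnames = list(NULL, unique(groups)))
    for (e in seq_along(blocks)) {
      idx <- which(benchmark$experiments == blocks[e])
      folds <- make_folds(length(idx), k)
      r <- cross_validated_predictivity(features[idx, , drop = FALSE],
                                        Y[idx, , drop = FALSE], folds,
                                        ridge = ridge)
      block_scores[e] <- participant_score(r)
      for (grp in unique(groups)) {
        block_group[e, grp] <- participant_score(r, groups == grp)
      }
      per_voxel[[length(per_voxel) + 1L]] <- tibble::tibble(
        participant = p, block = blocks[e], voxel = seq_len(n_vox),
        voxel_group = groups, r = r)
    }
    raw <- mean(block_scores)
    p_rows[[p]] <- tibble::tibble(participant = p, raw = raw,
                                  normalized = raw / benchmark$ceiling)
    g_rows[[p]] <- tibble::tibble(
      participant = p, voxel_group = colnames(block_group),
      raw = colMeans(block_group),
      normalized = colMeans(block_group) / benchmark$ceiling)
  }
  participant_scores <- dplyr::bind_rows(p_rows)
  structure(
    list(participant_scores = participant_scores,
         group_scores = dplyr::bind_rows(g_rows),
         per_voxel = dplyr::bind_rows(per_voxel),
         ceiling = benchmark$ceiling,
         summary = summarize_scores(participant_scores$normalized)),
    class = "predictivity_result"
  )
}

#' @export
print.predictivity_result <- function(x, ...) {
  cat(sprintf("<predictivity_result> %d participants, ceiling %.3f; normalized score median %.3f (MAD %.3f)\n",
              nrow(x$participant_scores), x$ceiling,
              x$summary$median, x$summary$mad))
  invisible(x)
}

#' @export
tidy.predictivity_result <- function(x, ...) x$participant_scores

#' @export
glance.predictivity_result <- function(x, ...) {
  tibble::tibble(median_normalized = x$summary$median,
                 mad_normalized = x$summary$mad,
                 n_participants = x$summary$n,
                 ceiling = x$ceiling)
}

#' Sweep the encoding pipeline over model layers
#'
#' Runs [score_neural_benchmark()] for every layer's feature matrix and
#' reports the participant-median normalized score per layer. The best layer
#' is the argmax; ties break toward the lowest layer index.
#'
#' @param features_by_layer List of `sentences x units` matrices, ordered
#'   from layer 0 (embedding) upward.
#' @param benchmark A `neural_benchmark`.
#' @inheritParams score_neural_benchmark
#' @return An object of class `layer_sweep`: a tibble with columns `layer`
#'   (0-based), `median_normalized`, `mad_normalized`, with attributes
#'   `best_layer` (0-based index) and `results` (per-layer
#'   `predictivity_result` objects).
#' @export
layer_sweep <- function(features_by_layer, benchmark, k = 5L, ridge = 0) {
  assert_that(is.list(features_by_layer) && length(features_by_layer) >= 1,
              "`features_by_layer` must be a non-empty list")
  results <- lapply(features_by_layer, score_neural_benchmark,
                    benchmark = benchmark, k = k, ridge = ridge)
  tbl <- tibble::tibble(
    layer = seq_along(results) - 1L,
    median_normalized = vapply(results, function(r) r$summary$median, numeric(1)),
    mad_normalized = vapply(results, function(r) r$summary$mad, numeric(1))
  )
  structure(tbl,
            best_layer = tbl$layer[which.max(tbl$median_normalized)],
            results = results,
            class = c("layer_sweep", class(tbl)))
}

#' Best layer of a sweep
#' @param sweep A [layer_sweep()] result.
#' @return 0-based index of the layer with the highest participant-median
#'   normalized score (lowest index on ties).
#' @export
best_layer <- function(sweep) {
  assert_that(inherits(sweep, "layer_sweep"), "`sweep` must be a layer_sweep")
  attr(sweep, "best_layer")
}
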