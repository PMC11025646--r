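#' Specify a synthetic multi-participant neural benchmark
#'
#' Describes how voxel responses are generated from a feature matrix: every
#' participant shares one linear readout of the features (the "signal"), and
#' receives independent Gaussian measurement noise. Because signal and noise
#' variances are known, the noise ceiling of the benchmark is available in
#' closed form.
#'
#' @param n_participants Number of simulated participants.
#' @param n_voxels Number of voxels per participant.
#' @param readout_weights Optional `units x n_voxels` matrix of readout
#'   weights. If `NULL`, weights are sampled i.i.d. standard normal at
#'   generation time (under `seed`).
#' @param noise_sd Gaussian noise standard deviation; either a scalar or a
#'   vector of length `n_participants`.
#' @param voxel_groups Optional character vector of length `n_voxels` with a
#'   group (e.g., ROI) label per voxel; defaults to a single `"all"` group.
#' @param seed Integer seed.
#'
#' @return An object of class `neural_spec`.
#' @export
neural_spec <- function(n_participants, n_voxels, readout_weights = NULL,
                        noise_sd = 1, voxel_groups = NULL, seed = 1L) {
  assert_count(n_participants, "n_participants")
  assert_count(n_voxels, "n_voxels")
  assert_that(is.numeric(noise_sd) && all(is.finite(noise_sd)) && all(noise_sd >= 0),
              "`noise_sd` must be nonnegative")
  assert_that(length(noise_sd) %in% c(1L, n_participants),
              "`noise_sd` must be a scalar or one value per participant")
  if (!is.null(readout_weights)) {
    assert_that(is.matrix(readout_weights) && ncol(readout_weights) == n_voxels,
                "`readout_weights` must be a units x n_voxels matrix")
    assert_that(all(is.finite(readout_weights)),
                "`readout_weights` must be finite")
  }
  if (is.null(voxel_groups)) voxel_groups <- rep("all", n_voxels)
  assert_that(length(voxel_groups) == n_voxels,
              "`voxel_groups` must have one label per voxel")
  structure(
    list(n_participants = as.integer(n_participants),
         n_voxels = as.integer(n_voxels),
         readout_weights = readout_weights,
         noise_sd = rep_len(noise_sd, n_participants),
         voxel_groups = as.character(voxel_groups),
         seed = as.integer(seed)),
    class = "neural_spec"
  )
}

#' Generate a synthetic neural benchmark from a feature matrix
#'
#' Each participant's response to sentence `s` in voxel `v` is
#' `(features %*% readout_weights)[s, v]` plus participant-specific Gaussian
#' noise. The returned ground truth records per-voxel signal variance, noise
#' variance, and the analytic noise ceiling
#' `sqrt(signal_var / (signal_var + noise_var))` — the expected correlation
#' between the noiseless signal and a noisy measurement, i.e., the best score
#' any model predicting the shared signal could reach on one participant.
#'
#' @param spec A [neural_spec()].
#' @param features Numeric `sentences x units` feature matrix (e.g., model
#'   layer activations for the stimuli).
#' @param experiments Optional factor/character vector assigning each
#'   sentence to an experiment block; defaults to a single block.
#'
#' @return A list with `benchmark` (class `neural_benchmark`: per-participant
#'   `sentences x voxels` response matrices, voxel group labels, experiment
#'   blocks, and a scalar ceiling — the median per-voxel analytic ceiling)
#'   and `ground_truth` (class `ground_truth` with per-voxel
#'   `signal_variance`, `noise_variance`, `analytic_ceiling`, and the
#'   noiseless `signal` matrix).
#' @export
generate_neural_benchmark <- function(spec, features, experiments = NULL) {
  assert_that(inherits(spec, "neural_spec"), "`spec` must be a neural_spec")
  assert_that(is.matrix(features) && all(is.finite(features)),
              "`features` must be a finite numeric matrix")
  n_sent <- nrow(features)
  assert_that(n_sent >= 2, "`features` must have at least 2 rows")
  if (is.null(experiments)) experiments <- rep("exp1", n_sent)
  assert_that(length(experiments) == n_sent,
              "`experiments` must have one entry per sentence")

  out <- with_seed(spec$seed, {
    W <- spec$readout_weights
    if (is.null(W)) {
      W <- matrix(rnorm(ncol(features) * spec$n_voxels), ncol(features))
    }
    assert_that(nrow(W) == ncol(features),
                "readout weight rows must match feature columns")
    signal <- features %*% W
    responses <- lapply(seq_len(spec$n_participants), function(p) {
      signal + matrix(rnorm(length(signal), sd = spec$noise_sd[p]),
                      nrow(signal), ncol(signal))
    })
    list(signal = signal, responses = responses)
  })

  sig_var <- apply(out$signal, 2, var)
  noise_var <- rep(mean(spec$noise_sd^2), spec$n_voxels)
  ceiling_v <- ifelse(sig_var + noise_var > 0,
                      sqrt(sig_var / (sig_var + noise_var)), 1)
  ceiling_v[noise_var == 0] <- 1

  ground_truth <- structure(
    list(signal_variance = sig_var,
         noise_variance = noise_var,
         analytic_ceiling = ceiling_v,
         signal = out$signal),
    class = "ground_truth"
  )
  benchmark <- structure(
    list(responses = lapply(out$responses, function(m) {
           dimnames(m) <- NULL; m
         }),
         voxel_groups = spec$voxel_groups,
         experiments = as.character(experiments),
         ceiling = stats::median(ceiling_v)),
    class = "neural_benchmark"
  )
  list(benchmark = benchmark, ground_truth = ground_truth)
}

#' Construct a neural benchmark from explicit response matrices
#'
#' @param responses List of `sentences x voxels` matrices, one per
#'   participant, all the same dimension.
#' @param voxel_groups Character vector, one label per voxel.
#' @param experiments Vector assigning each sentence to an experiment block.
#' @param ceiling Noise ceiling in (0, 1].
#' @return A `neural_benchmark` object.
#' @export
neural_benchmark <- function(responses, voxel_groups = NULL,
                             experiments = NULL, ceiling = 1) {
  assert_that(is.list(responses) && length(responses) >= 1,
              "`responses` must be a non-empty list of matrices")
  d <- dim(responses[[1]])
  for (m in responses) {
    assert_that(is.matrix(m) && all(dim(m) == d) && all(is.finite(m)),
                "all response matrices must be finite with equal dimensions")
  }
  assert_number(ceiling, "ceiling", min = 1e-12, max = 1)
  if (is.null(voxel_groups)) voxel_groups <- rep("all", d[2])
  if (is.null(experiments)) experiments <- rep("exp1", d[1])
  assert_that(length(voxel_groups) == d[2], "one group label per voxel required")
  assert_that(length(experiments) == d[1], "one experiment label per sentence required")
  structure(
    list(responses = responses, voxel_groups = as.character(voxel_groups),
         experiments = as.character(experiments), ceiling = ceiling),
    class = "neural_benchmark"
  )
}

#' @export
print.neural_benchmark <- function(x, ...) {
  d <- dim(x$responses[[1]])
  cat(sprintf(
    "<neural_benchmark> %d participants, %d sentences x %d voxels, ceiling %.3f\n",
    length(x$responses), d[1], d[2], x$ceiling))
  invisible(x)
}

#' Tidy a neural benchmark into long format
#'
#' @param x A `neural_benchmark`.
#' @param ... Unused.
#' @return A tibble with columns `participant`, `sentence`, `voxel`,
#'   `voxel_group`, `experiment`, `response`.
#' @export
tidy.neural_benchmark <- function(x, ...) {
  purrr::imap_dfr(x$responses, function(m, p) {
    tibble::tibble(
      participant = p,
      sentence = rep(seq_len(nrow(m)), times = ncol(m)),
      voxel = rep(seq_len(ncol(m)), each = nrow(m)),
      voxel_group = rep(x$voxel_groups, each = nrow(m)),
      experiment = rep(x$experiments, times = ncol(m)),
      response = as.vector(m)
    )
  })
}
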