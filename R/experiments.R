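# Desk-scale replications of the two controlled experiments the package is
# built around: (i) how validation perplexity and benchmark predictivity
# change with the amount of training, and (ii) whether the encoding layer
# sweep recovers the layer that generated a benchmark. Defaults define the
# study conditions; the methods vignette motivates each value.

#' Training-scale experiment on a synthetic Markov source
#'
#' Trains the same small causal transformer under increasing token budgets
#' on a first-order Markov corpus, then measures (a) validation perplexity
#' and (b) normalized predictivity of a synthetic neural benchmark whose
#' voxel responses are linear in the source's true next-token
#' log-probabilities (a stimulus property the model must learn to encode;
#' an untrained model's `d_model`-dimensional random embedding cannot
#' linearly represent it because the vocabulary is larger than `d_model`).
#' Replicated over seeds; medians across seeds are reported per budget.
#'
#' @param budgets Token budgets (tokens seen during training).
#' @param n_seeds Number of replicate seeds per budget.
#' @param vocab_size,d_model Source and model sizes (vocabulary deliberately
#'   exceeds the model width).
#' @param n_sentences,sentence_len Benchmark stimulus set.
#' @param n_participants,n_voxels Benchmark dimensions.
#' @param noise_frac Benchmark noise SD as a fraction of the median signal
#'   SD.
#' @param batch_size,context,lr Training hyperparameters.
#' @param seed Master seed; all per-replicate seeds derive from it.
#' @return A list with `by_budget` (tibble: budget, median_val_ppl,
#'   median_score over seeds), `runs` (per-seed tibble), and the benchmark
#'   ceiling.
#' @export
run_scaling_experiment <- function(budgets = c(1e3, 1e4, 1e5), n_seeds = 5L,
                                   vocab_size = 40L, d_model = 16L,
                                   n_sentences = 100L, sentence_len = 12L,
                                   n_participants = 3L, n_voxels = 30L,
                                   noise_frac = 0.6, batch_size = 8L,
                                   context = 16L, lr = 3e-3, seed = 1L) {
  seed <- as.integer(seed)
  Tm <- make_transition_matrix(vocab_size, seed = seed + 1000L)
  cfg <- transformer_config(n_layers = 2L, d_model = d_model, n_heads = 2L,
                            d_ff = 2L * d_model, context_size = context,
                            vocab_size = vocab_size)
  corpus_len <- as.integer(max(budgets) + 30000L)
  spec <- corpus_spec(vocab_size, 1L, Tm, total_tokens = corpus_len,
                      seed = seed + 2000L)
  corp <- generate_corpus(spec)

  sents <- lapply(seq_len(n_sentences), function(i) {
    generate_corpus(corpus_spec(vocab_size, 1L, Tm, total_tokens = sentence_len,
                                seed = seed + 3000L + i))$tokens
  })
  last_tok <- vapply(sents, function(s) s[length(s)], integer(1))
  # surprisal-profile features: the source's next-token log-probabilities
  # given the sentence-final token, clamped at 12 bits
  Ftrue <- log2(pmax(Tm, 2^-12))[last_tok, , drop = FALSE]
  W <- with_seed(seed + 4000L,
                 matrix(rnorm(vocab_size * n_voxels), vocab_size))
  sig_sd <- median(apply(Ftrue %*% W, 2, sd))
  gen <- generate_neural_benchmark(
    neural_spec(n_participants, n_voxels, readout_weights = W,
                noise_sd = noise_frac * sig_sd, seed = seed + 5000L),
    Ftrue)

  runs <- list()
  for (budget in budgets) {
    steps <- max(1L, as.integer(budget %/% (batch_size * context)))
    for (rs in seq_len(n_seeds)) {
      model <- init_lm(cfg, seed = seed + 10L * rs)
      tr <- train_lm(model, corp$tokens, n_steps = steps,
                     batch_size = batch_size, context = context, lr = lr,
                     seed = seed + 10L * rs + 1L)
      feats <- extract_sentence_features(tr$model, sents)
      sw <- layer_sweep(feats, gen$benchmark, k = 5L)
      runs[[length(runs) + 1L]] <- tibble::tibble(
        budget = budget, replicate = rs, steps = steps,
        val_ppl = tail(tr$history$val_ppl, 1),
        score = max(sw$median_normalized),
        best_layer = best_layer(sw))
    }
  }
  runs <- dplyr::bind_rows(runs)
  by_budget <- dplyr::summarise(
    dplyr::group_by(runs, .data$budget),
    median_val_ppl = median(.data$val_ppl),
    median_score = median(.data$score), .groups = "drop")
  list(by_budget = by_budget, runs = runs,
       ceiling = gen$benchmark$ceiling,
       entropy_rate = corp$entropy_rate)
}

#' Layer-recovery experiment
#'
#' Trains a small transformer on a Markov source, generates synthetic
#' benchmarks from the activations of one chosen layer at low noise, and
#' checks how often the layer sweep identifies that layer across replicate
#' benchmarks.
#'
#' @param true_layer 0-based index of the generating layer.
#' @param n_replicates Number of seeded benchmark replicates.
#' @param noise_frac Benchmark noise SD as a fraction of the median signal
#'   SD (low by design).
#' @param n_sentences,n_participants,n_voxels Benchmark dimensions.
#' @param train_steps Training steps for the toy model.
#' @param seed Master seed.
#' @return A list with `hit_rate`, `selected` (per-replicate best layers),
#'   and `true_layer`.
#' @export
run_layer_recovery <- function(true_layer = 1L, n_replicates = 10L,
                               noise_frac = 0.05, n_sentences = 150L,
                               n_participants = 5L, n_voxels = 40L,
                               train_steps = 800L, seed = 1L) {
  seed <- as.integer(seed)
  V <- 40L
  Tm <- make_transition_matrix(V, seed = seed + 1000L)
  corp <- generate_corpus(corpus_spec(V, 1L, Tm, total_tokens = 60000L,
                                      seed = seed + 2000L))
  cfg <- transformer_config(n_layers = 2L, d_model = 16L, n_heads = 2L,
                            d_ff = 32L, context_size = 16L, vocab_size = V)
  assert_that(true_layer >= 0 && true_layer <= cfg$n_layers,
              "`true_layer` must be a valid 0-based layer index")
  tr <- train_lm(init_lm(cfg, seed = seed + 21L), corp$tokens,
                 n_steps = train_steps, batch_size = 8L, context = 16L,
                 lr = 3e-3, seed = seed + 31L)
  sents <- lapply(seq_len(n_sentences), function(i) {
    generate_corpus(corpus_spec(V, 1L, Tm, total_tokens = 12L,
                                seed = seed + 3000L + i))$tokens
  })
  feats <- extract_sentence_features(tr$model, sents)
  X <- feats[[true_layer + 1L]]
  W <- with_seed(seed + 4000L, matrix(rnorm(ncol(X) * n_voxels), ncol(X)))
  sig_sd <- median(apply(X %*% W, 2, sd))
  selected <- vapply(seq_len(n_replicates), function(rep) {
    gen <- generate_neural_benchmark(
      neural_spec(n_participants, n_voxels, readout_weights = W,
                  noise_sd = noise_frac * sig_sd, seed = seed + 100L + rep),
      X)
    best_layer(layer_sweep(feats, gen$benchmark, k = 5L))
  }, integer(1))
  list(hit_rate = mean(selected == true_layer), selected = selected,
       true_layer = as.integer(true_layer))
}

#' Rough random transition matrix for synthetic sources
#'
#' Rows are normalized draws from a small-shape gamma, giving a source whose
#' conditional next-token distributions are peaked and vary strongly with
#' the previous token (large usable mutual information between adjacent
#' tokens).
#'
#' @param vocab_size Number of states.
#' @param seed Integer seed.
#' @param shape Gamma shape; smaller is peakier.
#' @return A row-stochastic matrix.
#' @export
make_transition_matrix <- function(vocab_size, seed = 1L, shape = 0.3) {
  assert_count(vocab_size, "vocab_size")
  with_seed(seed, {
    T <- matrix(rgamma(vocab_size^2, shape) + 1e-6, vocab_size)
    T / rowSums(T)
  })
}
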