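# lmencode

Controlled experiments on how the *amount* of language-model training
affects alignment with human neural and behavioral responses to language.

Large language models predict fMRI responses to sentences remarkably well,
but they are usually trained on orders of magnitude more text than a human
ever hears. Disentangling what alignment requires — architecture, training
objective, or sheer data volume — calls for controlled experiments: train
the same model under different token budgets and measure, at each budget,
(a) next-token prediction quality and (b) how well the model's internal
representations predict brain and reading-time data. `lmencode` packages
that entire pipeline in R, together with synthetic benchmark generators
with *analytically known* ground truth, so every stage is testable without
access to fMRI data.

## What's inside

- **A causal transformer LM built from scratch** (`transformer_config()`,
  `init_lm()`, `train_lm()`): GPT-2-style pre-norm blocks (layer norm →
  multi-head causal self-attention → layer norm → feedforward), learned
  token + position embeddings, hand-written backpropagation verified
  against finite differences, Adam training on random context windows,
  logarithmic checkpoint schedules, and exact token-budget accounting
  (`tokens_seen()`, `steps_for_one_pass()`). Controlled initialization
  schemes include the fully Gaussian N(0, 0.02²) variant used to probe
  untrained architectures.
- **Sliding-window perplexity** (`sliding_window_perplexity()`):
  PPL = 2^H with H = −(1/N) Σ log₂ P(xᵢ | context); overlapping windows
  score only newly entered tokens, so each token is scored once.
- **Neural encoding models** (`score_neural_benchmark()`, `layer_sweep()`):
  per layer, a cross-validated linear map from sentence representations
  (last-word activations, multi-token words averaged) to voxel responses;
  five contiguous, near-equal stimulus folds; per-voxel Pearson
  correlations fold-averaged; the participant score is the median over
  voxels, averaged over experiment blocks and divided by the noise
  ceiling. Minimum-norm (pseudoinverse) least squares handles the
  underdetermined regime; ridge is optional.
- **Reading-time predictivity** (`filter_rts()`, `word_folds()`,
  `rt_predictivity()`): [100, 3000] ms range filtering, word-level folds
  constrained so a word type never straddles the train/test split within a
  sentence, per-participant cross-validated scores normalized by a ceiling.
- **Corpus tools** (`ptb_tokenize()`, `ngram_stats()`,
  `contamination_check()`): PTB-style tokenization (contractions split,
  punctuation as tokens), unique n-gram counts, and exact-subsequence
  benchmark contamination checks.
- **Statistics and reporting** (`two_sample_ttest()`, `bonferroni()`,
  `summarize_scores()`, `report()`): independent two-sample t tests
  against a reference model with Bonferroni correction, median ± unscaled
  MAD summaries, deterministic CSV/JSON export, and `autoplot()` methods.
- **Synthetic data with known ground truth** (`generate_corpus()`,
  `generate_neural_benchmark()`, `generate_reading_times()`): token
  sources with closed-form entropy rates; multi-participant voxel
  responses as a shared linear readout plus Gaussian noise, giving the
  analytic noise ceiling √(σ²ₛ/(σ²ₛ+σ²ₙ)); reading times affine in
  surprisal with injected out-of-range artifacts.

## Worked example

Train a small transformer on a first-order Markov source, checkpoint it,
and score a synthetic fMRI-style benchmark generated from its own layer-2
representations:

```r
library(lmencode)

Tm     <- make_transition_matrix(30, seed = 1)
spec   <- corpus_spec(30, source_order = 1, distribution = Tm,
                      total_tokens = 50000, seed = 2)
corpus <- generate_corpus(spec)
2^corpus$entropy_rate          # optimal perplexity of this source: 11.27

cfg <- transformer_config(n_layers = 2, d_model = 16, n_heads = 2,
                          d_ff = 32, context_size = 16, vocab_size = 30)
training <- train_lm(init_lm(cfg, seed = 3), corpus$tokens,
                     schedule = checkpoint_schedule(400, c(0, 0.1, 1)),
                     batch_size = 8, context = 16, lr = 3e-3, seed = 4)
training$history
#>    step tokens_seen val_ppl train_loss
#> 1     0           0    30.0      NA
#> 2    40        5120    21.5       3.12
#> 3   400       51200    12.6       2.39
```

Validation perplexity falls from 30 (untrained; roughly the vocabulary
size) toward the source's entropy floor of 11.27. Now build a benchmark
whose voxels are a noisy linear readout of the trained model's layer-2
sentence representations, and sweep all layers:

```r
sents <- lapply(1:80, function(i)
  generate_corpus(corpus_spec(30, 1, Tm, total_tokens = 12,
                              seed = 100 + i))$tokens)
feats <- extract_sentence_features(best_checkpoint(training)$model, sents)
gen   <- generate_neural_benchmark(neural_spec(3, 20, noise_sd = 0.5,
                                               seed = 5), feats[[3]])
sw <- layer_sweep(feats, gen$benchmark)
sw
#>   layer median_normalized mad_normalized
#> 1     0             0.859         0.0530
#> 2     1             0.862         0.0541
#> 3     2             0.856         0.0630
glance(attr(sw, "results")[[best_layer(sw) + 1]])
#>   median_normalized mad_normalized n_participants ceiling
#> 1             0.862         0.0541              3   0.743
```

Every layer predicts ~86% of the ceiling-normalized signal: in a two-layer
model the residual stream keeps layers nearly linearly interchangeable for
a benchmark like this one. The packaged experiment
`run_layer_recovery()` makes the layer identifiable (deeper training, low
benchmark noise, more stimuli) and recovers the generating layer in 10/10
replicates at its defaults; `run_scaling_experiment()` reproduces the
headline scaling result — across 10³/10⁴/10⁵ training-token budgets,
median validation perplexity falls (38.9 → 27.5 → 18.8) while median
normalized benchmark predictivity rises (0.51 → 0.60 → 0.73; seed 1,
medians over 5 replicate seeds).

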