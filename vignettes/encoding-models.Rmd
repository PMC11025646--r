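---
title: "Training-scale encoding models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-scale encoding models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lmencode` implements a controlled pipeline for asking how the amount of
language-model training shapes alignment with human neural and behavioral
responses: train a small causal transformer under exact token budgets,
measure its next-token prediction quality (perplexity), and regress its
layer activations against (synthetic or supplied) fMRI-style and
reading-time benchmarks with ceiling normalization. This vignette is the
package's own account of the models, conventions, and design decisions.

## The language model

`transformer_config()` describes a GPT-2-family causal transformer: a
learned token embedding plus a learned positional embedding, then
`n_layers` pre-norm blocks — layer normalization, multi-head causal
self-attention, a second layer normalization, and a position-wise
feedforward layer (exact GELU, `x * pnorm(x)`) — each wrapped in residual
connections, followed by a final layer normalization and a linear
projection to next-token probabilities via softmax. The reference
configuration at full scale is 12 layers × 768 units with a 1,024-token
context; that configuration is expressible but the package's own
experiments run desk-scale models (2 layers × 16–64 units, 16–64-token
contexts), where training to near the entropy floor of a synthetic source
takes seconds, not GPUs. The residual-connection placement is the pre-norm
convention; descriptions of this block order elsewhere leave the residual
path unstated, and pre-norm is the standard choice that trains stably
without warmup.

Two initialization schemes are exposed rather than hard-coded
(`init_scheme()`): `"default"`, the conventional scaled-normal transformer
initialization (weights ~ N(0, 0.02²), biases 0, layer-norm gain 1), and
`"gaussian"`, in which *every* governed parameter — including layer-norm
gains and biases — is drawn from N(mean, sd²), by default N(0, 0.02²).
The Gaussian variant is the controlled "architecture-only" baseline: it
shares the unidirectional mask and connectivity of a trained model but
carries no distributional structure in its weights. A property test
confirms such models still propagate finite, non-degenerate activations
through every layer, so any failure to predict responses is not a
propagation collapse.

Training (`train_lm()`) is minibatch Adam (β₁ = 0.9, β₂ = 0.999,
ε = 1e−8, fixed learning rate) on uniformly sampled context windows.
Backpropagation is written out by hand in base R matrix algebra and is
checked against central finite differences on a tiny model in the test
suite (agreement ~1e−11). Checkpoints — a full weight copy, the step, the
exact tokens seen, and validation perplexity — are emitted on a
logarithmic schedule (`checkpoint_schedule()`, default multipliers 0,
0.001, 0.01, 0.1, 1, 10 of a base step count); `best_checkpoint()` selects
the smallest validation perplexity, mirroring how trained models are
chosen for evaluation.

Token accounting is exact integer arithmetic:
`tokens_per_step = context × batches × devices × grad_accumulations`,
`tokens_seen = tokens_per_step × steps` (stored as doubles, exact far
beyond these magnitudes), and `steps_for_one_pass()` returns the real
quotient, leaving rounding to the caller.

The tokenizer question is sidestepped by design: synthetic corpora are
integer token streams already, so no claim about byte-pair encodings is
made. For text, `ptb_tokenize()` provides the PTB-style scheme used for
corpus characterization: contractions split at the apostrophe with the
apostrophe discarded (`they're` → `they`, `re`) — following the printed
convention this package adopts rather than classic PTB's `'re` — and
punctuation emitted as stand-alone tokens, case preserved. Whether corpus
statistics should fold case variants together is left to the caller (they
are counted as distinct).

## Perplexity

`sliding_window_perplexity()` implements PPL = 2^H,
H = −(1/N) Σ log₂ P(xᵢ | context), with logs base 2 throughout. Three
conventions needed fixing where common practice varies:

- **Windowing.** With context `C` and stride `s ≤ C`, the first window
  scores positions 2..C; every later window advances by `s` and scores
  only its final `s` positions. Each token after the first is scored
  exactly once, with at least `C − s` tokens of context.
- **The first token is never scored** (it has no context); `N` excludes it.
- **Zero probabilities flag, not fail**: any scored token with P = 0
  yields an `Inf` perplexity with `zero_prob = TRUE` rather than a silent
  `NaN`.

A *scorer* is any function mapping a token window to a matrix whose row
`t` is the next-token distribution given the window through `t`; the
package supplies `lm_scorer()` (a model), `uniform_scorer()` (PPL equals
the vocabulary size, a useful exactness check), and `source_scorer()`
(the generating source itself, whose perplexity converges to
2^entropy-rate — the floor no trained model can beat).

## The neural encoding pipeline

`score_neural_benchmark()` is the model-to-brain comparison. Its
conventions, in pipeline order:

- **Sentence representations** are the activation of the last word of each
  sentence, with multi-token words averaged over their tokens
  (`sentence_representation()`). Trailing punctuation attached to the last
  word joins the average: selection is defined at the word level and no
  punctuation rule is imposed. Sentences are presented to the model in
  isolation by default; callers wanting passage context can prepend it
  when building token lists.
- **Folds** (`make_folds()`) are contiguous, near-equal batches in
  stimulus order; a remainder of `r` items adds one item to each of the
  last `r` folds, so 243 sentences in 5 folds gives 48, 48, 49, 49, 49.
  (A published 384-sentence split of 76, 76, 76, 78, 78 is inconsistent
  with any simple near-equal contiguous rule, which yields 76 + 4 × 77;
  the rule here is therefore validated against the 243-sentence case
  only.)
- **Regression** is ordinary least squares with an intercept, computed on
  centered data via the SVD pseudoinverse (`fit_linear_map()`). With many
  units and few training sentences the system is underdetermined and plain
  OLS is not unique; the pseudoinverse gives the minimum-norm solution,
  the canonical resolution. An optional ridge penalty is exposed but off
  by default. The intercept is required for predictions to match response
  means at all.
- **Scoring**: per fold, per-voxel Pearson correlations between predicted
  and observed held-out responses, averaged across folds
  (`cross_validated_predictivity()`; every test fold must have ≥ 3 items
  for the correlation to be defined). The participant score is the
  *median* over voxels (`participant_score()`), block scores are averaged
  over experiment blocks and divided by the ceiling
  (`combine_and_normalize()`). Even-count medians are the mean of the
  central pair. If a prediction is constant (zero variance), its
  correlation is recorded as 0 with a warning rather than NA, so fold
  averages stay defined.
- **Layer sweep** (`layer_sweep()`): the pipeline per layer, from layer 0
  (the embedding) upward; the best layer is the argmax of the
  participant-median normalized score, ties broken toward the lower layer.

Group-level summaries use the median across participants with the
*unscaled* median absolute deviation (`mad(x, constant = 1)`) as the error
bar — it is an error bar, not a standard-deviation estimate, so the
1.4826 consistency factor would be a category error.

## Reading-time predictivity

`filter_rts()` retains reading times in the inclusive [100, 3000] ms
range: "outside the range" excludes only the strict exterior, so boundary
values survive. Filtering is idempotent and reports how many records it
removed.

`word_folds()` builds per-participant folds under two constraints: within
a sentence, repeated occurrences of the same word *type* share a fold (so
a word never appears on both sides of a train/test split within its
sentence), and each sentence's occurrences are spread across folds as
evenly as possible. The assignment is greedy — largest type-group first,
into the fold with the least load within the sentence, ties broken by
global fold load and then a seeded random draw — and deterministic under
the seed. The same-word constraint is interpreted *within sentence*
rather than globally: a corpus-wide type constraint is unsatisfiable for
function words ("the" would force most of a story into one fold). Users
should know this is an interpretation, not the only possible reading.

`rt_predictivity()` then mirrors the neural pipeline per participant:
cross-validated least squares from word representations (by convention
the last model layer, each word's representation computed from its
sentence up to and including that word, multi-token words averaged) to
RTs, fold-averaged Pearson, divided by the ceiling.

## Synthetic data: what it emulates, and what it does not

The generators exist so every downstream stage has *known* ground truth.

- `generate_corpus()` draws from unigram or first-order Markov sources
  with closed-form entropy rates (`entropy_rate()`, via the stationary
  distribution from an eigen-decomposition). The rough default transition
  matrix (`make_transition_matrix()`, gamma(0.3) rows) gives peaked
  conditionals, so adjacent tokens carry real mutual information for a
  model to learn.
- `generate_neural_benchmark()` produces every participant's voxel
  responses as one *shared* linear readout of a feature matrix plus
  participant-specific i.i.d. Gaussian noise. Sharing the signal while
  varying the noise mirrors the "best possible model of the average
  participant" logic behind ceiling normalization, and Gaussian noise
  keeps the ceiling analytic: √(σ²ₛ/(σ²ₛ+σ²ₙ)) per voxel, the expected
  correlation between the noiseless signal and one participant's noisy
  measurement. The per-benchmark scalar ceiling is the median per-voxel
  analytic ceiling, matching the median-over-voxels score aggregation.
- `generate_reading_times()` makes RTs affine in surprisal plus Gaussian
  noise, with a Bernoulli fraction of trials replaced by artifacts drawn
  uniformly from [0, 100) ∪ (3000, 5000] ms — both sides of the range, so
  the filter is exercised at both boundaries.

What this does *not* emulate: hemodynamics, voxel spatial correlation,
localizer-based voxel selection, non-Gaussian or temporally structured
measurement noise, story-level discourse effects. The Gaussian choice is
a stand-in for an unknown noise structure, not an inference about real
data. Passing the recovery tests therefore shows the *pipeline* is
correct and well-calibrated under its own assumptions — it does not show
that real benchmarks satisfy those assumptions.

## The packaged experiments and their study conditions

`run_scaling_experiment()` trains a 2-layer, 16-unit transformer
(2 heads, 32-unit feedforward, 16-token context) on a 40-type first-order
Markov corpus under token budgets of 10³, 10⁴, and 10⁵ tokens (batch 8 ×
context 16 = 128 tokens/step), 5 replicate seeds per budget, and reports
median validation perplexity and median normalized predictivity of a
fixed synthetic benchmark per budget. The benchmark's voxels are linear
in the source's true next-token log-probabilities given the
sentence-final token (clamped at 12 bits), with noise at 0.6 × the median
signal SD (analytic ceiling ≈ 0.86). The vocabulary (40) deliberately
exceeds the model width (16): a random untrained embedding cannot
linearly encode an arbitrary function of 40 token identities in 16
dimensions, so predicting these responses requires the prediction-relevant
structure that training instills — which is what makes predictivity rise
with the budget rather than being free with the architecture. These sizes
were chosen as the smallest configuration in which all three regimes
(barely trained, partially trained, near-converged) are well separated;
at them the full experiment runs in about a minute on one CPU.

`run_layer_recovery()` trains the same architecture for 800 steps,
generates benchmarks from the activations of one layer at low noise
(0.05 × signal SD) for 150 sentences, 5 participants, 40 voxels, and
checks how often `layer_sweep()` picks that layer across 10 replicate
benchmarks. Low noise and a trained (not random) model are essential:
residual connections keep adjacent layers nearly linearly equivalent, so
the margin between the generating layer (which reaches the ceiling
exactly) and its neighbors (limited by the nonlinearity of the
block map) is small, and the fold-averaged correlation must be estimated
precisely enough to resolve it.

## Numerical choices

- Layer-norm ε = 1e−5; attention softmax subtracts the row maximum before
  exponentiating; scores are scaled by 1/√(d_head); the causal mask sets
  strictly-upper-triangular scores to −∞ before the softmax.
- GELU is exact (`x·Φ(x)`), with derivative `Φ(x) + x·φ(x)`.
- The pseudoinverse truncates singular values below
  `max(dim) · eps · max(d)` — the standard relative tolerance — so exact
  collinearity is handled without exploding weights.
- All generators and the trainer run under `withr::with_seed()`: fixed
  seeds give bit-identical corpora, benchmarks, batches, and weights, and
  the caller's RNG state is never disturbed.
- Degenerate statistical inputs follow explicit contracts: zero pooled
  variance with equal means gives t = 0, p = 1; with unequal means it is
  an error, not a silent ±Inf.

The two-sample t test defaults to the classic pooled-variance form (the
reference analyses state only "independent two-sample t tests");
`var_equal = FALSE` switches to Welch. Tests are two-sided, and
`bonferroni()` is the plain `min(1, p·m)` correction.

## Known limitations

- The LM is CPU-bound base R: ideal up to ~10⁵-token budgets and
  ~10⁵-parameter models, not a route to full-scale training.
- Only unidirectional (causal) attention is implemented; masked-LM
  architectures and pseudo-perplexity are out of scope.
- The encoding pipeline accepts any ceiling constant for real benchmarks
  but does not estimate ceilings from real data by subsampling; the
  analytic ceiling applies to the synthetic generators only.
- Word-fold constraints are satisfied greedily; pathological sentences
  (one word type repeated more than n/k times) can leave fold sizes
  uneven by more than one.
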