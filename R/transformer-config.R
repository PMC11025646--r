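#' Configure a causal transformer language model
#'
#' Architecture follows the GPT-2 family: a learned token embedding plus
#' learned positional embedding, then `n_layers` blocks each consisting of
#' (i) layer normalization, (ii) multi-head causal self-attention, (iii) a
#' second layer normalization, and (iv) a position-wise feedforward layer,
#' with pre-norm residual connections; a final layer normalization and a
#' linear projection map hidden states to next-token probabilities. The
#' full-scale reference configuration is 12 layers of 768 units with a
#' 1,024-token context; desk-scale experiments use far smaller values.
#'
#' @param n_layers Number of transformer blocks.
#' @param d_model Hidden size (must be divisible by `n_heads`).
#' @param n_heads Number of attention heads.
#' @param d_ff Feedforward inner size (default `4 * d_model`).
#' @param context_size Maximum sequence length.
#' @param vocab_size Vocabulary size.
#' @return An object of class `transformer_config`.
#' @export
transformer_config <- function(n_layers = 2L, d_model = 32L, n_heads = 2L,
                               d_ff = 4L * d_model, context_size = 64L,
                               vocab_size = 50L) {
  assert_count(n_layers, "n_layers")
  assert_count(d_model, "d_model")
  assert_count(n_heads, "n_heads")
  assert_count(d_ff, "d_ff")
  assert_count(context_size, "context_size")
  assert_count(vocab_size, "vocab_size", min = 2L)
  assert_that(d_model %% n_heads == 0, "`d_model` must be divisible by `n_heads`")
  structure(
    list(n_layers = as.integer(n_layers), d_model = as.integer(d_model),
         n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
         context_size = as.integer(context_size),
         vocab_size = as.integer(vocab_size)),
    class = "transformer_config"
  )
}

#' Weight-initialization scheme
#'
#' `"default"` is the conventional scaled-normal transformer initialization:
#' embedding, attention, and feedforward weights ~ N(0, 0.02^2), biases 0,
#' layer-norm gain 1 and bias 0. `"gaussian"` sets *every* governed weight —
#' including layer-norm gains and biases — to draws from N(mean, sd^2); with
#' the default mean 0 and sd 0.02 this is the controlled initialization used
#' to probe what an untrained architecture alone can predict.
#'
#' @param name `"default"` or `"gaussian"`.
#' @param mean,sd Parameters of the Gaussian (used by `"gaussian"`).
#' @return An object of class `init_scheme`.
#' @export
init_scheme <- function(name = c("default", "gaussian"), mean = 0, sd = 0.02) {
  assert_that(is.character(name) && name[1] %in% c("default", "gaussian"),
              "unknown initialization scheme")
  name <- match.arg(name)
  assert_number(mean, "mean")
  assert_number(sd, "sd", min = 0)
  structure(list(name = name, mean = mean, sd = sd), class = "init_scheme")
}

#' Training budget with exact token accounting
#'
#' A training step consumes
#' `context_tokens * batches_per_device * n_devices * grad_accumulations`
#' tokens; all products are exact integer arithmetic (stored as doubles,
#' which are exact well beyond the magnitudes involved).
#'
#' @param context_tokens Tokens per sequence.
#' @param batches_per_device Sequences per device per forward pass.
#' @param n_devices Number of devices (default 1).
#' @param grad_accumulations Gradient-accumulation factor (default 1).
#' @param n_steps Number of optimizer steps (default 0; may be set later).
#' @return An object of class `training_budget`.
#' @export
training_budget <- function(context_tokens, batches_per_device,
                            n_devices = 1L, grad_accumulations = 1L,
                            n_steps = 0L) {
  assert_count(context_tokens, "context_tokens")
  assert_count(batches_per_device, "batches_per_device")
  assert_count(n_devices, "n_devices")
  assert_count(grad_accumulations, "grad_accumulations")
  assert_count(n_steps, "n_steps", min = 0L)
  structure(
    list(context_tokens = context_tokens,
         batches_per_device = batches_per_device,
         n_devices = n_devices,
         grad_accumulations = grad_accumulations,
         n_steps = n_steps),
    class = "training_budget"
  )
}

#' Tokens consumed per training step
#' @param budget A [training_budget()].
#' @return Token count per step.
#' @export
tokens_per_step <- function(budget) {
  assert_that(inherits(budget, "training_budget"), "`budget` must be a training_budget")
  budget$context_tokens * budget$batches_per_device *
    budget$n_devices * budget$grad_accumulations
}

#' Total tokens seen over a training run
#'
#' @param budget A [training_budget()].
#' @param n_steps Optional override of the budget's step count.
#' @return `tokens_per_step * n_steps`, exact.
#' @export
tokens_seen <- function(budget, n_steps = NULL) {
  n <- n_steps %||% budget$n_steps
  assert_count(n, "n_steps", min = 0L)
  tokens_per_step(budget) * n
}

#' Training steps needed for one pass over a corpus
#'
#' @param corpus_tokens Total tokens in the corpus.
#' @param budget A [training_budget()].
#' @return `corpus_tokens / tokens_per_step` as a real number; callers round
#'   for reporting.
#' @export
steps_for_one_pass <- function(corpus_tokens, budget) {
  assert_count(corpus_tokens, "corpus_tokens")
  corpus_tokens / tokens_per_step(budget)
}

#' Logarithmic checkpoint schedule
#'
#' Converts a reference step count (defined as "100% of training") and a set
#' of multipliers into a deduplicated, strictly increasing list of integer
#' checkpoint steps. The default multipliers produce checkpoints at 0, 0.1%,
#' 1%, 10%, 100%, and 10x100% of training.
#'
#' @param base_steps Steps corresponding to 100% of training.
#' @param multipliers Ordered nonnegative multipliers.
#' @return An object of class `checkpoint_schedule` with element `steps`.
#' @export
checkpoint_schedule <- function(base_steps,
                                multipliers = c(0, 0.001, 0.01, 0.1, 1, 10)) {
  assert_count(base_steps, "base_steps")
  assert_that(is.numeric(multipliers) && all(is.finite(multipliers)) &&
                all(multipliers >= 0) && !is.unsorted(multipliers),
              "`multipliers` must be ordered nonnegative numbers")
  steps <- unique(round(base_steps * multipliers))
  assert_that(all(diff(steps) > 0), "schedule steps must be strictly increasing")
  structure(list(base_steps = base_steps, multipliers = multipliers,
                 steps = steps),
            class = "checkpoint_schedule")
}
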