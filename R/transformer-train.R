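# Backpropagation and Adam training for the causal transformer. Gradients
# are written out block by block in reverse order of the forward pass; the
# finite-difference test in the test suite checks them against numeric
# derivatives on a tiny model.

zeros_like <- function(x) {
  if (is.list(x)) lapply(x, zeros_like)
  else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
  else numeric(length(x))
}

# Cross-entropy loss (nats per scored position) and parameter gradients for
# a batch of equal-length sequences. Position t of each sequence predicts
# token t + 1; the final position carries no target.
lm_loss_grads <- function(model, tokens) {
  cfg <- model$config; p <- model$params
  tokens <- as_token_matrix(tokens, cfg)
  B <- nrow(tokens); T <- ncol(tokens)
  assert_that(T >= 2, "need at least 2 tokens per sequence to form targets")
  D <- cfg$d_model; H <- cfg$n_heads; dh <- D %/% H
  scale <- 1 / sqrt(dh)

  fw <- forward_pass(model, tokens, want_cache = TRUE)
  logp <- row_log_softmax(fw$logits)
  scored <- rep(seq_len(T) < T, B)          # last position of each sequence unscored
  tgt_flat <- as.vector(t(cbind(tokens[, -1, drop = FALSE], NA_integer_)))
  n_scored <- sum(scored)
  idx <- cbind(which(scored), tgt_flat[scored])
  loss <- -mean(logp[idx])

  grads <- zeros_like(p)
  dlogits <- exp(logp)
  dlogits[!scored, ] <- 0
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / n_scored

  grads$W_out <- crossprod(fw$lnf$y, dlogits)
  grads$b_out <- colSums(dlogits)
  dlnf <- layer_norm_bwd(dlogits %*% t(p$W_out), fw$lnf, p$lnf_g)
  grads$lnf_g <- dlnf$dg; grads$lnf_b <- dlnf$db
  dh_ <- dlnf$dx

  for (l in rev(seq_len(cfg$n_layers))) {
    blk <- p$blocks[[l]]; cache <- fw$caches[[l]]
    g <- grads$blocks[[l]]

    # feedforward branch
    df <- dh_
    g$W_ff2 <- crossprod(cache$gact, df)
    g$b_ff2 <- colSums(df)
    dg_act <- df %*% t(blk$W_ff2)
    du <- dg_act * gelu_grad(cache$u)
    g$W_ff1 <- crossprod(cache$ln2$y, du)
    g$b_ff1 <- colSums(du)
    dln2 <- layer_norm_bwd(du %*% t(blk$W_ff1), cache$ln2, blk$ln2_g)
    g$ln2_g <- dln2$dg; g$ln2_b <- dln2$db
    dh_ <- dh_ + dln2$dx                     # residual + branch

    # attention branch
    dattn <- dh_
    g$W_o <- crossprod(cache$O, dattn)
    g$b_o <- colSums(dattn)
    dO <- dattn %*% t(blk$W_o)
    dqkv <- matrix(0, B * T, 3 * D)
    for (b in seq_len(B)) {
      rows <- ((b - 1) * T + 1):(b * T)
      for (hd in seq_len(H)) {
        cols <- ((hd - 1) * dh + 1):(hd * dh)
        A <- cache$A_list[[(b - 1) * H + hd]]
        Q <- cache$qkv[rows, cols, drop = FALSE]
        K <- cache$qkv[rows, D + cols, drop = FALSE]
        Vm <- cache$qkv[rows, 2 * D + cols, drop = FALSE]
        dOh <- dO[rows, cols, drop = FALSE]
        dA <- tcrossprod(dOh, Vm)
        dV <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dqkv[rows, cols] <- dS %*% K * scale
        dqkv[rows, D + cols] <- crossprod(dS, Q) * scale
        dqkv[rows, 2 * D + cols] <- dV
      }
    }
    g$W_qkv <- crossprod(cache$ln1$y, dqkv)
    g$b_qkv <- colSums(dqkv)
    dln1 <- layer_norm_bwd(dqkv %*% t(blk$W_qkv), cache$ln1, blk$ln1_g)
    g$ln1_g <- dln1$dg; g$ln1_b <- dln1$db
    dh_ <- dh_ + dln1$dx
    grads$blocks[[l]] <- g
  }

  grads$emb <- rowsum_into(dh_, fw$flat, nrow(p$emb))
  grads$pos <- rowsum_into(dh_, rep(seq_len(T), B), nrow(p$pos))
  list(loss = loss, grads = grads)
}

rowsum_into <- function(M, index, n_out) {
  out <- matrix(0, n_out, ncol(M))
  rs <- rowsum(M, group = index)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Flatten/apply over the nested parameter list in a fixed order.
map_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map_params(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-2,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  delta <- map_params(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- map_params(params, delta, `-`)
  list(params = params, state = state)
}

#' Train a transformer language model with checkpointing
#'
#' Runs minibatch Adam on randomly positioned context windows from a token
#' corpus, emitting a checkpoint (a full copy of the weights, the step
#' number, the exact number of tokens seen, and the validation perplexity)
#' at every scheduled step. Step 0 corresponds to the untrained model.
#'
#' @param model A [init_lm()] model.
#' @param corpus Integer token vector (ids in `1..vocab_size`), longer than
#'   the training context.
#' @param n_steps Number of optimizer steps; defaults to the largest
#'   scheduled step.
#' @param schedule A [checkpoint_schedule()], or `NULL` to checkpoint only at
#'   step 0 and the final step.
#' @param validation Optional integer token vector used to compute validation
#'   perplexity at each checkpoint (sliding-window, stride = context / 2).
#'   Defaults to a held-out tail of `corpus` (the tail is then excluded from
#'   training windows).
#' @param batch_size Sequences per step.
#' @param context Tokens per sequence (default: the model's context size).
#' @param lr Adam learning rate.
#' @param seed Integer seed driving window sampling; training is
#'   deterministic given model and seed.
#' @return An object of class `lm_training`: a list with `checkpoints` (each
#'   with `model`, `step`, `tokens_seen`, `val_ppl`, `train_loss`), the final
#'   `model`, and a `history` tibble.
#' @export
train_lm <- function(model, corpus, n_steps = NULL, schedule = NULL,
                     validation = NULL, batch_size = 8L, context = NULL,
                     lr = 1e-2, seed = 1L) {
  assert_that(inherits(model, "transformer_lm"), "`model` must be a transformer_lm")
  assert_that(length(corpus) >= 2, "`corpus` must be a non-empty token vector")
  cfg <- model$config
  context <- as.integer(context %||% cfg$context_size)
  assert_that(context >= 2 && context <= cfg$context_size,
              "`context` must be in 2..context_size")
  corpus <- as.integer(corpus)
  assert_that(all(corpus >= 1 & corpus <= cfg$vocab_size),
              "corpus token ids must lie in 1..vocab_size")

  if (is.null(validation)) {
    n_val <- min(2048L, max(context + 1L, length(corpus) %/% 5L))
    assert_that(length(corpus) > n_val + context + 1L,
                "`corpus` too short to split off a validation tail")
    validation <- tail(corpus, n_val)
    corpus <- head(corpus, length(corpus) - n_val)
  }
  assert_that(length(corpus) > context, "`corpus` must be longer than the context")

  sched_steps <- if (!is.null(schedule)) {
    assert_that(inherits(schedule, "checkpoint_schedule"), "`schedule` must be a checkpoint_schedule")
    schedule$steps
  } else NULL
  n_steps <- as.integer(n_steps %||% max(sched_steps %||% 0L))
  if (is.null(sched_steps)) sched_steps <- unique(c(0L, n_steps))
  sched_steps <- sched_steps[sched_steps <= n_steps]

  tokens_per_step <- batch_size * context
  params <- model$params
  opt <- adam_init(params)
  checkpoints <- list()
  losses <- numeric(n_steps)
  recent_loss <- NA_real_

  snapshot <- function(step) {
    snap_model <- model; snap_model$params <- params
    val_ppl <- sliding_window_perplexity(
      lm_scorer(snap_model), validation,
      context_size = context, stride = max(1L, context %/% 2L))$PPL
    list(model = snap_model, step = step,
         tokens_seen = tokens_per_step * step,
         val_ppl = val_ppl, train_loss = recent_loss)
  }

  with_seed(seed, {
    if (0L %in% sched_steps) checkpoints[[length(checkpoints) + 1L]] <- snapshot(0L)
    max_start <- length(corpus) - context + 1L
    for (step in seq_len(n_steps)) {
      starts <- sample.int(max_start, batch_size, replace = TRUE)
      batch <- t(vapply(starts, function(s) corpus[s:(s + context - 1L)],
                        integer(context)))
      lg <- lm_loss_grads(`class<-`(list(config = cfg, params = params),
                                    "transformer_lm"), batch)
      losses[step] <- lg$loss
      recent_loss <- lg$loss
      upd <- adam_step(params, lg$grads, opt, lr = lr)
      params <- upd$params; opt <- upd$state
      if (step %in% sched_steps) {
        checkpoints[[length(checkpoints) + 1L]] <- snapshot(step)
      }
    }
  })

  final <- model; final$params <- params
  history <- tibble::tibble(
    step = vapply(checkpoints, `[[`, numeric(1), "step"),
    tokens_seen = vapply(checkpoints, `[[`, numeric(1), "tokens_seen"),
    val_ppl = vapply(checkpoints, `[[`, numeric(1), "val_ppl"),
    train_loss = vapply(checkpoints, `[[`, numeric(1), "train_loss")
  )
  structure(list(checkpoints = checkpoints, model = final,
                 history = history, losses = losses,
                 tokens_per_step = tokens_per_step),
            class = "lm_training")
}

#' @export
print.lm_training <- function(x, ...) {
  cat(sprintf("<lm_training> %d checkpoints, %d steps, %s tokens/step\n",
              length(x$checkpoints), length(x$losses),
              format(x$tokens_per_step, big.mark = ",")))
  print(x$history)
  invisible(x)
}

#' Select the checkpoint with the smallest validation perplexity
#'
#' @param training An [train_lm()] result.
#' @return The checkpoint list element (model, step, tokens_seen, val_ppl).
#' @export
best_checkpoint <- function(training) {
  assert_that(inherits(training, "lm_training"), "`training` must be an lm_training")
  vals <- vapply(training$checkpoints, `[[`, numeric(1), "val_ppl")
  training$checkpoints[[which.min(vals)]]
}
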