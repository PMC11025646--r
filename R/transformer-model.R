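# Causal transformer language model: parameter initialization and forward
# pass. Everything is plain R matrices; sequences within a batch are
# processed with shared (row-stacked) position-wise operations and
# per-sequence attention, which is efficient at the desk scales this
# package targets.

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

add_bias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

layer_norm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv_std <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv_std
  list(y = add_bias(sweep(xhat, 2, g, `*`), b),
       xhat = xhat, inv_std = inv_std)
}

layer_norm_bwd <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv_std * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

#' Initialize a causal transformer language model
#'
#' Two schemes are supported (see [init_scheme()]): the conventional
#' scaled-normal initialization (`"default"`), and a fully Gaussian scheme in
#' which every governed weight — layer-norm, self-attention, and feedforward
#' included — is drawn from N(mean, sd^2). Initialization is bit-identical
#' under a fixed seed.
#'
#' @param config A [transformer_config()].
#' @param scheme An [init_scheme()].
#' @param seed Integer seed.
#' @return An object of class `transformer_lm`.
#' @export
init_lm <- function(config, scheme = init_scheme("default"), seed = 1L) {
  assert_that(inherits(config, "transformer_config"), "`config` must be a transformer_config")
  assert_that(inherits(scheme, "init_scheme"), "`scheme` must be an init_scheme")
  D <- config$d_model; V <- config$vocab_size; C <- config$context_size
  F <- config$d_ff
  gaussian <- scheme$name == "gaussian"
  params <- with_seed(seed, {
    w <- function(nr, nc) matrix(rnorm(nr * nc, mean = if (gaussian) scheme$mean else 0,
                                       sd = if (gaussian) scheme$sd else 0.02), nr, nc)
    vec <- function(n, default) {
      if (gaussian) rnorm(n, scheme$mean, scheme$sd) else rep(default, n)
    }
    blocks <- lapply(seq_len(config$n_layers), function(l) {
      list(ln1_g = vec(D, 1), ln1_b = vec(D, 0),
           W_qkv = w(D, 3 * D), b_qkv = vec(3 * D, 0),
           W_o = w(D, D), b_o = vec(D, 0),
           ln2_g = vec(D, 1), ln2_b = vec(D, 0),
           W_ff1 = w(D, F), b_ff1 = vec(F, 0),
           W_ff2 = w(F, D), b_ff2 = vec(D, 0))
    })
    list(emb = w(V, D), pos = w(C, D), blocks = blocks,
         lnf_g = vec(D, 1), lnf_b = vec(D, 0),
         W_out = w(D, V), b_out = vec(V, 0))
  })
  structure(list(config = config, scheme = scheme, seed = as.integer(seed),
                 params = params),
            class = "transformer_lm")
}

#' @export
print.transformer_lm <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf(
    "<transformer_lm> %d layers, d_model %d, %d heads, context %d, vocab %d (%s init, %s parameters)\n",
    cfg$n_layers, cfg$d_model, cfg$n_heads, cfg$context_size, cfg$vocab_size,
    x$scheme$name, format(n_par, big.mark = ",")))
  invisible(x)
}

as_token_matrix <- function(tokens, config) {
  if (is.vector(tokens)) tokens <- matrix(as.integer(tokens), nrow = 1)
  assert_that(is.matrix(tokens) && ncol(tokens) >= 1, "`tokens` must be non-empty")
  assert_that(ncol(tokens) <= config$context_size,
              "sequence length exceeds the model context size")
  assert_that(all(tokens >= 1 & tokens <= config$vocab_size),
              "token ids must lie in 1..vocab_size")
  tokens
}

# Full forward pass over a batch of equal-length sequences. Rows of all
# position-wise matrices are sequence-major: row (b - 1) * T + t is position
# t of sequence b. Returns logits plus (optionally) the caches needed for
# backpropagation and the per-layer residual-stream activations.
forward_pass <- function(model, tokens, want_cache = FALSE, want_layers = FALSE) {
  cfg <- model$config
  p <- model$params
  tokens <- as_token_matrix(tokens, cfg)
  B <- nrow(tokens); T <- ncol(tokens)
  D <- cfg$d_model; H <- cfg$n_heads; dh <- D %/% H
  scale <- 1 / sqrt(dh)
  flat <- as.vector(t(tokens))              # sequence-major token ids
  h <- p$emb[flat, , drop = FALSE] + p$pos[rep(seq_len(T), B), , drop = FALSE]
  layers <- if (want_layers) vector("list", cfg$n_layers + 1L)
  if (want_layers) layers[[1]] <- h
  caches <- if (want_cache) vector("list", cfg$n_layers)
  mask <- upper.tri(matrix(0, T, T))

  for (l in seq_len(cfg$n_layers)) {
    blk <- p$blocks[[l]]
    h_in_attn <- h
    ln1 <- layer_norm_fwd(h, blk$ln1_g, blk$ln1_b)
    qkv <- add_bias(ln1$y %*% blk$W_qkv, blk$b_qkv)
    O <- matrix(0, B * T, D)
    A_list <- if (want_cache) vector("list", B * H)
    for (b in seq_len(B)) {
      rows <- ((b - 1) * T + 1):(b * T)
      for (hd in seq_len(H)) {
        cols <- ((hd - 1) * dh + 1):(hd * dh)
        Q <- qkv[rows, cols, drop = FALSE]
        K <- qkv[rows, D + cols, drop = FALSE]
        Vm <- qkv[rows, 2 * D + cols, drop = FALSE]
        S <- tcrossprod(Q, K) * scale
        S[mask] <- -Inf
        S <- S - apply(S, 1, max)
        A <- exp(S)
        A <- A / rowSums(A)
        O[rows, cols] <- A %*% Vm
        if (want_cache) A_list[[(b - 1) * H + hd]] <- A
      }
    }
    attn_out <- add_bias(O %*% blk$W_o, blk$b_o)
    h <- h + attn_out
    h_in_ff <- h
    ln2 <- layer_norm_fwd(h, blk$ln2_g, blk$ln2_b)
    u <- add_bias(ln2$y %*% blk$W_ff1, blk$b_ff1)
    gact <- gelu(u)
    ff <- add_bias(gact %*% blk$W_ff2, blk$b_ff2)
    h <- h + ff
    if (want_layers) layers[[l + 1L]] <- h
    if (want_cache) {
      caches[[l]] <- list(h_in_attn = h_in_attn, ln1 = ln1, qkv = qkv,
                          A_list = A_list, O = O, h_in_ff = h_in_ff,
                          ln2 = ln2, u = u, gact = gact)
    }
  }
  lnf <- layer_norm_fwd(h, p$lnf_g, p$lnf_b)
  logits <- add_bias(lnf$y %*% p$W_out, p$b_out)
  list(logits = logits, tokens = tokens, B = B, T = T,
       flat = flat, h_final = h, lnf = lnf,
       caches = caches, layers = layers)
}

row_log_softmax <- function(logits) {
  mx <- apply(logits, 1, max)
  z <- logits - mx
  z - log(rowSums(exp(z)))
}

#' Per-position next-token log-probabilities
#'
#' Runs the model on a single token sequence and returns, for every position
#' `t`, the natural-log probability distribution over the next token given
#' tokens `1..t`. Each row exponentiates to a distribution summing to 1, and
#' row `t` depends only on tokens at positions `<= t` (causal attention).
#'
#' @param model A [init_lm()] model.
#' @param tokens Integer vector of token ids in `1..vocab_size`, length at
#'   most `context_size`.
#' @return A `length(tokens) x vocab_size` matrix of log-probabilities.
#' @export
forward_logits <- function(model, tokens) {
  assert_that(is.numeric(tokens) && length(tokens) >= 1, "`tokens` must be non-empty")
  fw <- forward_pass(model, matrix(as.integer(tokens), nrow = 1))
  row_log_softmax(fw$logits)
}

#' Residual-stream activations at every layer
#'
#' Returns `n_layers + 1` matrices of shape `length(tokens) x d_model`:
#' element 1 ("layer 0") is the embedding output (token plus positional
#' embedding), and element `l + 1` is the residual stream after transformer
#' block `l`. Deterministic, and causal: activations at position `t` do not
#' depend on later tokens at any layer.
#'
#' @inheritParams forward_logits
#' @return A list of class `activation_set`.
#' @export
layer_activations <- function(model, tokens) {
  assert_that(is.numeric(tokens) && length(tokens) >= 1, "`tokens` must be non-empty")
  fw <- forward_pass(model, matrix(as.integer(tokens), nrow = 1),
                     want_layers = TRUE)
  structure(fw$layers, class = "activation_set",
            n_layers = model$config$n_layers)
}
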