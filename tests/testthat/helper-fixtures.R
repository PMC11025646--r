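# Shared builders for the test suite. All fixtures are generated in code
# under fixed seeds; nothing is read from disk.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_layers = 2L, d_model = 16L, n_heads = 2L, d_ff = 32L,
         context_size = 16L, vocab_size = 20L),
    list(...))
  do.call(transformer_config, args)
}

tiny_model <- function(seed = 1L, ...) {
  init_lm(tiny_config(...), init_scheme("default"), seed = seed)
}

# A rough, sparse-ish transition matrix: rows are Dirichlet-like with small
# concentration, giving a source whose next-token distribution varies
# strongly with the previous token.
make_markov <- function(V, seed = 42L, shape = 0.3) {
  withr::with_seed(seed, {
    T <- matrix(rgamma(V * V, shape) + 1e-6, V)
    T / rowSums(T)
  })
}

# Stationary distribution by power iteration: the independent oracle against
# the eigen-decomposition route used by the package.
stationary_by_power <- function(T, iters = 5000) {
  p <- rep(1 / nrow(T), nrow(T))
  for (i in seq_len(iters)) p <- drop(p %*% T)
  p / sum(p)
}

# Sentences drawn from a Markov source, as lists of token vectors.
make_sentences <- function(V, Tm, n, len, seed0 = 2000L) {
  lapply(seq_len(n), function(i) {
    generate_corpus(corpus_spec(V, 1L, Tm, total_tokens = len,
                                seed = seed0 + i))$tokens
  })
}

# Straight-line reimplementation of one fold of the encoding pipeline:
# explicit loops and an explicit pseudoinverse, kept deliberately independent
# of the package's vectorized path.
oracle_cv_predictivity <- function(X, Y, assignment) {
  k <- max(assignment)
  n_vox <- ncol(Y)
  r_sum <- rep(0, n_vox)
  for (f in seq_len(k)) {
    train <- which(assignment != f)
    test <- which(assignment == f)
    Xtr <- X[train, , drop = FALSE]
    Ytr <- Y[train, , drop = FALSE]
    xm <- colMeans(Xtr); ym <- colMeans(Ytr)
    Xc <- sweep(Xtr, 2, xm)
    s <- svd(Xc)
    keep <- s$d > max(dim(Xc)) * .Machine$double.eps * max(s$d)
    Winv <- s$v[, keep, drop = FALSE] %*%
      diag(1 / s$d[keep], sum(keep)) %*% t(s$u[, keep, drop = FALSE])
    B <- Winv %*% sweep(Ytr, 2, ym)
    for (v in seq_len(n_vox)) {
      pred <- numeric(length(test))
      for (ti in seq_along(test)) {
        pred[ti] <- sum((X[test[ti], ] - xm) * B[, v]) + ym[v]
      }
      r_sum[v] <- r_sum[v] + cor(pred, Y[test, v])
    }
  }
  r_sum / k
}
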