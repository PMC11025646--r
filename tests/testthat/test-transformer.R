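test_that("gaussian initialization has the requested moments and is deterministic", {
  cfg <- tiny_config(d_model = 64L, d_ff = 128L, vocab_size = 40L)
  m <- init_lm(cfg, init_scheme("gaussian", mean = 0, sd = 0.02), seed = 5)
  w <- as.vector(m$params$blocks[[1]]$W_qkv)   # >= 10^4 attention weights
  expect_gte(length(w), 1e4)
  expect_lt(abs(mean(w)), 3 * 0.02 / sqrt(length(w)))
  expect_lt(abs(sd(w) - 0.02) / 0.02, 0.05)
  # layer-norm gains are drawn from the same distribution, not set to 1
  expect_false(any(m$params$blocks[[1]]$ln1_g == 1))

  m2 <- init_lm(cfg, init_scheme("gaussian", mean = 0, sd = 0.02), seed = 5)
  expect_identical(m$params, m2$params)

  m0 <- init_lm(cfg, init_scheme("gaussian", mean = 0, sd = 0), seed = 5)
  expect_true(all(rapply(m0$params, function(x) all(x == 0), how = "unlist")))

  expect_error(init_scheme("xavier"), "unknown")
})

test_that("per-position distributions are normalized and the minimal input works", {
  m <- tiny_model(seed = 2)
  logp <- forward_logits(m, c(3, 1, 7, 7, 2))
  expect_equal(dim(logp), c(5L, 20L))
  expect_equal(rowSums(exp(logp)), rep(1, 5), tolerance = 1e-6)

  one <- forward_logits(m, 5)
  expect_equal(dim(one), c(1L, 20L))
  expect_equal(sum(exp(one)), 1, tolerance = 1e-6)

  expect_error(forward_logits(m, c(1, 21)), "vocab_size")
  expect_error(forward_logits(m, integer(0)), "non-empty")
  expect_error(forward_logits(m, 1:17), "context size")
})

test_that("causal masking: positions before a perturbation are invariant everywhere", {
  m <- tiny_model(seed = 3)
  toks <- c(4, 9, 1, 14, 6, 2, 11, 5)
  toks2 <- toks; toks2[6] <- 17
  lp1 <- forward_logits(m, toks); lp2 <- forward_logits(m, toks2)
  expect_lt(max(abs(lp1[1:5, ] - lp2[1:5, ])), 1e-6)
  expect_gt(max(abs(lp1[6:8, ] - lp2[6:8, ])), 1e-6)

  a1 <- layer_activations(m, toks); a2 <- layer_activations(m, toks2)
  for (l in seq_along(a1)) {
    expect_lt(max(abs(a1[[l]][1:5, ] - a2[[l]][1:5, ])), 1e-6)
  }
})

test_that("layer activations have n_layers + 1 entries, layer 0 the embedding", {
  m <- tiny_model(seed = 4, n_layers = 3L)
  toks <- c(2, 8, 15)
  acts <- layer_activations(m, toks)
  expect_length(acts, 4L)
  emb <- m$params$emb[toks, ] + m$params$pos[1:3, ]
  expect_equal(acts[[1]], emb)
  expect_identical(acts, layer_activations(m, toks))
  expect_true(all(vapply(acts, function(a) all(is.finite(a)), logical(1))))
})

test_that("a fully gaussian-initialized untrained model still propagates finite activations", {
  m <- init_lm(tiny_config(n_layers = 4L),
               init_scheme("gaussian", 0, 0.02), seed = 9)
  acts <- layer_activations(m, withr::with_seed(2, sample.int(20, 16, replace = TRUE)))
  expect_true(all(vapply(acts, function(a) all(is.finite(a)), logical(1))))
  expect_true(all(vapply(acts, function(a) sd(a) > 0, logical(1))))
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- transformer_config(n_layers = 2L, d_model = 8L, n_heads = 2L,
                            d_ff = 16L, context_size = 8L, vocab_size = 7L)
  m <- init_lm(cfg, seed = 3)
  toks <- matrix(c(1, 4, 2, 6, 5,
                   2, 3, 3, 1, 7), nrow = 2, byrow = TRUE)
  lg <- lmencode:::lm_loss_grads(m, toks)

  num_grad <- function(set, get, i) {
    eps <- 1e-5
    v <- get(m$params)
    up <- m; up$params <- set(m$params, replace(v, i, v[i] + eps))
    dn <- m; dn$params <- set(m$params, replace(v, i, v[i] - eps))
    (lmencode:::lm_loss_grads(up, toks)$loss -
       lmencode:::lm_loss_grads(dn, toks)$loss) / (2 * eps)
  }
  cases <- list(
    list(get = function(p) p$emb,
         set = function(p, v) { p$emb[] <- v; p },
         ana = lg$grads$emb),
    list(get = function(p) p$blocks[[1]]$W_qkv,
         set = function(p, v) { p$blocks[[1]]$W_qkv[] <- v; p },
         ana = lg$grads$blocks[[1]]$W_qkv),
    list(get = function(p) p$blocks[[2]]$W_ff1,
         set = function(p, v) { p$blocks[[2]]$W_ff1[] <- v; p },
         ana = lg$grads$blocks[[2]]$W_ff1),
    list(get = function(p) p$blocks[[2]]$ln1_g,
         set = function(p, v) { p$blocks[[2]]$ln1_g[] <- v; p },
         ana = lg$grads$blocks[[2]]$ln1_g),
    list(get = function(p) p$lnf_b,
         set = function(p, v) { p$lnf_b[] <- v; p },
         ana = lg$grads$lnf_b)
  )
  withr::with_seed(11, {
    for (cs in cases) {
      idx <- sample(length(cs$ana), min(4, length(cs$ana)))
      num <- vapply(idx, function(i) num_grad(cs$set, cs$get, i), numeric(1))
      expect_equal(num, cs$ana[idx], tolerance = 1e-5)
    }
  })
})
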