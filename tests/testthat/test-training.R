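test_that("token accounting reproduces the printed budget products exactly", {
  expect_identical(tokens_seen(training_budget(1024, 128), 1000), 131072000)
  expect_identical(tokens_seen(training_budget(1024, 128), 2000), 262144000)
  expect_identical(tokens_seen(training_budget(1024, 128), 14250), 1867776000)
  # exact arithmetic: 1024 * 128 * 310000 (the product, not a rounded figure)
  expect_identical(tokens_seen(training_budget(1024, 128), 310000), 40632320000)
  expect_identical(tokens_per_step(training_budget(1024, 8, 16, 4)), 524288)
  expect_identical(tokens_seen(training_budget(1024, 8, 16, 4), 20), 10485760)
  expect_identical(tokens_seen(training_budget(1024, 8, 16, 4), 200), 104857600)
  expect_identical(tokens_seen(training_budget(1024, 8, 16, 4), 200000), 104857600000)
  expect_identical(tokens_seen(training_budget(1024, 8, 16, 4), 0), 0)
})

test_that("steps for one corpus pass match the printed 17.2K figure", {
  b <- training_budget(1024, 8, 16, 4)
  steps <- steps_for_one_pass(9036044288, b)
  expect_equal(signif(steps / 1000, 3), 17.2)
  expect_equal(steps_for_one_pass(524288, b), 1)
  expect_equal(steps_for_one_pass(2048, training_budget(1024, 1)), 2)
})

test_that("the logarithmic checkpoint schedule yields the canonical step list", {
  s <- checkpoint_schedule(20000)
  expect_identical(s$steps, c(0, 20, 200, 2000, 20000, 200000))
  # duplicate multipliers deduplicate; unordered ones are invalid
  expect_identical(checkpoint_schedule(100, c(0, 0, 1))$steps, c(0, 100))
  expect_error(checkpoint_schedule(20000, c(1, 0.5)), "ordered")
})

test_that("training memorizes a single repeated sequence to perplexity ~1", {
  seqv <- withr::with_seed(5, sample.int(20, 32, replace = TRUE))
  m <- tiny_model(seed = 1, context_size = 32L)
  tr <- train_lm(m, rep(seqv, 40), n_steps = 400, batch_size = 4,
                 context = 32, lr = 1e-2, seed = 3,
                 validation = rep(seqv, 8))
  expect_lt(tail(tr$history$val_ppl, 1), 1.1)
})

test_that("validation perplexity on a uniform source approaches vocab size from above", {
  corp <- generate_corpus(corpus_spec(50, 0L, total_tokens = 20000, seed = 2))
  m <- tiny_model(seed = 1, vocab_size = 50L)
  tr <- train_lm(m, corp$tokens, n_steps = 250, batch_size = 8,
                 context = 16, lr = 3e-3, seed = 3)
  final <- tail(tr$history$val_ppl, 1)
  expect_lt(abs(final - 50) / 50, 0.10)
  expect_gt(final, 50)   # approaches the entropy floor from above
})

test_that("checkpoints appear exactly at scheduled steps with exact token counts", {
  corp <- generate_corpus(corpus_spec(20, 1L, make_markov(20), 6000, seed = 4))
  m <- tiny_model(seed = 2)
  sched <- checkpoint_schedule(30, multipliers = c(0, 0.1, 1))
  tr <- train_lm(m, corp$tokens, schedule = sched, batch_size = 4,
                 context = 16, lr = 3e-3, seed = 5)
  expect_identical(tr$history$step, c(0, 3, 30))
  expect_identical(tr$history$tokens_seen, c(0, 3, 30) * 4 * 16)
  expect_true(!is.unsorted(tr$history$tokens_seen))
  # best-checkpoint selection picks the smallest validation perplexity
  bc <- best_checkpoint(tr)
  expect_equal(bc$val_ppl, min(tr$history$val_ppl))

  expect_error(train_lm(m, integer(0)), "non-empty")
})

test_that("training is deterministic under a fixed seed", {
  corp <- generate_corpus(corpus_spec(20, 1L, make_markov(20), 4000, seed = 4))
  m <- tiny_model(seed = 2)
  t1 <- train_lm(m, corp$tokens, n_steps = 10, batch_size = 4, context = 16,
                 lr = 3e-3, seed = 8)
  t2 <- train_lm(m, corp$tokens, n_steps = 10, batch_size = 4, context = 16,
                 lr = 3e-3, seed = 8)
  expect_identical(t1$model$params, t2$model$params)
  expect_identical(t1$history, t2$history)
})

test_that("trained validation perplexity never beats the source entropy floor", {
  Tm <- make_markov(20)
  spec <- corpus_spec(20, 1L, Tm, 30000, seed = 7)
  corp <- generate_corpus(spec)
  m <- tiny_model(seed = 1)
  tr <- train_lm(m, corp$tokens, n_steps = 300, batch_size = 8, context = 16,
                 lr = 3e-3, seed = 2)
  # Monte-Carlo floor: true-source perplexity on the same validation stream
  val <- tail(corp$tokens, 2048)
  floor_ppl <- sliding_window_perplexity(source_scorer(spec), val,
                                         context_size = 16, stride = 8)$PPL
  expect_gt(tail(tr$history$val_ppl, 1), 0.98 * floor_ppl)
})
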