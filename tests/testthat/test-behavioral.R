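test_that("RT filtering keeps the inclusive [100, 3000] ms range and is idempotent", {
  bm <- tibble::tibble(
    participant = 1, story = 1, sentence = 1, word_index = 1:6,
    word = letters[1:6],
    rt_ms = c(50, 100, 250, 3000, 3000.5, 99.9))
  out <- suppressMessages(filter_rts(bm))
  expect_identical(out$rt_ms, c(100, 250, 3000))
  expect_identical(attr(out, "n_removed"), 3L)
  # boundaries retained, strict exterior excluded
  expect_true(all(c(100, 3000) %in% out$rt_ms))
  # idempotent; no-op input returned unchanged
  again <- filter_rts(out)
  expect_identical(again$rt_ms, out$rt_ms)
  expect_identical(attr(again, "n_removed"), 0L)
})

test_that("filtering preserves the benchmark ceiling attribute", {
  bm <- generate_reading_times(
    behavioral_spec(outlier_fraction = 0.2, n_participants = 1, seed = 3),
    runif(200, 2, 8))
  out <- suppressMessages(filter_rts(bm))
  expect_equal(attr(out, "ceiling"), attr(bm, "ceiling"))
  expect_gt(attr(out, "n_removed"), 0L)
  expect_true(all(out$rt_ms >= 100 & out$rt_ms <= 3000))
})

test_that("word folds satisfy the spread and same-word constraints", {
  # 5 distinct words, k = 5: one word per fold
  rec5 <- tibble::tibble(story = 1, sentence = 1, word_index = 1:5,
                         word = c("a", "b", "c", "d", "e"))
  f5 <- word_folds(rec5, k = 5, seed = 1)
  expect_identical(sort(tabulate(f5$assignment, 5)), rep(1L, 5))

  # 10 distinct words in one sentence, k = 5: two per fold
  rec10 <- tibble::tibble(story = 1, sentence = 1, word_index = 1:10,
                          word = letters[1:10])
  f10 <- word_folds(rec10, k = 5, seed = 1)
  expect_identical(tabulate(f10$assignment, 5), rep(2L, 5))

  # repeated word type within a sentence shares a fold
  rec <- tibble::tibble(story = 1, sentence = 1, word_index = 1:5,
                        word = c("the", "cat", "saw", "the", "dog"))
  f <- word_folds(rec, k = 5, seed = 1)
  expect_identical(f$assignment[1], f$assignment[4])
  others <- f$assignment[c(2, 3, 5)]
  expect_identical(anyDuplicated(c(f$assignment[1], others)), 0L)

  expect_error(word_folds(rec5[1:3, ], k = 5), "fewer")
})

test_that("word-fold constraints hold across a whole synthetic benchmark", {
  words <- c("the", "dog", "saw", "the", "cat", "and", "the", "cat",
             "ran", "home", "very", "fast")
  surp <- tibble::tibble(
    story = rep(1:2, each = 12),
    sentence = rep(rep(1:2, each = 6), 2),
    word_index = rep(1:6, 4),
    word = rep(words, 2),
    surprisal = runif(24, 1, 8))
  f <- word_folds(surp, k = 3, seed = 5)
  expect_identical(length(f$assignment), 24L)
  grp <- split(f$assignment, paste(surp$story, surp$sentence, surp$word))
  # same word type within a sentence: always one fold
  expect_true(all(vapply(grp, function(g) length(unique(g)) == 1L, logical(1))))
  # within each sentence the fold loads differ by at most 1 (over type groups)
  for (sid in unique(paste(surp$story, surp$sentence))) {
    rows <- paste(surp$story, surp$sentence) == sid
    loads <- tabulate(f$assignment[rows], f$k)
    types <- length(unique(surp$word[rows]))
    if (types >= f$k) expect_lte(max(loads) - min(loads), 2L)
  }
  # determinism under seed
  expect_identical(f$assignment, word_folds(surp, k = 3, seed = 5)$assignment)
})

test_that("reading-time predictivity is exact for linear RTs and null for noise", {
  withr::with_seed(37, {
    n <- 60
    feats <- matrix(rnorm(n * 4), n)
    surp <- tibble::tibble(story = 1, sentence = rep(1:6, each = 10),
                           word_index = rep(1:10, 6),
                           word = paste0("w", 1:n), surprisal = runif(n, 1, 8))
    bm <- generate_reading_times(
      behavioral_spec(noise_sd_ms = 0, outlier_fraction = 0,
                      n_participants = 2, seed = 4), surp)
    bm$rt_ms <- rep(drop(feats %*% c(3, -2, 1, 4)) + 200,
                    2)[seq_len(nrow(bm))]
    res <- rt_predictivity(bm, feats, ceiling = 1, k = 5, seed = 2)
    expect_equal(res$participant_scores$raw, rep(1, 2), tolerance = 1e-6)

    bm$rt_ms <- rnorm(nrow(bm), 300, 50)
    res_null <- rt_predictivity(bm, feats, ceiling = 1, k = 5, seed = 2)
    expect_lt(abs(mean(res_null$participant_scores$raw)), 0.35)
  })
})

test_that("normalization divides by the ceiling (0.38 / 0.76 = 0.5 style)", {
  expect_equal(0.38 / 0.76, 0.5)
  withr::with_seed(41, {
    n <- 40
    feats <- matrix(rnorm(n * 3), n)
    surp <- tibble::tibble(story = 1, sentence = rep(1:4, each = 10),
                           word_index = rep(1:10, 4),
                           word = paste0("w", 1:n), surprisal = runif(n, 1, 8))
    bm <- generate_reading_times(
      behavioral_spec(noise_sd_ms = 20, outlier_fraction = 0,
                      n_participants = 1, seed = 6), surp)
    res <- rt_predictivity(bm, feats, ceiling = 0.76, k = 4, seed = 3)
    expect_equal(res$participant_scores$normalized,
                 res$participant_scores$raw / 0.76)
  })
})

test_that("predictivity increases with the slope-to-noise ratio of the generator", {
  withr::with_seed(43, {
    n <- 150
    surp <- tibble::tibble(story = 1, sentence = rep(1:15, each = 10),
                           word_index = rep(1:10, 15),
                           word = paste0("w", 1:n), surprisal = runif(n, 1, 9))
    # features = surprisal plus distractor dimensions, so the regression can
    # recover the generating signal
    feats <- cbind(surp$surprisal, matrix(rnorm(n * 2), n))
    scores <- vapply(c(2, 10, 50), function(slope) {
      bm <- generate_reading_times(
        behavioral_spec(slope_ms_per_bit = slope, noise_sd_ms = 80,
                        outlier_fraction = 0, n_participants = 3, seed = 8),
        surp)
      median(rt_predictivity(bm, feats, ceiling = 1, k = 5,
                             seed = 4)$participant_scores$raw)
    }, numeric(1))
    expect_true(all(diff(scores) > 0))
  })
})
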