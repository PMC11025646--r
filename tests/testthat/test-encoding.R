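test_that("sentence representations take the last word, averaging multi-token words", {
  acts <- list(matrix(c(1, 2), 1, 2),
               matrix(c(1, 3, 1, 3), 2, 2))
  rep1 <- sentence_representation(acts, list(1L, c(1L, 2L)))
  expect_equal(rep1[1, ], c(1, 2))
  expect_equal(rep1[2, ], c(2, 2))
  # symmetry: token order within the word does not matter
  rep2 <- sentence_representation(acts, list(1L, c(2L, 1L)))
  expect_equal(rep1, rep2)
  # default: last token of each sentence
  rep3 <- sentence_representation(acts)
  expect_equal(rep3[2, ], acts[[2]][2, ])
  expect_error(sentence_representation(acts, list(1L, 5L)), "out of range")
})

test_that("fold construction gives contiguous near-equal batches with the stated remainder rule", {
  f <- make_folds(243, 5)
  expect_identical(sort(tabulate(f$assignment, 5)), c(48L, 48L, 49L, 49L, 49L))
  expect_identical(tabulate(make_folds(10, 5)$assignment, 5), rep(2L, 5))
  expect_identical(sort(tabulate(make_folds(7, 5)$assignment, 5)),
                   c(1L, 1L, 1L, 2L, 2L))
  # contiguity and complete single-assignment coverage
  expect_true(all(diff(f$assignment) >= 0))
  expect_identical(length(f$assignment), 243L)
  expect_error(make_folds(4, 5), "at least")
})

test_that("least-squares maps recover exact linear structure", {
  withr::with_seed(7, {
    X <- matrix(rnorm(40 * 5), 40)
    # self-regression: identity map, zero residual
    fit <- fit_linear_map(X, X)
    expect_equal(fit$W, diag(5), tolerance = 1e-8)
    expect_equal(predict(fit, X), X, tolerance = 1e-8)

    # orthonormal design recovers the coefficients exactly
    Q <- qr.Q(qr(matrix(rnorm(30 * 4), 30)))
    w <- matrix(rnorm(4 * 3), 4)
    fit2 <- fit_linear_map(Q, Q %*% w)
    expect_equal(predict(fit2, Q), Q %*% w, tolerance = 1e-8)

    # underdetermined: matches the explicit pseudoinverse (minimum norm)
    Xu <- matrix(rnorm(6 * 10), 6)
    Yu <- matrix(rnorm(6 * 2), 6)
    fit3 <- fit_linear_map(Xu, Yu)
    Xc <- scale(Xu, scale = FALSE)
    s <- svd(Xc)
    keep <- s$d > 1e-10
    W_oracle <- s$v[, keep] %*% diag(1 / s$d[keep]) %*% t(s$u[, keep]) %*%
      scale(Yu, scale = FALSE)
    expect_equal(fit3$W, W_oracle, tolerance = 1e-8)
    expect_equal(predict(fit3, Xu), Yu, tolerance = 1e-8)

    expect_error(fit_linear_map(Xu, Yu[1:5, ]), "equal row counts")
    expect_error(fit_linear_map(matrix(c(1, NA), 2, 1), matrix(1:2, 2, 1)),
                 "finite")
  })
})

test_that("cross-validated predictivity is exact for noiseless signal and null for noise", {
  withr::with_seed(11, {
    X <- matrix(rnorm(60 * 6), 60)
    Y <- X %*% matrix(rnorm(6 * 8), 6)
    r <- cross_validated_predictivity(X, Y, make_folds(60, 5))
    expect_equal(r, rep(1, 8), tolerance = 1e-6)

    Ynull <- matrix(rnorm(60 * 200), 60)
    rnull <- cross_validated_predictivity(X, Ynull, make_folds(60, 5))
    expect_lt(abs(mean(rnull)), 2 * sd(rnull) / sqrt(length(rnull)) + 0.05)
    expect_true(all(abs(rnull) <= 1))
  })
  expect_error(
    cross_validated_predictivity(matrix(rnorm(10), 5), matrix(rnorm(5), 5),
                                 make_folds(5, 2)),
    "at least 3 items")
})

test_that("participant scores and ceiling normalization follow the stated conventions", {
  expect_equal(participant_score(rep(0.3, 7)), 0.3)
  expect_equal(participant_score(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(participant_score(c(0.1, 0.2, 0.3, 0.4)), 0.25)
  expect_error(participant_score(c(0.1, 0.2), group = logical(2)), "non-empty")

  expect_equal(combine_and_normalize(c(0.12, 0.20), 0.32), 0.5)
  expect_equal(combine_and_normalize(0.32, 0.32), 1)
  expect_error(combine_and_normalize(0.3, 0), "positive")
})

test_that("predictivity is invariant to voxelwise affine rescaling and common feature scaling", {
  withr::with_seed(13, {
    X <- matrix(rnorm(50 * 5), 50)
    Y <- X %*% matrix(rnorm(5 * 4), 5) + matrix(rnorm(50 * 4), 50)
    folds <- make_folds(50, 5)
    r0 <- cross_validated_predictivity(X, Y, folds)
    Y2 <- sweep(sweep(Y, 2, c(2, 0.5, 3, 10), `*`), 2, c(1, -5, 0, 2), `+`)
    expect_equal(cross_validated_predictivity(X, Y2, folds), r0, tolerance = 1e-8)
    expect_equal(cross_validated_predictivity(3.7 * X, Y, folds), r0, tolerance = 1e-8)
  })
})

test_that("on a synthetic benchmark the pipeline recovers the analytic ceiling", {
  withr::with_seed(17, {
    X <- matrix(rnorm(120 * 12), 120)
    gen <- generate_neural_benchmark(neural_spec(3, 20, noise_sd = 4, seed = 3), X)
    res <- score_neural_benchmark(X, gen$benchmark, k = 5)
    med_ceiling <- median(gen$ground_truth$analytic_ceiling)
    # median per-voxel r approximates the ceiling; normalized score ~ 1
    expect_equal(median(res$per_voxel$r), med_ceiling, tolerance = 0.1)
    expect_equal(res$summary$median, 1, tolerance = 0.15)
    # noiseless benchmark: normalized equals raw (ceiling 1)
    gen0 <- generate_neural_benchmark(neural_spec(2, 6, noise_sd = 0, seed = 4), X)
    res0 <- score_neural_benchmark(X, gen0$benchmark, k = 5)
    expect_equal(res0$participant_scores$raw,
                 res0$participant_scores$normalized)
  })
})

test_that("normalized score decreases with noise and rises to 1 as noise vanishes", {
  withr::with_seed(19, {
    X <- matrix(rnorm(100 * 10), 100)
    raw <- vapply(c(0, 2, 4), function(s) {
      gen <- generate_neural_benchmark(neural_spec(2, 12, noise_sd = s, seed = 5), X)
      median(score_neural_benchmark(X, gen$benchmark, k = 5)$participant_scores$raw)
    }, numeric(1))
    expect_true(all(diff(raw) < 0))
    expect_equal(raw[1], 1, tolerance = 1e-6)
  })
})

test_that("each sentence lands in exactly one test fold across cross-validation", {
  f <- make_folds(37, 5)
  seen <- integer(37)
  for (k in 1:5) seen[f$assignment == k] <- seen[f$assignment == k] + 1L
  expect_identical(seen, rep(1L, 37))
})

test_that("the full pipeline agrees with a straight-line loop/pseudoinverse oracle", {
  withr::with_seed(23, {
    X <- matrix(rnorm(20 * 8), 20)
    Y <- X %*% matrix(rnorm(8 * 10), 8) + 0.5 * matrix(rnorm(20 * 10), 20)
    folds <- make_folds(20, 4)
    r_pkg <- cross_validated_predictivity(X, Y, folds)
    r_oracle <- oracle_cv_predictivity(X, Y, folds$assignment)
    expect_equal(r_pkg, r_oracle, tolerance = 1e-8)
  })
})

test_that("layer sweep scores every layer and recovers the generating layer", {
  withr::with_seed(29, {
    feats <- lapply(1:3, function(l) matrix(rnorm(80 * 10), 80))
    gen <- generate_neural_benchmark(neural_spec(3, 15, noise_sd = 1, seed = 6),
                                     feats[[2]])
    sw <- layer_sweep(feats, gen$benchmark, k = 5)
    expect_identical(nrow(sw), 3L)
    expect_identical(sw$layer, 0:2)
    expect_identical(best_layer(sw), 1L)

    # single layer: trivially best
    sw1 <- layer_sweep(feats[1], gen$benchmark, k = 5)
    expect_identical(best_layer(sw1), 0L)
  })
})

test_that("voxel-group breakdowns score each group separately", {
  withr::with_seed(31, {
    X <- matrix(rnorm(60 * 5), 60)
    gen <- generate_neural_benchmark(
      neural_spec(2, 6, noise_sd = 1,
                  voxel_groups = rep(c("LH", "RH"), each = 3), seed = 8), X)
    res <- score_neural_benchmark(X, gen$benchmark)
    expect_setequal(unique(res$group_scores$voxel_group), c("LH", "RH"))
    expect_identical(nrow(res$group_scores), 4L)   # 2 participants x 2 groups
  })
})
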