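# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg, class = "lmencode_error")
  invisible(TRUE)
}

assert_count <- function(x, name, min = 1L) {
  assert_that(
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x),
    sprintf("`%s` must be a single integer >= %d", name, min)
  )
}

assert_number <- function(x, name, min = -Inf, max = Inf) {
  assert_that(
    is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x <= max,
    sprintf("`%s` must be a single finite number in [%s, %s]", name, min, max)
  )
}

assert_prob_vector <- function(p, name, tol = 1e-9) {
  assert_that(is.numeric(p) && all(is.finite(p)) && all(p >= 0),
              sprintf("`%s` must be a nonnegative numeric vector", name))
  assert_that(abs(sum(p) - 1) <= tol,
              sprintf("`%s` must sum to 1 (within %g)", name, tol))
}

assert_stochastic_matrix <- function(T, name, tol = 1e-9) {
  assert_that(is.matrix(T) && nrow(T) == ncol(T),
              sprintf("`%s` must be a square matrix", name))
  assert_that(all(is.finite(T)) && all(T >= 0),
              sprintf("`%s` must have nonnegative finite entries", name))
  assert_that(all(abs(rowSums(T) - 1) <= tol),
              sprintf("`%s` rows must each sum to 1 (within %g)", name, tol))
}

# Pearson correlation that tolerates degenerate (zero-variance) inputs:
# returns 0 with a warning rather than NA, so fold averages stay defined.
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    rlang::warn("zero-variance input to correlation; returning 0",
                .frequency = "once", .frequency_id = "lmencode_safe_cor")
    return(0)
  }
  cor(x, y)
}

# Moore-Penrose pseudoinverse via SVD with a relative tolerance, so that
# underdetermined least-squares problems get the minimum-norm solution.
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Run code under a local RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
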