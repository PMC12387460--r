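# Covariance pooling: flattening, covariance forms, trace normalization,
# Newton-Schulz square root vs the eigendecomposition oracle, and
# vectorization.

test_that("flatten_spatial uses row-major spatial order and round-trips", {
  x <- array(0, dim = c(2, 1, 1))
  x[1, 1, 1] <- 3; x[2, 1, 1] <- -7
  f <- flatten_spatial(x)
  expect_equal(f$matrix, matrix(c(3, -7), 2, 1))
  expect_equal(f$n, 1)

  x2 <- array(0, dim = c(1, 2, 2))
  x2[1, 1, ] <- c(1, 2); x2[1, 2, ] <- c(3, 4)
  expect_equal(flatten_spatial(x2)$matrix, matrix(c(1, 2, 3, 4), 1, 4))

  # round trip: reshape the output back and compare bit-exactly
  x3 <- array(rnorm(3 * 4 * 5), dim = c(3, 4, 5))
  m <- flatten_spatial(x3)$matrix
  back <- array(0, dim = dim(x3))
  for (h in 1:4) for (w in 1:5) back[, h, w] <- m[, (h - 1) * 5 + w]
  expect_identical(back, x3)
})

test_that("compute_covariance matches both published forms", {
  # hand-derived case: F = [[1, -1], [0, 0]]
  f <- matrix(c(1, 0, -1, 0), 2, 2)
  cv <- compute_covariance(f)
  expect_equal(cv$matrix, matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(cv$trace_pre_norm, 1)

  # identical columns -> zero matrix
  cv0 <- compute_covariance(matrix(5, 3, 7))
  expect_equal(cv0$matrix, matrix(0, 3, 3))

  # loop form vs matrix form with the centering matrix, 200 random cases
  for (case in 1:200) {
    d <- lungsop:::with_seed(case, sample(2:16, 1))
    n <- lungsop:::with_seed(case + 1000, sample(2:64, 1))
    f <- lungsop:::with_seed(case + 2000, matrix(rnorm(d * n), d, n))
    loop <- matrix(0, d, d)
    mu <- rowMeans(f)
    for (j in seq_len(n)) loop <- loop + tcrossprod(f[, j] - mu)
    loop <- loop / n
    jj <- rep(1, n)
    ibar <- (diag(n) - tcrossprod(jj) / n) / n
    mat_form <- f %*% ibar %*% t(f)
    expect_lt(max_abs_diff(loop, mat_form), 1e-10)
    expect_lt(max_abs_diff(compute_covariance(f)$matrix, mat_form), 1e-10)
  }
})

test_that("trace_normalize scales to unit trace and flags degeneracy", {
  cv <- as_cov_desc(diag(c(3, 1)))
  tn <- lungsop:::trace_normalize(cv)
  expect_equal(tn$matrix, diag(c(0.75, 0.25)))
  expect_equal(tn$trace_pre_norm, 4)

  idn <- lungsop:::trace_normalize(as_cov_desc(diag(5)))
  expect_equal(idn$matrix, diag(5) / 5)
  expect_equal(idn$trace_pre_norm, 5)

  expect_error(lungsop:::trace_normalize(as_cov_desc(matrix(0, 3, 3))),
               class = "lungsop_degenerate_input")
})

test_that("newton_schulz_sqrt matches the scalar recursion on multiples of I", {
  for (d in c(2, 5, 11)) {
    ch <- as_cov_desc(diag(d) / d, trace_pre_norm = 1)
    it <- newton_schulz_sqrt(ch, 5)
    y_scalar <- scalar_ns(1 / d, 5)
    expect_lt(max_abs_diff(it$Y, y_scalar * diag(d)), 1e-12)
    expect_lt(abs(y_scalar - sqrt(1 / d)), 2e-2 * sqrt(1 / d))
  }
})

test_that("newton_schulz_sqrt approaches the eigendecomposition square root", {
  ch <- as_cov_desc(diag(c(0.75, 0.25)))
  it <- newton_schulz_sqrt(ch, 5)
  expect_lt(rel_fro(it$Y, diag(sqrt(c(0.75, 0.25)))), 1e-3)

  # zero iterations return Y_0 unchanged
  it0 <- newton_schulz_sqrt(ch, 0)
  expect_identical(it0$Y, ch$matrix)
  expect_equal(it0$n_iter, 0)
})

test_that("newton_schulz_sqrt warns (not errors) when unconverged", {
  # severely ill-conditioned input converges poorly in 1 iteration
  m <- random_psd_unit_trace(8, cond = 1e6, seed = 4)
  expect_warning(newton_schulz_sqrt(as_cov_desc(m), 1),
                 class = "lungsop_not_converged")
})

test_that("post_compensate restores the original scale", {
  y <- lungsop:::with_seed(1, matrix(rnorm(9), 3, 3))
  expect_identical(post_compensate(y, 1), y)
  expect_equal(post_compensate(y, 0), matrix(0, 3, 3))

  # original C = I_2: C-hat = I/2, sqrt = sqrt(1/2) I, compensated back to I
  ch <- lungsop:::trace_normalize(as_cov_desc(diag(2)))
  it <- newton_schulz_sqrt(ch, 5)
  expect_lt(max_abs_diff(post_compensate(it, ch$trace_pre_norm), diag(2)), 1e-3)
})

test_that("matrix_power_eig is an exact power oracle", {
  expect_equal(matrix_power_eig(as_cov_desc(diag(c(4, 1))), 0.5), diag(c(2, 1)))
  m <- random_psd_unit_trace(6, cond = 50, seed = 3)
  expect_lt(max_abs_diff(matrix_power_eig(as_cov_desc(m), 1), m), 1e-10)
  r <- matrix_power_eig(as_cov_desc(m), 0.5)
  expect_lt(max_abs_diff(r %*% r, m), 1e-8)
})

test_that("second_order_pool composes the full pipeline", {
  # constant map is degenerate -> zero matrix with a warning
  expect_warning(
    z <- second_order_pool(array(2, dim = c(3, 4, 4))),
    class = "lungsop_degenerate_input"
  )
  expect_equal(z, matrix(0, 3, 3))

  # map whose covariance is exactly I_2: columns (+1,+1),(+1,-1),(-1,+1),(-1,-1)
  x <- array(0, dim = c(2, 2, 2))
  x[, 1, 1] <- c(1, 1); x[, 1, 2] <- c(1, -1)
  x[, 2, 1] <- c(-1, 1); x[, 2, 2] <- c(-1, -1)
  expect_lt(max_abs_diff(second_order_pool(x), diag(2)), 1e-3)

  # oracle equivalence on a random map
  xr <- lungsop:::with_seed(8, array(rnorm(8 * 7 * 7), dim = c(8, 7, 7)))
  cv <- compute_covariance(flatten_spatial(xr))
  expect_lt(rel_fro(second_order_pool(xr), matrix_power_eig(cv, 0.5)), 1e-2)
})

test_that("second_order_pool output is symmetric PSD and scale-consistent", {
  x <- lungsop:::with_seed(2, array(rnorm(6 * 5 * 5), dim = c(6, 5, 5)))
  s1 <- second_order_pool(x)
  expect_lt(max(abs(s1 - t(s1))), 1e-5)
  expect_gt(min(eigen(s1, symmetric = TRUE, only.values = TRUE)$values), -1e-5)
  for (k in c(0.5, 2)) {
    cv_k <- compute_covariance(flatten_spatial(x * k))
    cv_1 <- compute_covariance(flatten_spatial(x))
    expect_lt(rel_fro(cv_k$matrix, k^2 * cv_1$matrix), 1e-10)
    expect_lt(rel_fro(second_order_pool(x * k), abs(k) * s1), 1e-6)
  }
})

test_that("five iterations resolve well-conditioned spectra; refinement is monotone", {
  # Five Newton-Schulz iterations resolve eigenvalues holding >= ~5% of the
  # trace to better than 1e-2 relative Frobenius error; smaller trace shares
  # converge only linearly (rate 3/2 per iteration) and need more steps.
  # This property test therefore pins the bound on near-uniform spectra at
  # small d and separately checks monotone refinement and eventual
  # convergence under heavier conditioning.
  for (i in 1:40) {
    d <- lungsop:::with_seed(i, sample(2:8, 1))
    lam <- lungsop:::with_seed(i + 50, runif(d, 0.5, 1))
    m <- lungsop:::with_seed(i + 100, {
      q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
      a <- q %*% (lam * t(q))
      (a + t(a)) / 2 / sum(lam)
    })
    oracle <- matrix_power_eig(as_cov_desc(m), 0.5)
    res <- vapply(1:5, function(k) {
      rel_fro(suppressWarnings(newton_schulz_sqrt(as_cov_desc(m), k))$Y, oracle)
    }, numeric(1))
    expect_lte(res[5], 1e-2)
    expect_true(all(diff(res) <= 1e-9))
  }
  # heavier conditioning: still monotone, and 25 iterations reach the oracle
  m <- random_psd_unit_trace(16, cond = 1e3, seed = 77)
  oracle <- matrix_power_eig(as_cov_desc(m), 0.5)
  expect_lt(rel_fro(suppressWarnings(newton_schulz_sqrt(as_cov_desc(m), 25))$Y,
                    oracle), 1e-2)
})

test_that("sop_vectorize flattens row-major in both modes and round-trips", {
  expect_equal(sop_vectorize(diag(2), "full"), c(1, 0, 0, 1))
  expect_equal(sop_vectorize(diag(2), "upper"), c(1, 0, 1))
  m <- lungsop:::with_seed(5, { a <- matrix(rnorm(16), 4, 4); (a + t(a)) / 2 })
  v <- sop_vectorize(m, "full")
  expect_identical(matrix(v, 4, 4, byrow = TRUE), m)
  # upper mode row-major ordering: first row of the triangle comes first
  expect_equal(sop_vectorize(m, "upper")[1:4], m[1, ])
})
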