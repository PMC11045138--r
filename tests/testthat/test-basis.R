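test_that("identity-mapped DCT-II basis is orthonormal for N up to 64", {
  for (N in c(1:8, 16, 33, 64)) {
    psi <- build_dct_basis(N)$matrix
    expect_lt(max(abs(crossprod(psi) - diag(N))), 1e-8)
  }
})

test_that("DCT entries match the closed form", {
  expect_equal(build_dct_basis(1)$matrix, matrix(1), tolerance = 1e-12)
  # row 1, column 2 of the N = 2 basis: cos(pi/4)
  expect_equal(build_dct_basis(2)$matrix[1, 2], cos(pi / 4),
               tolerance = 1e-12)
  # generic entry against the formula, N = 5
  psi <- build_dct_basis(5)$matrix
  for (n in 1:5) for (k in 2:5)
    expect_equal(psi[n, k],
                 sqrt(2 / 5) * cos(pi * (2 * n - 1) * (k - 1) / 10),
                 tolerance = 1e-12)
  expect_error(build_dct_basis(0))
})

test_that("frequency mapping inserts target periods and conserves size", {
  # identity when no targets
  g0 <- build_frequency_mapping(16, 1, target_periods = numeric(0))
  expect_identical(g0$f_values, as.numeric(1:16))

  # the 100-day target on the 20-minute grid lands at f = 8.3
  g <- build_frequency_mapping(26280, 1 / 72, target_periods = 100)
  expect_true(any(abs(g$f_values - 8.3) < 1e-9))
  expect_length(g$f_values, 26280)

  # conservation: n stays N, added == removed
  g2 <- build_frequency_mapping(720, 1 / 6, target_periods = c(11.3, 23.7),
                                removal_period_ceiling = 1)
  expect_length(g2$f_values, 720)
  expect_equal(sum(!(g2$f_values %in% 1:720)), 2)

  # bounds and ordering invariants
  expect_true(all(g2$f_values >= 1 & g2$f_values <= 720))
  expect_true(all(diff(g2$f_values) > 0))
})

test_that("frequency mapping deduplicates targets already on the grid", {
  # period 2*N*dt/(f-1) with integer f: 120-day record, dt = 1/6, target 30
  # lands exactly on f = 9 and must not be double-counted
  g <- build_frequency_mapping(720, 1 / 6, target_periods = c(30, 23.7),
                               removal_period_ceiling = 1)
  expect_length(g$f_values, 720)
  expect_equal(sum(abs(g$f_values - 9) < 1e-9), 1)
  expect_equal(sum(!(g$f_values %in% 1:720)), 1)  # only 23.7 d was net-added
})

test_that("period/index relation round-trips on the grid", {
  g <- build_frequency_mapping(720, 1 / 6, target_periods = c(11.3, 23.7),
                               removal_period_ceiling = 1)
  per <- grid_periods(g)
  f <- g$f_values
  nz <- f > 1
  expect_lt(max(abs(1 + 2 * g$N * g$dt / per[nz] - f[nz])), 1e-10)
  expect_true(is.infinite(per[f == 1]))
})

test_that("remapping is deterministic in the seed", {
  a <- build_frequency_mapping(720, 1 / 6, target_periods = c(3.3, 7.7),
                               removal_period_ceiling = 1, seed = 42)
  b <- build_frequency_mapping(720, 1 / 6, target_periods = c(3.3, 7.7),
                               removal_period_ceiling = 1, seed = 42)
  d <- build_frequency_mapping(720, 1 / 6, target_periods = c(3.3, 7.7),
                               removal_period_ceiling = 1, seed = 43)
  expect_identical(a$f_values, b$f_values)
  expect_false(identical(a$f_values, d$f_values))
})

test_that("mapping fails when targets exceed removable columns", {
  expect_error(build_frequency_mapping(720, 1 / 6, target_periods = 11.3,
                                       removal_period_ceiling = 0.25),
               "removal ceiling")
})

test_that("mapped basis realizes fractional-index columns as cosines", {
  # identity grid reproduces the plain DCT
  g0 <- build_frequency_mapping(32, 1, target_periods = numeric(0))
  expect_equal(build_mapped_basis(g0)$matrix, build_dct_basis(32)$matrix,
               tolerance = 1e-12)

  # a fractional column is a sampled cosine of its nominal period
  N <- 720; dt <- 1 / 6; P <- 31
  g <- build_frequency_mapping(N, dt, target_periods = P,
                               removal_period_ceiling = 1)
  k <- which(abs(grid_periods(g) - P) < 1e-9)
  col <- build_mapped_basis(g)$matrix[, k]
  tt <- (seq_len(N) - 0.5) * dt
  expected <- sqrt(2 / N) * cos(2 * pi * tt / P)
  expect_lt(max(abs(col - expected)), 1e-8)
})

test_that("column amplitudes are bounded and coherence is reported", {
  g <- small_grid(720, 1 / 6)
  M <- build_mapped_basis(g)$matrix
  expect_lte(max(abs(M)), sqrt(2 / 720) + 1e-12)
  expect_lt(basis_coherence(build_dct_basis(24)), 1e-10)
  mu <- basis_coherence(M)      # sub-Rayleigh insertions correlate strongly
  expect_true(mu > 0 && mu <= 1)
})

test_that("polynomial basis normalizes time and has p = degree + 1 columns", {
  pb0 <- build_polynomial_basis(c(1, 4, 9), max_degree = 0)
  expect_equal(pb0$matrix, matrix(1, 3, 1))

  pb1 <- build_polynomial_basis(c(0, 182.5, 365), max_degree = 1)
  expect_equal(pb1$matrix[, 2], c(-1, 0, 1), tolerance = 1e-12)

  for (deg in 0:3)
    expect_equal(build_polynomial_basis(0:9, deg)$p, deg + 1L)

  expect_warning(build_polynomial_basis(c(1, 1, 1), max_degree = 1),
                 "rank-deficient")
  # evaluation at new times uses the stored affine map
  expect_equal(evaluate_polynomial_basis(pb1, 365 / 2)[1, ], c(1, 0),
               tolerance = 1e-12)
})

test_that("subsample_rows selects rows without materializing a selector", {
  M <- matrix(1:20, 5, 4)
  expect_identical(subsample_rows(M, 1:5), M)
  expect_identical(subsample_rows(M, 2L), M[2, , drop = FALSE])
  expect_identical(dim(subsample_rows(M, c(1L, 4L))), c(2L, 4L))
  expect_error(subsample_rows(M, c(2L, 2L)))
  expect_error(subsample_rows(M, c(4L, 2L)))
  expect_error(subsample_rows(M, 6L))
  # consistent with direct row computation of the dictionary
  g <- small_grid(96, 0.25)
  expect_equal(subsample_rows(build_mapped_basis(g), c(3L, 50L)),
               dct_rows(g, c(3L, 50L)), tolerance = 1e-12)
})
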