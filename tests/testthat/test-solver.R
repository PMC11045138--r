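test_that("residual projector centers, annihilates, and is idempotent", {
  B <- matrix(1, 4, 1)
  P <- residual_projector(B)
  # action on the identity equals I - J/4
  PI <- project_residual(P, diag(4))
  expect_equal(PI, diag(4) - matrix(1 / 4, 4, 4), tolerance = 1e-12)

  set.seed(1)
  B2 <- cbind(1, rnorm(7))
  P2 <- residual_projector(B2)
  expect_lt(max(abs(project_residual(P2, B2))), 1e-10)
  M <- matrix(rnorm(7 * 3), 7)
  expect_lt(max(abs(project_residual(P2, project_residual(P2, M)) -
                      project_residual(P2, M))), 1e-10)
  expect_warning(residual_projector(cbind(1, 1, rnorm(5))), "rank-deficient")
})

test_that("L1-ball projection is exact", {
  expect_equal(project_l1(c(0.2, -0.1), 1), c(0.2, -0.1))   # inside: identity
  v <- c(3, -1, 0.5)
  p <- project_l1(v, 2)
  expect_equal(sum(abs(p)), 2, tolerance = 1e-12)
  expect_equal(project_l1(p, 2), p, tolerance = 1e-12)       # idempotent
  # optimality vs a fine brute-force search on the 2-sphere of the ball
  v2 <- c(1.7, -0.4)
  p2 <- project_l1(v2, 1)
  th <- seq(0, 2 * pi, length.out = 20001)
  cand <- cbind(cos(th), sin(th))
  cand <- cand / rowSums(abs(cand))           # L1-sphere parameterization
  best <- min(colSums((t(cand) - v2)^2))
  expect_lte(sum((p2 - v2)^2), best + 1e-6)
  expect_equal(project_l1(v, 0), c(0, 0, 0))
})

test_that("constrained solver handles degenerate and inactive regimes", {
  set.seed(2)
  A <- matrix(rnorm(36), 6)
  y <- rnorm(6)
  expect_equal(solve_l1_constrained(A, y, 0)$x, rep(0, 6))
  x_ls <- solve(A, y)
  s <- solve_l1_constrained(A, y, sum(abs(x_ls)) * 1.5, tol = 1e-12)
  expect_equal(s$x, x_ls, tolerance = 1e-5)
})

test_that("constrained solutions match the penalized-path oracle", {
  skip_if_not_installed("glmnet")
  # independent oracle: sweep the Lagrangian lasso path, locate the penalty
  # whose solution has ||x||_1 = delta, compare objectives
  for (seed in 1:5) {
    set.seed(seed)
    m <- 6; n <- 6
    A <- matrix(rnorm(m * n), m)
    y <- rnorm(m)
    x_ls <- qr.solve(A, y)
    delta <- 0.4 * sum(abs(x_ls))            # active-constraint regime
    mine <- solve_l1_constrained(A, y, delta, tol = 1e-12)
    l1_at <- function(lam) {
      fit <- glmnet::glmnet(A, y, alpha = 1, lambda = lam, intercept = FALSE,
                            standardize = FALSE, thresh = 1e-14,
                            maxit = 1e7)
      as.numeric(fit$beta)
    }
    lo <- 1e-8; hi <- max(abs(crossprod(A, y))) / m
    for (it in 1:60) {
      mid <- sqrt(lo * hi)
      if (sum(abs(l1_at(mid))) > delta) lo <- mid else hi <- mid
    }
    x_or <- l1_at(sqrt(lo * hi))
    obj_or <- sum((y - A %*% x_or)^2)
    expect_lt(abs(mine$objective - obj_or), 1e-6 * (1 + obj_or))
    expect_lte(sum(abs(mine$x)), delta * (1 + 1e-6))
  }
})

test_that("polynomial recovery equals the least-squares trend", {
  set.seed(3)
  B <- cbind(1, seq(-1, 1, length.out = 9), seq(-1, 1, length.out = 9)^2)
  y <- rnorm(9)
  # x = 0: ordinary least squares
  z <- recover_polynomial(B, y)
  expect_equal(z, unname(stats::lm.fit(B, y)$coefficients),
               tolerance = 1e-10)
  # exact consistent instance
  z0 <- c(2, -1, 0.5)
  expect_equal(recover_polynomial(B, as.numeric(B %*% z0)), z0,
               tolerance = 1e-10)
  # dual-path pseudoinverse agreement: normal equations vs svd route
  A <- matrix(rnorm(9 * 4), 9)
  x <- c(1, 0, -2, 0)
  r <- y - as.numeric(A %*% x)
  z_ne <- as.numeric(solve(crossprod(B), crossprod(B, r)))
  expect_equal(recover_polynomial(B, y, A, x), z_ne, tolerance = 1e-8)
})

test_that("variable projection composes into a full fit", {
  # zero data -> zero fit
  pr0 <- random_problem(10, 8, 2, 1, seed = 4)
  pr0$y <- rep(0, 10)
  f0 <- fit_bpwp(pr0)
  expect_equal(f0$x, rep(0, 8))
  expect_equal(f0$z, c(0, 0), tolerance = 1e-10)

  # noiseless dictionary signal, full sampling: exact recovery at the true
  # budget
  N <- 64
  psi <- build_dct_basis(N)$matrix
  pb <- build_polynomial_basis(seq_len(N), max_degree = 1)
  x_true <- rep(0, N); x_true[c(4, 11)] <- c(3, -2)
  z_true <- c(5, 1.5)
  y <- as.numeric(psi %*% x_true + pb$matrix %*% z_true)
  fit <- fit_bpwp(bpwp_problem(y, psi, pb$matrix, sum(abs(x_true))),
                  tol = 1e-12)
  expect_lt(max(abs(fit$x - x_true)), 1e-4)
  expect_lt(max(abs(fit$z - z_true)), 1e-4)
  expect_equal(fit$objective, sum(fit$residual^2), tolerance = 1e-10)

  # objective is non-increasing in delta (nested feasible sets)
  pr <- random_problem(12, 10, 2, 0, seed = 6)
  objs <- vapply(c(0, 0.5, 1, 2, 4, 8), function(d) {
    pr$delta <- d
    fit_bpwp(pr, tol = 1e-10)$objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-8))
})

test_that("variable projection agrees with the joint-form solver", {
  worst <- 0
  for (i in 1:100) {
    set.seed(i)
    m <- sample(5:20, 1); n <- sample(2:30, 1); p <- sample(0:3, 1)
    pr <- random_problem(m, n, p, delta = runif(1, 0.1, 3), seed = i + 500)
    f <- fit_bpwp(pr, tol = 1e-12)
    j <- joint_fit_oracle(pr, tol = 1e-12)
    worst <- max(worst, abs(f$objective - j$objective) / (1 + j$objective))
  }
  expect_lt(worst, 1e-6)
})

test_that("joint solver degenerates correctly", {
  # delta = 0 reduces to polynomial least squares
  pr <- random_problem(12, 6, 2, 0, seed = 9)
  j <- joint_fit_oracle(pr, tol = 1e-13)
  expect_equal(j$x, rep(0, 6))
  expect_equal(j$z, unname(stats::lm.fit(pr$B, pr$y)$coefficients),
               tolerance = 1e-6)
  # p = 0 reduces to plain basis-pursuit denoising
  pr2 <- random_problem(10, 8, 0, 0.7, seed = 10)
  j2 <- joint_fit_oracle(pr2, tol = 1e-13)
  s2 <- solve_l1_constrained(pr2$A, pr2$y, 0.7, tol = 1e-12)
  expect_lt(abs(j2$objective - s2$objective), 1e-6 * (1 + s2$objective))
  expect_error(joint_fit_oracle(random_problem(60, 10, 1, 1, seed = 1)),
               "limited")
})

test_that("solutions satisfy feasibility and stationarity", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- 15; n <- 25
    A <- matrix(rnorm(m * n), m)
    y <- rnorm(m)
    delta <- runif(1, 0.05, 5)
    s <- solve_l1_constrained(A, y, delta, tol = 1e-12)
    l1 <- sum(abs(s$x))
    expect_lte(l1, delta * (1 + 1e-6))
    if (l1 < delta * (1 - 1e-6)) {
      g <- 2 * crossprod(A, A %*% s$x - y)
      expect_lt(max(abs(g)), 1e-4 * max(1, sqrt(sum(y^2))))
    }
  }
})

test_that("working-set route agrees with the plain route", {
  set.seed(31)
  m <- 40; n <- 300
  A <- matrix(rnorm(m * n), m)
  y <- rnorm(m)
  for (delta in c(0.3, 2, 10)) {
    plain <- solve_l1_constrained(A, y, delta, tol = 1e-12,
                                  working_set = FALSE)
    ws <- solve_l1_constrained(A, y, delta, tol = 1e-12, working_set = TRUE)
    expect_lt(abs(plain$objective - ws$objective),
              1e-6 * (1 + plain$objective))
  }
})

test_that("reconstruction assembles oscillations and trend with filters", {
  N <- 48
  g <- build_frequency_mapping(N, 0.5, target_periods = numeric(0))
  pb <- build_polynomial_basis((seq_len(N) - 1) * 0.5, max_degree = 1)
  fit <- structure(list(x = rep(0, N), z = c(7, 0), delta = 0,
                        objective = 0, residual = numeric(0)),
                   class = "bpwp_fit")
  rec <- reconstruct(fit, g, pb)
  expect_equal(rec$values, rep(7, N), tolerance = 1e-12)

  # keep-nothing filter leaves the trend alone
  fit$x[5] <- 2
  rec_trend <- reconstruct(fit, g, pb, keep = rep(FALSE, N))
  expect_equal(rec_trend$values, rep(7, N), tolerance = 1e-12)

  # full-sampling noiseless fit reconstructs the input
  psi <- build_mapped_basis(g)$matrix
  x_true <- rep(0, N); x_true[c(3, 9)] <- c(2, 1)
  z_true <- c(1, 0.5)
  y <- as.numeric(psi %*% x_true + pb$matrix %*% z_true)
  f2 <- fit_bpwp(bpwp_problem(y, psi, pb$matrix, sum(abs(x_true))),
                 tol = 1e-12)
  rec2 <- reconstruct(f2, g, pb)
  expect_lt(max(abs(rec2$values - y)), 1e-4)
  expect_error(reconstruct(f2, g, pb, keep = TRUE), "length")
})
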