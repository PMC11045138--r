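#' BPWP problem container
#'
#' Bundles the observation vector with the two subsampled dictionaries and
#' the L1 budget: minimize `||y - A x - B z||^2` subject to `||x||_1 <= delta`.
#'
#' @param y Observed m-vector.
#' @param A m x n subsampled oscillation dictionary.
#' @param B m x p subsampled polynomial dictionary (p may be 0 for plain
#'   basis-pursuit denoising).
#' @param delta Nonnegative L1 budget on the oscillation coefficients.
#' @return An object of class `bpwp_problem`.
#' @export
bpwp_problem <- function(y, A, B, delta) {
  y <- as.numeric(y)
  stopifnot(is.matrix(A), nrow(A) == length(y))
  if (is.null(B)) B <- matrix(numeric(0), nrow = length(y), ncol = 0)
  stopifnot(is.matrix(B), nrow(B) == length(y))
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0)
    stop("'delta' must be a single nonnegative number")
  structure(list(y = y, A = A, B = B, delta = as.numeric(delta)),
            class = "bpwp_problem")
}

#' Projector onto the orthogonal complement of a trend's column space
#'
#' Returns the action of `P = I - B B^+` through a rank-revealing orthogonal
#' decomposition of `B`: `P v = v - Q (Q' v)` where `Q` spans the column
#' space. `P` is symmetric, idempotent, and annihilates `B`; it is never
#' materialized as an m x m matrix.
#'
#' @param B m x p matrix (p may be 0).
#' @return An object of class `residual_projector` with fields `Q`
#'   (orthonormal basis, m x rank) and `rank`. Apply it with
#'   [project_residual()].
#' @export
residual_projector <- function(B) {
  stopifnot(is.matrix(B))
  if (ncol(B) == 0) {
    return(structure(list(Q = matrix(numeric(0), nrow(B), 0), rank = 0L,
                          p = 0L),
                     class = "residual_projector"))
  }
  sv <- svd(B)
  tol <- 1e-10 * sv$d[1]
  r <- sum(sv$d > tol)
  if (r < ncol(B))
    warning(sprintf("trend dictionary is rank-deficient (rank %d < %d); projecting onto the attained column space",
                    r, ncol(B)))
  structure(list(Q = sv$u[, seq_len(r), drop = FALSE], rank = as.integer(r),
                 p = ncol(B)),
            class = "residual_projector")
}

#' Apply a residual projector
#'
#' @param proj A `residual_projector`.
#' @param M Vector or matrix with as many rows as the projector.
#' @return `M` minus its component in the trend column space.
#' @export
project_residual <- function(proj, M) {
  stopifnot(inherits(proj, "residual_projector"))
  if (proj$rank == 0L) return(M)
  if (is.matrix(M)) M - proj$Q %*% crossprod(proj$Q, M)
  else as.numeric(M - proj$Q %*% crossprod(proj$Q, M))
}

#' Euclidean projection onto the L1 ball
#'
#' Exact projection of `v` onto `{x : ||x||_1 <= delta}` by the sort-based
#' soft-threshold construction.
#'
#' @param v Numeric vector.
#' @param delta Ball radius (>= 0).
#' @return The projected vector.
#' @export
project_l1 <- function(v, delta) {
  if (delta <= 0) return(numeric(length(v)))
  a <- abs(v)
  if (sum(a) <= delta) return(v)
  u <- sort(a, decreasing = TRUE)
  sv <- cumsum(u)
  rho <- max(which(u > (sv - delta) / seq_along(u)))
  theta <- (sv[rho] - delta) / rho
  sign(v) * pmax(a - theta, 0)
}

# Largest singular value of A by power iteration on A'A (deterministic start).
op_norm <- function(A, iters = 60L, tol = 1e-9) {
  n <- ncol(A)
  if (n == 0) return(0)
  v <- rep(1 / sqrt(n), n)
  s_old <- 0
  for (i in seq_len(iters)) {
    w <- crossprod(A, A %*% v)
    s <- sqrt(sum(w^2))
    if (s == 0) return(0)
    v <- as.numeric(w / s)
    if (abs(sqrt(s) - s_old) < tol * max(1, s_old)) break
    s_old <- sqrt(s)
  }
  sqrt(s)
}

# Accelerated projected gradient (FISTA with function restart) for
#   min ||y - A x||^2  s.t.  ||x||_1 <= delta
# on a fixed column set. Returns the iterate, objective, and iteration count.
fista_l1 <- function(A, y, delta, tol, max_iter, x0 = NULL, L = NULL) {
  n <- ncol(A)
  if (delta <= 0 || n == 0) {
    x <- numeric(n)
    return(list(x = x, objective = sum(y^2), iterations = 0L,
                converged = TRUE))
  }
  if (is.null(L)) L <- 2 * op_norm(A)^2
  if (L <= 0) L <- 1
  x <- if (is.null(x0)) numeric(n) else project_l1(x0, delta)
  zv <- x
  tk <- 1
  r <- y - A %*% x
  obj <- sum(r^2)
  stall <- 0L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    rz <- y - A %*% zv
    g <- -2 * crossprod(A, rz)
    x_new <- project_l1(zv - as.numeric(g) / L, delta)
    r_new <- y - A %*% x_new
    obj_new <- sum(r_new^2)
    if (obj_new > obj) {            # function restart
      zv <- x
      tk <- 1
      rz <- y - A %*% zv
      g <- -2 * crossprod(A, rz)
      x_new <- project_l1(zv - as.numeric(g) / L, delta)
      r_new <- y - A %*% x_new
      obj_new <- sum(r_new^2)
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zv <- x_new + ((tk - 1) / t_new) * (x_new - x)
    rel <- abs(obj - obj_new) / max(1, obj)
    x <- x_new
    obj <- obj_new
    tk <- t_new
    stall <- if (rel < tol) stall + 1L else 0L
    if (stall >= 5L) break
  }
  list(x = as.numeric(x), objective = obj, iterations = it,
       converged = stall >= 5L)
}

#' L1-ball-constrained least squares
#'
#' Solves `min_x ||y - A x||^2` subject to `||x||_1 <= delta` by accelerated
#' projected gradient descent with exact Euclidean projection onto the L1
#' ball. For wide dictionaries a working-set strategy is used: the problem is
#' solved on a subset of columns and the subset grown until the full-problem
#' optimality conditions hold, which leaves the solution unchanged but avoids
#' most full-width matrix products.
#'
#' @param A m x n design matrix.
#' @param y Observed m-vector.
#' @param delta L1 budget (>= 0).
#' @param tol Relative objective tolerance (default 1e-8).
#' @param max_iter Iteration cap for the proximal route (default 50000).
#' @param x0 Optional warm start.
#' @param working_set Use the working-set acceleration; default `TRUE` when
#'   `n > 4000`.
#' @return List with `x`, `objective` (residual sum of squares),
#'   `iterations`, `converged`.
#' @export
solve_l1_constrained <- function(A, y, delta, tol = 1e-8, max_iter = 50000L,
                                 x0 = NULL,
                                 working_set = ncol(A) > 4000) {
  stopifnot(is.matrix(A), nrow(A) == length(y))
  if (tol <= 0) stop("'tol' must be positive")
  if (delta < 0) stop("'delta' must be nonnegative")
  n <- ncol(A)
  if (delta == 0 || n == 0) {
    return(list(x = numeric(n), objective = sum(y^2), iterations = 0L,
                converged = TRUE))
  }
  if (!working_set) {
    res <- fista_l1(A, y, delta, tol, max_iter, x0 = x0)
    if (!res$converged)
      warning(sprintf("L1 solver reached the iteration cap (%d); last relative objective gap above %g",
                      res$iterations, tol))
    return(res)
  }
  # working-set route
  g0 <- abs(as.numeric(crossprod(A, y)))
  W <- order(g0, decreasing = TRUE)[seq_len(min(n, 1500L))]
  if (!is.null(x0)) W <- union(which(x0 != 0), W)
  x <- numeric(n)
  if (!is.null(x0)) x <- project_l1(x0, delta)
  total_it <- 0L
  converged <- FALSE
  for (round in seq_len(30L)) {
    W <- sort(W)
    sub <- fista_l1(A[, W, drop = FALSE], y, delta, tol,
                    max_iter = max_iter, x0 = x[W])
    total_it <- total_it + sub$iterations
    x <- numeric(n)
    x[W] <- sub$x
    r <- y - A[, W, drop = FALSE] %*% sub$x
    g <- as.numeric(crossprod(A, r))           # full gradient/2 (sign flipped)
    l1 <- sum(abs(sub$x))
    scale_g <- max(abs(g), .Machine$double.eps)
    if (l1 < delta * (1 - 1e-8)) {
      # constraint inactive: need gradient ~ 0 everywhere
      viol <- which(abs(g) > 1e-6 * max(1, sqrt(sum(y^2))))
    } else {
      lambda <- max(abs(g[W]))
      viol <- setdiff(which(abs(g) > lambda * (1 + 1e-6) + 1e-12 * scale_g), W)
    }
    if (!length(viol)) { converged <- sub$converged; break }
    ord <- viol[order(abs(g[viol]), decreasing = TRUE)]
    W <- union(W, ord[seq_len(min(500L, length(ord)))])
  }
  obj <- sum((y - A %*% x)^2)
  if (!converged)
    warning("working-set L1 solver stopped before certifying full optimality")
  list(x = x, objective = obj, iterations = total_it, converged = converged)
}

#' Recover the polynomial trend given oscillation coefficients
#'
#' Computes `z = B^+ (y - A x)`, the least-squares trend on the oscillation
#' residual, via an orthogonal decomposition of `B`.
#'
#' @param B m x p trend dictionary.
#' @param y Observed m-vector.
#' @param A m x n oscillation dictionary (ignored when `x` is zero-length).
#' @param x Oscillation coefficients.
#' @return Numeric p-vector `z`.
#' @export
recover_polynomial <- function(B, y, A = NULL, x = NULL) {
  stopifnot(is.matrix(B))
  if (ncol(B) == 0) return(numeric(0))
  r <- y
  if (!is.null(x) && length(x) && any(x != 0)) r <- y - as.numeric(A %*% x)
  sv <- svd(B)
  tol <- 1e-10 * sv$d[1]
  keep <- sv$d > tol
  if (!all(keep))
    warning("rank-deficient trend dictionary in recover_polynomial")
  d_inv <- ifelse(keep, 1 / sv$d, 0)
  as.numeric(sv$v %*% (d_inv * crossprod(sv$u, r)))
}

#' Fit BPWP by variable projection
#'
#' The two-block problem `min_{x,z} ||y - A x - B z||^2, ||x||_1 <= delta`
#' is reduced to a single block by projecting onto the orthogonal complement
#' of the trend column space: solve
#' `min_x ||P (y - A x)||^2, ||x||_1 <= delta` with `P = I - B B^+`, then
#' recover `z = B^+ (y - A x)`.
#'
#' @param problem A [bpwp_problem()].
#' @param tol Relative objective tolerance for the L1 solver (default 1e-8).
#' @param max_iter Iteration cap (default 50000).
#' @param x0 Optional warm start for the oscillation coefficients.
#' @param working_set Passed to [solve_l1_constrained()].
#' @return An object of class `bpwp_fit` with fields `x`, `z`, `delta`,
#'   `objective` (residual sum of squares), `residual`, `iterations`,
#'   `solver_tolerance`, `converged`.
#' @export
fit_bpwp <- function(problem, tol = 1e-8, max_iter = 50000L, x0 = NULL,
                     working_set = ncol(problem$A) > 4000) {
  stopifnot(inherits(problem, "bpwp_problem"))
  P <- residual_projector(problem$B)
  At <- project_residual(P, problem$A)
  yt <- project_residual(P, problem$y)
  sol <- solve_l1_constrained(At, yt, problem$delta, tol = tol,
                              max_iter = max_iter, x0 = x0,
                              working_set = working_set)
  z <- recover_polynomial(problem$B, problem$y, problem$A, sol$x)
  fitted <- as.numeric(problem$A %*% sol$x)
  if (ncol(problem$B)) fitted <- fitted + as.numeric(problem$B %*% z)
  residual <- problem$y - fitted
  structure(list(x = sol$x, z = z, delta = problem$delta,
                 objective = sum(residual^2), residual = residual,
                 iterations = sol$iterations, solver_tolerance = tol,
                 converged = sol$converged),
            class = "bpwp_fit")
}

#' @export
print.bpwp_fit <- function(x, ...) {
  cat(sprintf("<bpwp_fit> delta = %.6g, ||x||_1 = %.6g, %d nonzero of %d, RSS = %.6g\n",
              x$delta, sum(abs(x$x)), sum(x$x != 0), length(x$x),
              x$objective))
  invisible(x)
}

#' Joint-form solver (certification oracle)
#'
#' Solves `min_{x,z} ||y - A x - B z||^2, ||x||_1 <= delta` directly over the
#' stacked variable (projected gradient on the joint block, with the L1
#' projection applied to the oscillation block only), without variable
#' projection. Intended to certify [fit_bpwp()] on small instances; guarded
#' to m, n <= 50.
#'
#' @param problem A [bpwp_problem()] with `m, n <= 50`.
#' @param tol Relative objective tolerance (default 1e-10).
#' @param max_iter Iteration cap.
#' @return List with `x`, `z`, `objective`.
#' @export
joint_fit_oracle <- function(problem, tol = 1e-10, max_iter = 200000L) {
  stopifnot(inherits(problem, "bpwp_problem"))
  m <- length(problem$y)
  n <- ncol(problem$A)
  if (m > 50 || n > 50) stop("joint_fit_oracle is limited to m, n <= 50")
  A <- problem$A; B <- problem$B; y <- problem$y; delta <- problem$delta
  p <- ncol(B)
  C <- cbind(A, B)
  L <- 2 * op_norm(C)^2
  if (L <= 0) L <- 1
  w <- numeric(n + p)
  zv <- w; tk <- 1
  obj <- sum(y^2)
  stall <- 0L
  proj <- function(w) {
    if (n) w[seq_len(n)] <- project_l1(w[seq_len(n)], delta)
    w
  }
  for (it in seq_len(max_iter)) {
    g <- -2 * as.numeric(crossprod(C, y - C %*% zv))
    w_new <- proj(zv - g / L)
    obj_new <- sum((y - C %*% w_new)^2)
    if (obj_new > obj) { zv <- w; tk <- 1; next }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zv <- w_new + ((tk - 1) / t_new) * (w_new - w)
    rel <- abs(obj - obj_new) / max(1, obj)
    w <- w_new; obj <- obj_new; tk <- t_new
    stall <- if (rel < tol) stall + 1L else 0L
    if (stall >= 10L) break
  }
  list(x = w[seq_len(n)], z = if (p) w[n + seq_len(p)] else numeric(0),
       objective = obj)
}

#' Reconstruct the dense underlying series from a fit
#'
#' Computes `s_hat = Psi x' + T z` on the dense grid, where `x'` optionally
#' zeroes coefficients excluded by a filter (for example significant-only, or
#' period longer than two days). Only the columns with nonzero retained
#' coefficients are evaluated, so the full N x n dictionary is never formed.
#'
#' @param fit A `bpwp_fit`.
#' @param grid The `frequency_grid` the fit was computed on.
#' @param poly The dense-grid `polynomial_basis` the fit was computed on.
#' @param keep Optional logical vector (length n) of coefficients to retain;
#'   `NULL` keeps all.
#' @param include_trend Include the polynomial trend (default `TRUE`).
#' @return A `dense_series` on the grid implied by `poly$times`.
#' @export
reconstruct <- function(fit, grid, poly, keep = NULL, include_trend = TRUE) {
  stopifnot(inherits(fit, "bpwp_fit"), inherits(grid, "frequency_grid"),
            inherits(poly, "polynomial_basis"))
  x <- fit$x
  if (!is.null(keep)) {
    if (length(keep) != length(x)) stop("'keep' filter length mismatch")
    x <- ifelse(keep, x, 0)
  }
  N <- grid$N
  tt <- poly$times
  if (length(tt) != N) stop("polynomial basis is not on the dense grid")
  vals <- numeric(N)
  nz <- which(x != 0)
  if (length(nz)) {
    f <- grid$f_values[nz]
    M <- sqrt(2 / N) * cos(outer(2 * seq_len(N) - 1, f - 1) * (pi / (2 * N)))
    dc <- which(abs(f - 1) < 1e-12)
    if (length(dc)) M[, dc] <- M[, dc] / sqrt(2)
    vals <- as.numeric(M %*% x[nz])
  }
  if (include_trend && length(fit$z))
    vals <- vals + as.numeric(poly$matrix %*% fit$z)
  dense_series(vals, t0 = tt[1], dt = if (N > 1) tt[2] - tt[1] else 1)
}

#' Narrowband amplitude spectrum of a fit
#'
#' @param fit A `bpwp_fit`.
#' @param grid The `frequency_grid` the fit was computed on.
#' @return A data frame of class `bpwp_spectrum` with columns `period_days`,
#'   `f`, `amplitude` (|x|), `significant` (all `NA` until
#'   [flag_significant()] fills them), `threshold`.
#' @export
bpwp_spectrum <- function(fit, grid) {
  stopifnot(inherits(fit, "bpwp_fit"), inherits(grid, "frequency_grid"))
  if (length(fit$x) != length(grid$f_values))
    stop("fit and grid dimensions disagree")
  out <- data.frame(period_days = grid_periods(grid), f = grid$f_values,
                    amplitude = abs(fit$x), significant = NA,
                    threshold = NA_real_)
  class(out) <- c("bpwp_spectrum", "data.frame")
  out
}
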