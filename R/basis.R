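#' Orthonormal DCT-II synthesis matrix
#'
#' Builds the N x N orthonormal type-II discrete cosine transform basis.
#' With 1-based column index k, entry (n, k) is
#' `sqrt(2/N) * cos(pi * (2n - 1) * (k - 1) / (2N))`, scaled by `1/sqrt(2)`
#' in the first (DC) column so that the columns are orthonormal.
#'
#' @param N Positive integer, dense grid length.
#' @return An `oscillation_basis` whose `matrix` is the N x N DCT-II basis and
#'   whose `grid` is the identity [frequency_grid()].
#' @examples
#' psi <- build_dct_basis(8)
#' max(abs(crossprod(psi$matrix) - diag(8)))  # orthonormal
#' @export
build_dct_basis <- function(N) {
  grid <- build_frequency_mapping(N = N, dt = 1, target_periods = numeric(0))
  build_mapped_basis(grid)
}

#' Nonuniform DCT frequency grid
#'
#' Constructs the frequency index map f(k) of the remapped DCT dictionary. The
#' identity grid f = 1..N has period resolution proportional to period
#' squared, i.e. sparse coverage of long (multi-day) periods. Each requested
#' target period P inserts the (generally fractional) index
#' `f = 1 + 2 N dt / P`, and an equal number of identity indices whose period
#' falls below `removal_period_ceiling` is removed uniformly at random, so the
#' dictionary stays square (n = N).
#'
#' @param N Dense grid length (number of samples).
#' @param dt Dense grid spacing in days.
#' @param target_periods Periods (days) to guarantee on the grid. Default:
#'   2 to 150 days in 0.5-day steps, truncated to periods representable on
#'   the grid. Use `numeric(0)` for the plain identity grid.
#' @param removal_period_ceiling Identity indices with period strictly below
#'   this many days are eligible for removal (default 0.25 days).
#' @param seed Integer seed controlling which high-frequency indices are
#'   removed.
#' @return An object of class `frequency_grid` with fields `N`, `dt`,
#'   `f_values` (sorted, length N), `target_periods`, `removal_ceiling`,
#'   `seed`.
#' @examples
#' g <- build_frequency_mapping(240, dt = 1/24, target_periods = c(3, 5))
#' range(grid_periods(g))
#' @export
build_frequency_mapping <- function(N, dt,
                                    target_periods = NULL,
                                    removal_period_ceiling = 0.25,
                                    seed = 1L) {
  N <- as.integer(N)
  if (length(N) != 1 || is.na(N) || N < 1) stop("'N' must be a positive integer")
  stopifnot(dt > 0)
  if (is.null(target_periods)) {
    target_periods <- seq(2, 150, by = 0.5)
    # keep only periods the record can actually express
    target_periods <- target_periods[target_periods <= N * dt &
                                       target_periods > 2 * dt]
  }
  if (length(target_periods)) {
    if (any(target_periods > N * dt))
      stop("target periods must not exceed the record length N*dt")
    if (any(target_periods <= 2 * dt))
      stop("target periods must exceed twice the grid spacing")
    if (length(target_periods) &&
        min(target_periods) <= removal_period_ceiling)
      stop("removal ceiling must be shorter than the shortest target period")
  }

  f_identity <- seq_len(N)
  f_new <- 1 + 2 * N * dt / unique(target_periods)
  # drop targets that duplicate an existing grid frequency
  f_new <- setdiff_tol(f_new, f_identity)
  n_add <- length(f_new)

  if (n_add > 0) {
    # identity indices whose period is below the ceiling: period = 2*N*dt/(f-1)
    per_identity <- c(Inf, 2 * N * dt / (f_identity[-1] - 1))
    removable <- which(per_identity < removal_period_ceiling)
    if (length(removable) < n_add)
      stop(sprintf(
        "cannot insert %d target frequencies: only %d identity indices have period below the removal ceiling (%g days)",
        n_add, length(removable), removal_period_ceiling))
    drop_idx <- removable[with_seed(seed, sample.int(length(removable), n_add))]
    f_values <- sort(c(f_identity[-drop_idx], f_new))
  } else {
    f_values <- as.numeric(f_identity)
  }
  stopifnot(length(f_values) == N)
  structure(list(N = N, dt = dt, f_values = f_values,
                 target_periods = as.numeric(target_periods),
                 removal_ceiling = removal_period_ceiling,
                 seed = as.integer(seed)),
            class = "frequency_grid")
}

# numeric setdiff with tolerance for fractional indices landing on integers
setdiff_tol <- function(x, table, tol = 1e-9) {
  keep <- vapply(x, function(v) all(abs(v - table) > tol), logical(1))
  x[keep]
}

#' @export
print.frequency_grid <- function(x, ...) {
  p <- grid_periods(x)
  cat(sprintf("<frequency_grid> n = %d (N = %d, dt = %.6g days)\n",
              length(x$f_values), x$N, x$dt))
  cat(sprintf("  periods: %.4g .. %s days, %d fractional indices\n",
              min(p), format(max(p), digits = 4),
              sum(abs(x$f_values - round(x$f_values)) > 1e-9)))
  invisible(x)
}

#' Periods (days) represented by a frequency grid
#'
#' The period of index f is `2 N dt / (f - 1)`; the DC index f = 1 maps to an
#' infinite period.
#'
#' @param grid A `frequency_grid`.
#' @return Numeric vector of periods in days, aligned with `grid$f_values`.
#' @export
grid_periods <- function(grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  f <- grid$f_values
  ifelse(f > 1, 2 * grid$N * grid$dt / (f - 1), Inf)
}

#' Remapped DCT oscillation dictionary
#'
#' Realizes the dictionary on a (possibly nonuniform) frequency grid: column k
#' is `sqrt(2/N) * cos(pi * (2n - 1) * (f_k - 1) / (2N))` over rows n = 1..N,
#' with the DC `1/sqrt(2)` scaling applied only where f = 1. With the identity
#' grid this is exactly the orthonormal DCT-II; fractional indices trade exact
#' orthogonality for denser coverage of long periods.
#'
#' @param grid A `frequency_grid`.
#' @return An `oscillation_basis` with fields `matrix` (N x n) and `grid`.
#' @export
build_mapped_basis <- function(grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  structure(list(matrix = dct_rows(grid, seq_len(grid$N)), grid = grid),
            class = "oscillation_basis")
}

#' Rows of the remapped DCT dictionary, computed directly
#'
#' Computes the selected rows of the dictionary without materializing the full
#' N x n matrix; this is how the fitting routines obtain the subsampled
#' design matrix A for large grids.
#'
#' @param grid A `frequency_grid`.
#' @param rows Integer vector of row indices in 1..N.
#' @return A `length(rows)` x n numeric matrix.
#' @export
dct_rows <- function(grid, rows) {
  stopifnot(inherits(grid, "frequency_grid"))
  rows <- as.integer(rows)
  if (any(rows < 1L) || any(rows > grid$N)) stop("row indices out of range")
  N <- grid$N
  f <- grid$f_values
  M <- sqrt(2 / N) * cos(outer(2 * rows - 1, f - 1) * (pi / (2 * N)))
  dc <- which(abs(f - 1) < 1e-12)
  if (length(dc)) M[, dc] <- M[, dc] / sqrt(2)
  M
}

#' @export
print.oscillation_basis <- function(x, ...) {
  cat(sprintf("<oscillation_basis> %d x %d\n", nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Worst-case column coherence of a dictionary
#'
#' Maximum absolute off-diagonal entry of the Gram matrix of the
#' (column-normalized) dictionary. The identity-mapped DCT has coherence ~0;
#' inserting fractional frequencies below the Rayleigh resolution of the
#' record necessarily produces strongly correlated neighboring columns, which
#' this diagnostic quantifies.
#'
#' @param basis An `oscillation_basis` or a plain matrix.
#' @return Single number in \[0, 1\].
#' @export
basis_coherence <- function(basis) {
  M <- if (inherits(basis, "oscillation_basis")) basis$matrix else basis
  nrm <- sqrt(colSums(M^2))
  G <- crossprod(sweep(M, 2, pmax(nrm, .Machine$double.eps), "/"))
  diag(G) <- 0
  max(abs(G))
}

#' Vandermonde polynomial trend dictionary
#'
#' Column j is the normalized time raised to the power j - 1, for j = 1..p
#' with p = `max_degree + 1`. Raw times are affinely mapped to \[-1, 1\]
#' before exponentiation to keep the basis well conditioned.
#'
#' @param times Numeric vector of times (days).
#' @param max_degree Maximum polynomial degree (>= 0); default 1 (a linear
#'   trend).
#' @return A `polynomial_basis` with fields `matrix` (length(times) x p), `p`,
#'   `time_scale` (named offset/scale of the affine map), `times`.
#' @export
build_polynomial_basis <- function(times, max_degree = 1) {
  stopifnot(is.numeric(times), all(is.finite(times)))
  max_degree <- as.integer(max_degree)
  if (max_degree < 0) stop("'max_degree' must be >= 0")
  p <- max_degree + 1L
  if (length(unique(times)) < p)
    warning("fewer distinct times than polynomial columns: trend is rank-deficient")
  offset <- (max(times) + min(times)) / 2
  scale <- (max(times) - min(times)) / 2
  if (scale == 0) scale <- 1
  structure(list(matrix = poly_columns(times, p, offset, scale),
                 p = p, time_scale = c(offset = offset, scale = scale),
                 times = as.numeric(times)),
            class = "polynomial_basis")
}

poly_columns <- function(times, p, offset, scale) {
  u <- (times - offset) / scale
  outer(u, seq_len(p) - 1, "^")
}

#' Evaluate a polynomial basis at new times
#'
#' Applies the stored affine time normalization, so trend coefficients fitted
#' on one set of rows predict consistently at any other times.
#'
#' @param basis A `polynomial_basis`.
#' @param times Numeric vector of times (days).
#' @return A `length(times)` x p matrix.
#' @export
evaluate_polynomial_basis <- function(basis, times) {
  stopifnot(inherits(basis, "polynomial_basis"))
  poly_columns(times, basis$p, basis$time_scale[["offset"]],
               basis$time_scale[["scale"]])
}

#' @export
print.polynomial_basis <- function(x, ...) {
  cat(sprintf("<polynomial_basis> %d x %d (degree %d)\n",
              nrow(x$matrix), x$p, x$p - 1L))
  invisible(x)
}

#' Subsample dictionary rows at observation times
#'
#' Realizes the action of the binary row-subsampling operator: returns the
#' rows of the dictionary at the observed grid indices. No dense selection
#' matrix is ever formed.
#'
#' @param basis An `oscillation_basis`, `polynomial_basis`, or plain matrix.
#' @param mask Integer vector of row indices, strictly increasing and unique.
#' @return A `length(mask)` x ncol matrix.
#' @export
subsample_rows <- function(basis, mask) {
  M <- if (inherits(basis, c("oscillation_basis", "polynomial_basis")))
    basis$matrix else basis
  stopifnot(is.matrix(M))
  mask <- as.integer(mask)
  if (any(mask < 1L) || any(mask > nrow(M))) stop("mask indices out of range")
  if (anyDuplicated(mask)) stop("mask indices must be unique")
  if (length(mask) >= 2 && any(diff(mask) <= 0))
    stop("mask indices must be strictly increasing")
  M[mask, , drop = FALSE]
}
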