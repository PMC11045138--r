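#' Cross-validation configuration
#'
#' Settings for the repeated random-split cross-validation that selects the
#' L1 budget `delta`: the number of folds, the train fraction, and the
#' candidate grid. "10-fold 75/25" means ten independent random 75/25 splits
#' of the fixed sample set (Monte-Carlo cross-validation); a partitioned
#' 10-fold scheme cannot produce 75/25 splits.
#'
#' @param n_folds Number of random splits (default 10).
#' @param train_fraction Fraction of samples used for fitting in each split
#'   (default 0.75; 0.90 is the common alternative).
#' @param delta_grid Candidate `delta` values, sorted ascending; `NULL`
#'   (default) uses 20 log-spaced points between `1e-2` and
#'   `1e2 * ||y||_2 * sqrt(m)`, a bracket spanning the inactive-to-saturated
#'   range of the constraint.
#' @param n_delta Grid size when `delta_grid` is `NULL` (default 20).
#' @param seed Seed for the fold splits (default 1).
#' @param max_iter Per-fit iteration cap used inside CV (default 2000).
#' @param early_stop Stop ascending the delta grid within a fold once the
#'   held-out MSE has clearly passed its minimum (exceeds `early_stop` times
#'   the fold's running minimum); the tail of the fold's curve is filled with
#'   the last computed value. Set `Inf` to disable. Default 2.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, train_fraction = 0.75,
                      delta_grid = NULL, n_delta = 20L, seed = 1L,
                      max_iter = 2000L, early_stop = 2) {
  stopifnot(n_folds >= 1, train_fraction > 0, train_fraction < 1)
  if (!is.null(delta_grid)) {
    stopifnot(length(delta_grid) >= 1, all(delta_grid >= 0))
    delta_grid <- sort(delta_grid)
  }
  structure(list(n_folds = as.integer(n_folds),
                 train_fraction = train_fraction,
                 delta_grid = delta_grid, n_delta = as.integer(n_delta),
                 seed = as.integer(seed), max_iter = as.integer(max_iter),
                 early_stop = early_stop),
            class = "cv_config")
}

default_delta_grid <- function(y, n_delta = 20L) {
  upper <- 1e2 * sqrt(sum(y^2)) * sqrt(length(y))
  exp(seq(log(1e-2), log(upper), length.out = n_delta))
}

#' Select the L1 budget by repeated random-split cross-validation
#'
#' For each fold, the samples are split at random into a training and a test
#' subset; BPWP is fitted on the training rows for every candidate `delta`
#' (warm-started along the ascending grid) and the held-out samples are
#' predicted as `A_test x + B_test z`. The `delta` minimizing the mean
#' held-out MSE across folds is selected; ties break toward the smaller
#' (sparser) `delta`.
#'
#' @param sampled A `sampled_series` with grid mask.
#' @param grid A `frequency_grid`.
#' @param max_degree Polynomial trend degree (default 1).
#' @param config A [cv_config()].
#' @param design Optional precomputed design (internal reuse).
#' @param tol Solver tolerance inside CV (default 1e-5).
#' @return An object of class `cv_result`: `delta_grid`, `mean_mse`, `ci95`
#'   (half-width, 1.96 sd / sqrt(folds)), `fold_mse` (folds x deltas),
#'   `selected_delta`, `config`.
#' @export
cross_validate_delta <- function(sampled, grid, max_degree = 1,
                                 config = cv_config(), design = NULL,
                                 tol = 1e-5) {
  stopifnot(inherits(sampled, "sampled_series"), inherits(config, "cv_config"))
  if (is.null(design)) design <- build_design(sampled, grid, max_degree)
  y <- sampled$values
  m <- length(y)
  p <- ncol(design$B)
  deltas <- config$delta_grid
  if (is.null(deltas)) deltas <- default_delta_grid(y, config$n_delta)
  n_test <- m - floor(config$train_fraction * m)
  if (n_test < p + 2)
    stop("test folds would have fewer than p + 2 points")

  fold_mse <- matrix(NA_real_, config$n_folds, length(deltas))
  for (k in seq_len(config$n_folds)) {
    tr <- with_seed(child_seed(config$seed, k),
                    sort(sample.int(m, floor(config$train_fraction * m))))
    te <- setdiff(seq_len(m), tr)
    A_tr <- design$A[tr, , drop = FALSE]
    B_tr <- design$B[tr, , drop = FALSE]
    A_te <- design$A[te, , drop = FALSE]
    B_te <- design$B[te, , drop = FALSE]
    y_tr <- y[tr]
    P <- residual_projector(B_tr)
    At <- project_residual(P, A_tr)
    yt <- project_residual(P, y_tr)
    x_warm <- NULL
    flat_from <- NA_integer_
    best <- Inf
    for (j in seq_along(deltas)) {
      if (!is.na(flat_from)) {        # constraint slack or curve clearly past
        fold_mse[k, j] <- fold_mse[k, j - 1]   # its minimum: fill the tail
        next
      }
      sol <- suppressWarnings(
        solve_l1_constrained(At, yt, deltas[j], tol = tol,
                             max_iter = config$max_iter, x0 = x_warm))
      x_warm <- sol$x
      z <- recover_polynomial(B_tr, y_tr, A_tr, sol$x)
      pred <- as.numeric(A_te %*% sol$x)
      if (p) pred <- pred + as.numeric(B_te %*% z)
      fold_mse[k, j] <- mean((y[te] - pred)^2)
      best <- min(best, fold_mse[k, j])
      if (sum(abs(sol$x)) < deltas[j] * (1 - 1e-6) ||
          fold_mse[k, j] > config$early_stop * best)
        flat_from <- j
    }
  }
  mean_mse <- colMeans(fold_mse)
  ci95 <- 1.96 * apply(fold_mse, 2, stats::sd) / sqrt(config$n_folds)
  if (diff(range(mean_mse)) < 1e-12 * max(1, mean(mean_mse)))
    warning("cross-validation MSE curve is flat across the delta grid")
  best <- which(mean_mse <= min(mean_mse))[1]  # ties -> smaller delta
  structure(list(delta_grid = deltas, mean_mse = mean_mse, ci95 = ci95,
                 fold_mse = fold_mse, selected_delta = deltas[best],
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d deltas in [%.3g, %.3g]; selected delta = %.6g (mean MSE %.6g)\n",
              length(x$delta_grid), min(x$delta_grid), max(x$delta_grid),
              x$selected_delta, min(x$mean_mse)))
  invisible(x)
}
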