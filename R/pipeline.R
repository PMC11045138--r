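# Subsampled design matrices for a sampled series on an analysis grid.
# A = rows of the remapped DCT dictionary at the observed grid indices,
# B = rows of the dense-grid Vandermonde trend at the same indices.
# The dense polynomial basis is returned too, for reconstruction.
build_design <- function(sampled, grid, max_degree = 1) {
  stopifnot(inherits(sampled, "sampled_series"),
            inherits(grid, "frequency_grid"))
  if (is.null(sampled$mask))
    stop("sampled series has no grid mask; call attach_grid() first")
  if (!is.null(sampled$N) && sampled$N != grid$N)
    stop("sampled series and frequency grid disagree on N")
  t0 <- if (!is.null(sampled$t0)) sampled$t0 else 0
  tt_dense <- t0 + (seq_len(grid$N) - 1) * grid$dt
  poly <- build_polynomial_basis(tt_dense, max_degree = max_degree)
  list(A = dct_rows(grid, sampled$mask),
       B = poly$matrix[sampled$mask, , drop = FALSE],
       poly = poly, mask = sampled$mask)
}

#' Full BPWP analysis of a sampled series
#'
#' High-level wrapper running the estimation pipeline on a sparse series:
#' build the subsampled dictionaries, select the L1 budget `delta` by
#' cross-validation when it is not supplied, fit by variable projection,
#' optionally build the shuffle null and flag significant coefficients.
#'
#' @param sampled A `sampled_series` with a grid mask (from [random_sample()]
#'   or [attach_grid()]).
#' @param grid A `frequency_grid` on the same dense geometry.
#' @param max_degree Maximum polynomial trend degree (default 1).
#' @param delta L1 budget; `NULL` (default) selects it with
#'   [cross_validate_delta()].
#' @param cv A [cv_config()] used when `delta` is `NULL`.
#' @param n_shuffle Number of shuffle-null iterations (default 100); set to 0
#'   to skip significance testing.
#' @param percentile Null percentile for significance (default 99).
#' @param seed Seed for the shuffle null.
#' @param tol,max_iter Solver controls for the final fit.
#' @param pipeline_tol Looser solver tolerance used inside cross-validation
#'   and the shuffle null (default 1e-5).
#' @return An object of class `bpwp_analysis`: list with `fit`, `spectrum`,
#'   `grid`, `poly`, `delta`, `cv` (or `NULL`), `null` (or `NULL`),
#'   `sampled`.
#' @export
bpwp <- function(sampled, grid, max_degree = 1, delta = NULL,
                 cv = cv_config(), n_shuffle = 100L, percentile = 99,
                 seed = 1L, tol = 1e-8, max_iter = 50000L,
                 pipeline_tol = 1e-5) {
  design <- build_design(sampled, grid, max_degree)
  cv_res <- NULL
  if (is.null(delta)) {
    cv_res <- cross_validate_delta(sampled, grid, max_degree = max_degree,
                                   config = cv, design = design,
                                   tol = pipeline_tol)
    delta <- cv_res$selected_delta
  }
  problem <- bpwp_problem(sampled$values, design$A, design$B, delta)
  fit <- fit_bpwp(problem, tol = tol, max_iter = max_iter)
  spectrum <- bpwp_spectrum(fit, grid)
  null <- NULL
  if (n_shuffle > 0) {
    null <- build_shuffle_null(sampled, grid, max_degree = max_degree,
                               delta = delta, n_iter = n_shuffle,
                               percentile = percentile, seed = seed,
                               design = design, tol = pipeline_tol)
    spectrum <- flag_significant(fit, null, percentile = percentile,
                                 grid = grid)
  }
  structure(list(fit = fit, spectrum = spectrum, grid = grid,
                 poly = design$poly, delta = delta, cv = cv_res, null = null,
                 sampled = sampled),
            class = "bpwp_analysis")
}

#' @export
print.bpwp_analysis <- function(x, ...) {
  cat(sprintf("<bpwp_analysis> m = %d samples, n = %d coefficients, delta = %.6g\n",
              length(x$sampled$times), length(x$fit$x), x$delta))
  if (!is.null(x$null)) {
    sig <- x$spectrum[which(x$spectrum$significant), , drop = FALSE]
    cat(sprintf("  %d significant coefficients", nrow(sig)))
    if (nrow(sig))
      cat(": periods ",
          paste(format(sort(sig$period_days), digits = 4), collapse = ", "),
          " days", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Significant periods of an analysis
#'
#' @param analysis A `bpwp_analysis`.
#' @param min_period Only report periods at least this long (days).
#' @return Numeric vector of significant periods (days), decreasing.
#' @export
significant_periods <- function(analysis, min_period = 0) {
  stopifnot(inherits(analysis, "bpwp_analysis"))
  sp <- analysis$spectrum
  p <- sp$period_days[which(sp$significant & sp$period_days >= min_period)]
  sort(p, decreasing = TRUE)
}
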