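# Shared small-scale fixtures: short records on coarse grids so full
# pipelines run in seconds. All generated in code; nothing stored on disk.

# 120-day record, 4-hour grid (N = 720), two cycles + linear trend + noise
small_sim_spec <- function(seed = 5) {
  simulation_spec(duration_days = 120, update_minutes = 240,
                  periods_days = c(7, 30), amplitudes = c(10, 10),
                  phases = c(0, 0), trend = c(0, 20), noise_sd = 8,
                  seed = seed)
}

small_grid <- function(N, dt, seed = 1) {
  tp <- seq(2, 60, 0.5)
  build_frequency_mapping(N, dt, target_periods = tp[tp <= N * dt],
                          removal_period_ceiling = 1, seed = seed)
}

# a quick cv config for pipeline-level tests
quick_cv <- function(n_delta = 10L, seed = 1L)
  cv_config(n_delta = n_delta, seed = seed, max_iter = 2000L)

random_problem <- function(m, n, p, delta, seed) {
  set.seed(seed)
  A <- matrix(rnorm(m * n), m)
  B <- if (p > 0) cbind(1, matrix(rnorm(m * (p - 1)), m)) else
    matrix(numeric(0), m, 0)
  y <- rnorm(m)
  bpwp_problem(y, A, B, delta)
}
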