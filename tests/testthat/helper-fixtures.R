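# Shared fixtures, built once per test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small calibrated pool with bootstrap error columns (60 items, N = 200)
small_calibration <- function() {
  fixture("small_calibration", function() {
    pool <- generate_item_pool(60, seed = 101)
    design <- build_linked_design(pool, n_clusters = 4, cluster_size = 15,
                                  seed = 102)
    dat <- simulate_calibration_data(pool, design, n_per_item = 200,
                                     seed = 103)
    fit <- fit_2pl_mml(dat)
    calibrated <- bootstrap_item_errors(dat, fit, n_reps = 40, seed = 104)
    list(pool = pool, design = design, data = dat, fit = fit,
         calibrated = calibrated)
  })
}

# random administered-item tibble with error metadata, for estimator tests
random_error_items <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    item_id = sprintf("x%02d", seq_len(n)),
    a = rlnorm(n, 0, 0.4),
    b = rnorm(n),
    se_a = runif(n, 0, 0.3),
    se_b = runif(n, 0, 0.4),
    cov_ab = runif(n, -0.05, 0.05),
    delta_a = rnorm(n, 0, 0.05),
    delta_b = rnorm(n, 0, 0.08)
  ))
}

# draw store with all draws degenerate at the pool's point values
degenerate_store <- function(pool, S = 50) {
  draw_store(matrix(pool$a, S, nrow(pool), byrow = TRUE),
             matrix(pool$b, S, nrow(pool), byrow = TRUE),
             pool$item_id)
}
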