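#' Simulate a calibration-error CAT study
#'
#' End-to-end Monte Carlo comparison of CAT regimes under item calibration
#' error, at a configurable (by default desk) scale:
#'
#' 1. generate a synthetic item pool ([generate_item_pool()]);
#' 2. simulate a circularly linked calibration ([build_linked_design()],
#'    [simulate_calibration_data()]) with `n_per_item` responses per item;
#' 3. calibrate by MML ([fit_2pl_mml()]) and estimate per-item error
#'    covariances and biases by bootstrap ([bootstrap_item_errors()]);
#' 4. build draw stores: independent normal pseudo-draws of item parameters
#'    for the cWLE + BMI track, and — depending on `bayes_draws` — either a
#'    joint-normal approximation using the bootstrap covariance or a
#'    hierarchical Bayesian calibration ([fit_2pl_bayes_hier()]) for the
#'    Bayesian track;
#' 5. administer fixed-length CATs for every requested approach at every true
#'    ability level ([run_condition()]), generating responses from the true
#'    parameters;
#' 6. summarize conditional bias and MSE per level ([condition_summary()]).
#'
#' @param n_items Pool size (default 300).
#' @param n_clusters,cluster_size Linked-design shape (defaults 20 x 15).
#' @param n_per_item Calibration responses per item (default 100, the
#'   highest-error condition).
#' @param n_boot Bootstrap replications (default 200).
#' @param test_length CAT length(s); a vector runs every length as its own
#'   cell (default 20).
#' @param theta_levels True ability levels (default extremes -3 and 3).
#' @param n_per_level Simulated testees per level (default 500).
#' @param S Draws for BMI selection and the Bayesian engine (default 1000).
#' @param approaches Which regimes to run (default all four).
#' @param bayes_draws `"hier_mcmc"` (hierarchical Bayesian calibration
#'   draws, the default) or `"normal_approx"` (joint-normal draws from the
#'   MML fit and bootstrap covariance).
#' @param seed Master seed; all stage seeds derive from it.
#' @param verbose Print stage progress to standard error.
#' @return List with `truth` (generating pool), `calibrated` (pool with
#'   bootstrap error columns), `results` (per-session estimates), `summary`
#'   ([condition_summary()] table) and `reduction` ([bias_reduction_table()]
#'   when the `none` baseline was run).
#' @export
simulate_study <- function(n_items = 300, n_clusters = 20, cluster_size = 15,
                           n_per_item = 100, n_boot = 200, test_length = 20,
                           theta_levels = c(-3, 3), n_per_level = 500,
                           S = 1000,
                           approaches = c("none", "cwle", "cwle_bmi", "bayes"),
                           bayes_draws = c("hier_mcmc", "normal_approx"),
                           seed = 1, verbose = TRUE) {
  bayes_draws <- match.arg(bayes_draws)
  approaches <- match.arg(approaches, several.ok = TRUE)
  say <- function(...) if (verbose) message(...)
  stage_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, 8))

  say("Generating pool of ", n_items, " items")
  truth <- generate_item_pool(n_items, seed = stage_seeds[1])
  design <- build_linked_design(truth, n_clusters, cluster_size,
                                seed = stage_seeds[2])
  say("Simulating calibration data (", n_per_item, " responses per item)")
  dat <- simulate_calibration_data(truth, design, n_per_item,
                                   seed = stage_seeds[3])
  say("Calibrating by MML")
  fit <- fit_2pl_mml(dat)
  say("Bootstrapping item errors (", n_boot, " replications)")
  calibrated <- bootstrap_item_errors(dat, fit, n_reps = n_boot,
                                      seed = stage_seeds[4])

  pseudo <- NULL
  if ("cwle_bmi" %in% approaches) {
    # pseudo-draws use the calibration's information-based SEs (the standard
    # output of an IRT analysis); the bootstrap quantities feed the bias
    # function, not the selection draws
    pseudo <- normal_draw_store(fit$items, S, joint = FALSE,
                                seed = stage_seeds[5])
  }
  posterior <- NULL
  if ("bayes" %in% approaches) {
    if (bayes_draws == "normal_approx") {
      say("Building joint-normal approximation draw store")
      posterior <- normal_draw_store(calibrated, S, joint = TRUE,
                                     seed = stage_seeds[6])
    } else {
      say("Hierarchical Bayesian calibration")
      bf <- fit_2pl_bayes_hier(dat, S = S, iter = 2500, seed = stage_seeds[6])
      posterior <- bf$draws
    }
  }

  results <- list()
  for (app in approaches) {
    for (tl in test_length) {
      say("Running approach: ", app, " (test length ", tl, ")")
      cfg <- cat_config(app, test_length = tl, S = S)
      dr <- switch(app, cwle_bmi = pseudo, bayes = posterior, NULL)
      results[[paste(app, tl)]] <-
        run_condition(truth, calibrated, cfg, theta_levels, n_per_level,
                      draws = dr, seed = stage_seeds[7])
    }
  }
  results <- bind_rows(results)
  summary <- condition_summary(results)
  reduction <- if ("none" %in% approaches && length(approaches) > 1L)
    bias_reduction_table(summary) else NULL
  list(truth = truth, calibrated = calibrated, results = results,
       summary = summary, reduction = reduction)
}
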