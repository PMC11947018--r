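#' CAT session configuration
#'
#' Bundles the settings of one adaptive-test regime:
#' * `"none"` — WLE ability estimation, maximum-information selection,
#'   calibration error ignored (the conventional procedure);
#' * `"cwle"` — bias-corrected WLE estimation, MI selection;
#' * `"cwle_bmi"` — cWLE estimation, Bayesian MI selection over normal
#'   pseudo-draws of item parameters and ability;
#' * `"bayes"` — fully Bayesian sequential posterior updating with BMI
#'   selection over posterior draws.
#'
#' @param approach One of `"none"`, `"cwle"`, `"cwle_bmi"`, `"bayes"`.
#' @param test_length Fixed number of items per session (>= 1).
#' @param S Number of draws used by BMI selection and the Bayesian engine.
#' @param prior_mean,prior_sd Start prior of the Bayesian track (default
#'   N(0, 1.5^2)).
#' @param theta_start Starting ability point for the likelihood tracks
#'   (default 0, the calibration population mean).
#' @param sampler Posterior sampler of the Bayesian track (`"grid"` or
#'   `"mcmc"`), see [posterior_update()].
#' @param grid_n Grid resolution for the grid sampler.
#' @return Object of class `cat_config`.
#' @export
cat_config <- function(approach = c("none", "cwle", "cwle_bmi", "bayes"),
                       test_length = 20, S = 2000,
                       prior_mean = 0, prior_sd = 1.5,
                       theta_start = 0, sampler = c("grid", "mcmc"),
                       grid_n = 2001) {
  approach <- match.arg(approach)
  sampler <- match.arg(sampler)
  if (test_length < 1) abort("`test_length` must be >= 1.")
  structure(
    list(approach = approach, test_length = as.integer(test_length),
         S = as.integer(S), prior_mean = prior_mean, prior_sd = prior_sd,
         theta_start = theta_start, sampler = sampler,
         grid_n = as.integer(grid_n)),
    class = "cat_config"
  )
}

#' @export
print.cat_config <- function(x, ...) {
  cat("CAT config:", x$approach, "| test length", x$test_length,
      "| S =", x$S, "\n")
  invisible(x)
}

#' Administer one fixed-length adaptive test
#'
#' Runs a single simulated CAT session for a testee with true ability
#' `true_theta`. Responses are always generated from the *true* generating
#' item parameters (`truth`), while selection and estimation see only the
#' calibration artifacts — this separation is what lets calibration error
#' affect the results. The provisional estimate before any response is
#' `theta_start` for the likelihood tracks and the initial prior for the
#' Bayesian track.
#'
#' @param truth Generating pool tibble (`item_id`, `a`, `b`).
#' @param calibrated Calibrated pool tibble (`item_id`, `a`, `b`, plus error
#'   columns `se_a`, `se_b`, `cov_ab`, `delta_a`, `delta_b` for the cWLE
#'   tracks). May be `NULL` for the Bayesian track.
#' @param config A [cat_config()].
#' @param true_theta True ability of the simulated testee.
#' @param draws A [draw_store()]; required for `"cwle_bmi"` (normal
#'   pseudo-draws of item parameters) and `"bayes"` (posterior draws).
#' @param marginal Optional cached [marginal_likelihood_grid()] matrix for
#'   the Bayesian grid sampler.
#' @param seed Optional integer seed (applied locally).
#' @return Object of class `cat_result`: administered `items`, `responses`,
#'   per-step `trace` tibble (`t`, `item_id`, `u`, `est`, `se`), final
#'   `theta_hat` and `se`.
#' @export
administer_cat <- function(truth, calibrated, config, true_theta,
                           draws = NULL, marginal = NULL, seed = NULL) {
  stopifnot(inherits(config, "cat_config"))
  approach <- config$approach
  if (approach %in% c("cwle_bmi", "bayes") && is.null(draws))
    abort(paste0("Approach '", approach, "' requires a draw store."))
  if (approach %in% c("none", "cwle", "cwle_bmi")) {
    if (is.null(calibrated)) abort("Likelihood tracks require `calibrated`.")
    if (config$test_length > nrow(calibrated))
      abort("`test_length` exceeds the pool size.")
    if (approach %in% c("cwle", "cwle_bmi") &&
        !all(c("se_a", "se_b", "cov_ab", "delta_a", "delta_b")
             %in% names(calibrated)))
      abort("cWLE tracks need bootstrap error columns in `calibrated`.")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  true_a <- setNames(truth$a, truth$item_id)
  true_b <- setNames(truth$b, truth$item_id)
  T_len <- config$test_length
  administered <- character(T_len)
  u <- integer(T_len)
  est_tr <- numeric(T_len)
  se_tr <- numeric(T_len)

  if (approach == "bayes") {
    if (config$test_length > length(draws$item_id))
      abort("`test_length` exceeds the pool size.")
    grid <- default_grid(config$grid_n)
    state <- init_prior(config$S, config$prior_mean, config$prior_sd)
    for (t in seq_len(T_len)) {
      id <- select_bmi(draws, state$draws, administered[seq_len(t - 1L)])
      administered[t] <- id
      p_true <- plogis(true_a[[id]] * (true_theta - true_b[[id]]))
      u[t] <- as.integer(runif(1) < p_true)
      if (config$sampler == "grid") {
        pbar <- if (!is.null(marginal)) marginal[, id] else NULL
        state <- posterior_update(
          state, u[t],
          item_draws = if (is.null(pbar))
            list(a = draws$a[, id], b = draws$b[, id]) else NULL,
          pbar = pbar, sampler = "grid", grid = grid)
      } else {
        state <- posterior_update(
          state, u[t], item_draws = list(a = draws$a[, id], b = draws$b[, id]),
          sampler = "mcmc")
      }
      est_tr[t] <- state$mu
      se_tr[t] <- sqrt(state$sigma2)
    }
    theta_hat <- mean(state$draws)
    se_final <- sd(state$draws)
  } else {
    est <- config$theta_start
    se_est <- NA_real_
    cal_idx <- setNames(seq_len(nrow(calibrated)), calibrated$item_id)
    for (t in seq_len(T_len)) {
      prev <- administered[seq_len(t - 1L)]
      id <- if (approach == "cwle_bmi" && t > 1L) {
        theta_draws <- rnorm(config$S, est, se_est)
        select_bmi(draws, theta_draws, prev)
      } else {
        select_mi(calibrated, est, prev)
      }
      administered[t] <- id
      p_true <- plogis(true_a[[id]] * (true_theta - true_b[[id]]))
      u[t] <- as.integer(runif(1) < p_true)
      items_adm <- calibrated[cal_idx[administered[seq_len(t)]], ]
      fit <- if (approach == "none") wle(items_adm, u[seq_len(t)])
             else cwle(items_adm, u[seq_len(t)])
      est <- fit$theta
      se_est <- fit$se
      est_tr[t] <- est
      se_tr[t] <- se_est
    }
    theta_hat <- est
    se_final <- se_est
  }

  structure(
    list(approach = approach, true_theta = true_theta,
         items = administered, responses = u,
         trace = tibble(t = seq_len(T_len), item_id = administered, u = u,
                        est = est_tr, se = se_tr),
         theta_hat = theta_hat, se = se_final),
    class = "cat_result"
  )
}

#' @export
print.cat_result <- function(x, ...) {
  cat("CAT session (", x$approach, "): ", length(x$items),
      " items, final estimate ", round(x$theta_hat, 3),
      " (SE ", round(x$se, 3), "), true theta ", x$true_theta, "\n", sep = "")
  invisible(x)
}

#' @rdname administer_cat
#' @param x A `cat_result`.
#' @param ... Unused.
#' @export
tidy.cat_result <- function(x, ...) x$trace

#' @rdname administer_cat
#' @export
glance.cat_result <- function(x, ...) {
  tibble(approach = x$approach, true_theta = x$true_theta,
         test_length = length(x$items), theta_hat = x$theta_hat, se = x$se)
}

#' Simulate a full CAT condition
#'
#' Runs `n_per_level` independent sessions at each true ability level and
#' collects the final estimates. Session seeds are derived deterministically
#' from `seed` (one draw per level x replicate), so any condition is
#' reproducible independently of the others.
#'
#' @inheritParams administer_cat
#' @param theta_levels Vector of true ability levels.
#' @param n_per_level Testees per level.
#' @param seed Master seed for the condition.
#' @return Tibble with one row per session: `approach`, `true_theta`,
#'   `replicate`, `theta_hat`, `se`.
#' @export
run_condition <- function(truth, calibrated, config, theta_levels,
                          n_per_level, draws = NULL, seed = 1) {
  if (length(theta_levels) < 1L) abort("`theta_levels` must be non-empty.")
  n_total <- length(theta_levels) * n_per_level
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_total))
  marginal <- NULL
  if (config$approach == "bayes" && config$sampler == "grid" && !is.null(draws))
    marginal <- marginal_likelihood_grid(draws, default_grid(config$grid_n))
  out_theta <- numeric(n_total)
  out_se <- numeric(n_total)
  k <- 0L
  for (li in seq_along(theta_levels)) {
    for (r in seq_len(n_per_level)) {
      k <- k + 1L
      res <- administer_cat(truth, calibrated, config, theta_levels[li],
                            draws = draws, marginal = marginal,
                            seed = seeds[k])
      out_theta[k] <- res$theta_hat
      out_se[k] <- res$se
    }
  }
  tibble(
    approach = config$approach,
    test_length = config$test_length,
    true_theta = rep(theta_levels, each = n_per_level),
    replicate = rep(seq_len(n_per_level), times = length(theta_levels)),
    theta_hat = out_theta,
    se = out_se
  )
}
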