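#' Initial ability prior for Bayesian CAT
#'
#' Starting state of the sequential Bayesian engine: a normal ability prior
#' (default N(0, 1.5^2), a slightly diffuse start relative to the N(0, 1)
#' calibration metric) together with `S` draws from it, available to the BMI
#' item-selection criterion before any response has been observed.
#'
#' @param S Number of stored ability draws.
#' @param mean,sd Prior mean and SD (defaults 0 and 1.5).
#' @param seed Optional integer seed (applied locally).
#' @return Object of class `posterior_state`: list with `draws` (length `S`),
#'   `mu`, `sigma2` (the carried normal prior), and update counter `t`.
#' @export
init_prior <- function(S = 2000, mean = 0, sd = 1.5, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  structure(
    list(draws = rnorm(S, mean, sd), mu = mean, sigma2 = sd^2, t = 0L),
    class = "posterior_state"
  )
}

#' @export
print.posterior_state <- function(x, ...) {
  cat("Posterior state after", x$t, "update(s): prior N(",
      round(x$mu, 3), ",", round(sqrt(x$sigma2), 3), "^2 ),",
      length(x$draws), "draws\n")
  invisible(x)
}

#' Empirical normal prior from posterior draws
#'
#' Mean and variance of a draw vector, both with divisor `S` (not `S - 1`),
#' as used to summarize each posterior update into the normal prior carried
#' to the next item. The variance is floored at `floor` to keep the carried
#' prior proper after near-degenerate updates.
#'
#' @param theta_draws Numeric vector of posterior draws (length >= 1).
#' @param floor Variance floor (default 1e-4).
#' @return Named list with `mu` and `sigma2`.
#' @export
empirical_prior <- function(theta_draws, floor = 1e-4) {
  S <- length(theta_draws)
  if (S < 1L) abort("At least one draw is required.")
  mu <- sum(theta_draws) / S
  sigma2 <- sum((theta_draws - mu)^2) / S
  list(mu = mu, sigma2 = max(sigma2, floor))
}

#' Sequential Bayesian posterior update of ability
#'
#' One step of the fully Bayesian CAT engine. Given the carried normal prior
#' N(mu, sigma2) and a response `u` to an item with `S` stored calibration
#' draws, the target posterior density is
#' \deqn{f(\theta \mid u) \propto N(\theta; \mu, \sigma^2)\;
#'   S^{-1}\sum_s f(u \mid \theta, \xi^{(s)}),}
#' i.e. the item-parameter integral is evaluated as the stored-draw average.
#' New draws replace the previous draw set and the new empirical normal prior
#' is computed via [empirical_prior()].
#'
#' Two samplers target the same density: `"grid"` (default) evaluates the
#' posterior on a fine deterministic grid over \[-6, 6\] and resamples `S`
#' draws by inverse-CDF with within-cell linear interpolation — reproducible
#' and fast; `"mcmc"` runs random-walk Metropolis chains with a split-Rhat
#' convergence gate (warning at Rhat >= 1.05).
#'
#' @param state A [init_prior()] / previous `posterior_update()` state.
#' @param u Response in {0, 1}.
#' @param item_draws List with numeric vectors `a` and `b`: the administered
#'   item's stored draws (length must match `length(state$draws)`).
#' @param pbar Optional precomputed draw-averaged correct-response curve on
#'   `grid` (mean over draws of P(theta_g)); supply instead of `item_draws`
#'   when the marginal curve has been cached (see
#'   [marginal_likelihood_grid()]). Grid sampler only.
#' @param sampler `"grid"` or `"mcmc"`.
#' @param grid Grid for the `"grid"` sampler (default 2001 equally spaced
#'   points on \[-6, 6\]).
#' @param chains,iter MCMC settings (`"mcmc"` sampler): number of chains and
#'   iterations per chain (first half discarded as burn-in).
#' @param seed Optional integer seed (applied locally).
#' @return Updated `posterior_state`; diagnostics (sampler, Rhat when MCMC)
#'   in attribute `"diagnostics"`.
#' @export
posterior_update <- function(state, u, item_draws = NULL, pbar = NULL,
                             sampler = c("grid", "mcmc"),
                             grid = default_grid(), chains = 4, iter = 1000,
                             seed = NULL) {
  sampler <- match.arg(sampler)
  if (!u %in% c(0L, 1L)) abort("`u` must be 0 or 1.")
  if (!is.null(seed)) withr::local_seed(seed)
  S <- length(state$draws)
  diagnostics <- list(sampler = sampler)

  if (sampler == "grid") {
    if (is.null(pbar)) {
      if (is.null(item_draws)) abort("Provide `item_draws` or `pbar`.")
      if (length(item_draws$a) != S)
        abort("`item_draws` must hold one draw per stored ability draw.")
      pbar <- drop(cpp_pbar_grid(cbind(item_draws$a), cbind(item_draws$b),
                                 grid))
    }
    lik <- if (u == 1L) pbar else 1 - pbar
    dens <- dnorm(grid, state$mu, sqrt(state$sigma2)) * lik
    tot <- sum(dens)
    if (!is.finite(tot) || tot <= 0)
      abort("Posterior mass vanished on the grid.")
    draws <- sample_grid_inverse_cdf(grid, dens / tot, S)
  } else {
    if (is.null(item_draws)) abort("MCMC sampler requires `item_draws`.")
    log_post <- function(th) {
      p <- plogis(item_draws$a * (th - item_draws$b))
      lbar <- mean(if (u == 1L) p else 1 - p)
      dnorm(th, state$mu, sqrt(state$sigma2), log = TRUE) + log(lbar)
    }
    keep_per_chain <- ceiling(S / chains)
    burn <- floor(iter / 2)
    if (chains * (iter - burn) < S)
      abort("MCMC sampler retains fewer draws than `length(state$draws)`; increase `iter`.")
    step <- 2.4 * sqrt(state$sigma2)
    chains_draws <- lapply(seq_len(chains), function(ch) {
      th <- rnorm(1, state$mu, sqrt(state$sigma2))
      lp <- log_post(th)
      out <- numeric(iter - burn)
      for (it in seq_len(iter)) {
        prop <- th + step * rnorm(1)
        if (prop >= THETA_RANGE[1] && prop <= THETA_RANGE[2]) {
          lp_prop <- log_post(prop)
          if (log(runif(1)) < lp_prop - lp) { th <- prop; lp <- lp_prop }
        }
        if (it > burn) out[it - burn] <- th
      }
      out
    })
    rhat <- split_rhat(do.call(cbind, chains_draws))
    diagnostics$rhat <- rhat
    if (is.finite(rhat) && rhat >= 1.05)
      warn(paste0("Posterior update MCMC split-Rhat ", round(rhat, 3),
                  " >= 1.05."))
    draws <- head(unlist(lapply(chains_draws, function(z)
      tail(z, keep_per_chain))), S)
  }

  pr <- empirical_prior(draws)
  if (pr$sigma2 <= 1e-4)
    inform("Carried prior variance at floor; posterior nearly degenerate.")
  out <- structure(
    list(draws = draws, mu = pr$mu, sigma2 = pr$sigma2, t = state$t + 1L),
    class = "posterior_state"
  )
  attr(out, "diagnostics") <- diagnostics
  out
}

default_grid <- function(n = 2001) {
  seq(THETA_RANGE[1], THETA_RANGE[2], length.out = n)
}

# inverse-CDF sampling from a density tabulated on an equally spaced grid,
# with uniform jitter inside cells (piecewise-constant cell masses)
sample_grid_inverse_cdf <- function(grid, mass, S) {
  cdf <- cumsum(mass)
  cdf <- cdf / cdf[length(cdf)]
  u <- runif(S)
  idx <- findInterval(u, cdf) + 1L
  idx[idx > length(grid)] <- length(grid)
  half <- (grid[2] - grid[1]) / 2
  lo <- ifelse(idx == 1L, 0, cdf[idx - 1L])
  frac <- (u - lo) / pmax(cdf[idx] - lo, .Machine$double.eps)
  grid[idx] - half + (grid[2] - grid[1]) * frac
}

#' Draw-averaged response curves on the working grid
#'
#' For each item in a [draw_store()], the correct-response probability
#' averaged over the stored draws, evaluated on `grid`. Caching this matrix
#' makes every grid-sampler [posterior_update()] a cheap vector operation.
#'
#' @param draws A `draw_store`.
#' @param grid Theta grid (default 2001 points on \[-6, 6\]).
#' @return `length(grid) x n_items` matrix with item ids as column names.
#' @export
marginal_likelihood_grid <- function(draws, grid = default_grid()) {
  m <- cpp_pbar_grid(draws$a, draws$b, grid)
  colnames(m) <- draws$item_id
  m
}

# split-half Rhat over a (iterations x chains) draw matrix
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2L) return(NA_real_)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}
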