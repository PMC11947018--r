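test_that("the initial prior is N(0, 1.5^2) with reproducible draws", {
  st <- init_prior(S = 4000, seed = 51)
  expect_equal(st$mu, 0)
  expect_equal(st$sigma2, 1.5^2)
  expect_equal(st$t, 0L)
  expect_lt(abs(mean(st$draws)), 4 * 1.5 / sqrt(4000))
  expect_identical(init_prior(S = 100, seed = 7)$draws,
                   init_prior(S = 100, seed = 7)$draws)
})

test_that("the empirical prior uses divisor S and a variance floor", {
  pr <- empirical_prior(c(0, 2))
  expect_equal(pr$mu, 1)
  expect_equal(pr$sigma2, 1)  # divisor S = 2, not S - 1
  expect_equal(empirical_prior(rep(3.3, 10))$sigma2, 1e-4)
  expect_equal(empirical_prior(rep(3.3, 10))$mu, 3.3)
  expect_error(empirical_prior(numeric(0)))
  x <- withr::with_seed(52, rnorm(500))
  pr <- empirical_prior(x)
  expect_equal(pr$mu, sum(x) / 500)
  expect_equal(pr$sigma2, sum((x - mean(x))^2) / 500)
})

test_that("grid posterior updates match direct quadrature", {
  withr::with_seed(53, {
    for (k in 1:25) {
      S <- 3000
      a0 <- rlnorm(1, 0, 0.3); b0 <- rnorm(1)
      item <- list(a = rep(a0, S), b = rep(b0, S))
      st <- init_prior(S = S, mean = 0, sd = 1)
      u <- rbinom(1, 1, 0.5)
      new <- posterior_update(st, u, item_draws = item)
      oracle <- oracle_posterior_mean_quad(0, 1, u, a0, b0)
      mcse <- sqrt(new$sigma2 / S)
      expect_lt(abs(new$mu - oracle), max(0.01, 4 * mcse))
      expect_equal(new$t, 1L)
      expect_length(new$draws, S)
    }
  })

  # non-degenerate draws: the marginalized likelihood is the draw average
  S <- 500
  item <- withr::with_seed(54,
    list(a = rlnorm(S, 0, 0.3), b = rnorm(S, 0.5, 0.4)))
  st <- init_prior(S = S, mean = 0, sd = 1.2, seed = 55)
  new <- posterior_update(st, 1L, item_draws = item, seed = 56)
  oracle <- oracle_posterior_mean_quad(0, 1.2, 1L, item$a, item$b)
  expect_lt(abs(new$mu - oracle), max(0.01, 4 * sqrt(new$sigma2 / S)))
})

test_that("posterior updates are symmetric in the response at b = mu = 0", {
  S <- 2000
  item <- list(a = rep(1.2, S), b = rep(0, S))
  st <- init_prior(S = S, mean = 0, sd = 1, seed = 57)
  up1 <- posterior_update(st, 1L, item_draws = item, seed = 58)
  up0 <- posterior_update(st, 0L, item_draws = item, seed = 59)
  expect_lt(abs(up1$mu + up0$mu), 4 * sqrt(2 * up1$sigma2 / S))
})

test_that("a near-degenerate prior dominates the likelihood", {
  S <- 500
  st <- structure(list(draws = rep(0.8, S), mu = 0.8, sigma2 = 1e-4, t = 3L),
                  class = "posterior_state")
  item <- list(a = rep(1.5, S), b = rep(-1, S))
  for (u in c(0L, 1L)) {
    new <- suppressMessages(posterior_update(st, u, item_draws = item,
                                             seed = 60))
    expect_equal(new$mu, 0.8, tolerance = 0.01)
  }
})

test_that("the MCMC sampler targets the same posterior as the grid", {
  S <- 600
  item <- withr::with_seed(61,
    list(a = rlnorm(S, 0, 0.3), b = rnorm(S, -0.3, 0.3)))
  st <- init_prior(S = S, mean = 0.2, sd = 1, seed = 62)
  g <- posterior_update(st, 1L, item_draws = item, sampler = "grid",
                        seed = 63)
  m <- posterior_update(st, 1L, item_draws = item, sampler = "mcmc",
                        iter = 2000, seed = 64)
  expect_lt(abs(m$mu - g$mu), 0.05)
  expect_lt(abs(sqrt(m$sigma2) - sqrt(g$sigma2)), 0.1)
  expect_true(!is.null(attr(m, "diagnostics")$rhat))
})

test_that("sequential normal-summary updating tracks the exact-carry
           posterior over a full test", {
  # exact carry: the posterior density itself is propagated on the grid, so
  # the sequential product equals the one-shot joint posterior by construction;
  # the engine's normal summaries must stay close in posterior mean
  S <- 4000
  n_items <- 20
  grid <- seq(-6, 6, length.out = 2001)
  devs <- c()
  withr::with_seed(65, {
    for (true_theta in c(-2, 0, 1.5)) {
      a <- rlnorm(n_items, 0, 0.4)
      b <- sort(rnorm(n_items, true_theta, 0.7))
      u <- rbinom(n_items, 1, plogis(a * (true_theta - b)))
      ds <- list(a = matrix(rep(a, each = S) * exp(rnorm(S * n_items, 0, 0.1)),
                            S, n_items),
                 b = matrix(rep(b, each = S) + rnorm(S * n_items, 0, 0.15),
                            S, n_items))

      # exact carry on the grid and one-shot joint posterior
      dens_seq <- dnorm(grid, 0, 1.5)
      joint <- dnorm(grid, 0, 1.5)
      for (t in seq_len(n_items)) {
        pbar <- rowMeans(plogis(outer(grid, rep(1, S)) * 0 +
          matrix(ds$a[, t], 2001, S, byrow = TRUE) *
            (grid - matrix(ds$b[, t], 2001, S, byrow = TRUE))))
        lik <- if (u[t] == 1) pbar else 1 - pbar
        dens_seq <- dens_seq * lik
        dens_seq <- dens_seq / sum(dens_seq)
        joint <- joint * lik
      }
      joint <- joint / sum(joint)
      expect_equal(dens_seq, joint, tolerance = 1e-10)
      exact_mean <- sum(grid * joint)

      # engine: normal summary carried between items
      st <- init_prior(S = S, mean = 0, sd = 1.5)
      for (t in seq_len(n_items)) {
        st <- posterior_update(st, u[t],
                               item_draws = list(a = ds$a[, t], b = ds$b[, t]))
      }
      devs <- c(devs, st$mu - exact_mean)
    }
  })
  # the normal summary tracks the exact posterior mean on average; single
  # sessions carry draw-moment MC noise of ~sigma_t/sqrt(S) per step
  expect_lt(mean(abs(devs)), 0.05)
})

test_that("posterior spread shrinks as informative items accumulate", {
  S <- 800
  withr::with_seed(66, {
    st <- init_prior(S = S, mean = 0, sd = 1.5)
    spreads <- sqrt(st$sigma2)
    for (t in 1:10) {
      item <- list(a = rep(1.4, S), b = rep(st$mu, S))
      u <- rbinom(1, 1, 0.5)
      st <- posterior_update(st, u, item_draws = item)
      spreads <- c(spreads, sqrt(st$sigma2))
    }
    # monotone in expectation; allow small MC wiggle per step
    expect_lt(spreads[11], spreads[1] / 2)
    expect_true(all(diff(spreads) < 0.05))
  })
})
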