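test_that("single-item WLE has the log(3) closed form", {
  one <- tibble::tibble(item_id = "i1", a = 1, b = 0)
  # stationarity of log P + 0.5 log I at u = 1 implies P = 3/4
  expect_equal(wle(one, 1L)$theta, log(3), tolerance = 1e-6)
  expect_equal(wle(one, 0L)$theta, -log(3), tolerance = 1e-6)
  est <- wle(one, 1L)
  expect_equal(est$se, 1 / sqrt(item_info(est$theta, 1, 0)))
  expect_identical(est$method, "WLE")
  expect_error(wle(one[0, ], integer(0)))
})

test_that("WLE matches the grid argmax of the weighted likelihood", {
  withr::with_seed(21, {
    for (k in 1:50) {
      n <- 10
      a <- rlnorm(n, 0, 0.5); b <- rnorm(n)
      u <- rbinom(n, 1, plogis(runif(1, -2, 2) - b))
      items <- tibble::tibble(item_id = as.character(1:n), a = a, b = b)
      expect_lt(abs(wle(items, u)$theta - oracle_wle_grid(a, b, u)), 1e-3)
    }
  })
})

test_that("the WLE score residual vanishes at interior solutions", {
  withr::with_seed(22, {
    for (k in 1:20) {
      n <- 15
      a <- rlnorm(n, 0, 0.4); b <- rnorm(n)
      u <- rbinom(n, 1, 0.5)
      items <- tibble::tibble(item_id = as.character(1:n), a = a, b = b)
      th <- wle(items, u)$theta
      if (abs(th) < 5.9) {
        p <- prob_2pl(th, a, b)
        info <- sum(a^2 * p * (1 - p))
        dinfo <- sum(a^3 * p * (1 - p) * (1 - 2 * p))
        score <- sum(a * (u - p)) + dinfo / (2 * info)
        expect_lt(abs(score), 1e-6)
      }
    }
  })
})

test_that("the bias function vanishes without error inputs and matches hand
           calculations", {
  items <- tibble::tibble(item_id = "i1", a = 1, b = 0,
                          se_a = 0, se_b = 0, cov_ab = 0,
                          delta_a = 0, delta_b = 0)
  for (th in seq(-3, 3, by = 0.5)) expect_equal(bias_function(th, items), 0)

  # single item, only error covariance: B = J3 / I = 2 * I * cov / I... at
  # theta = b: D = 0, J1 = 0, J2 = 0, J3 = 2 * 0.25 * 0.1 = 0.05, I = 0.25
  items$cov_ab <- 0.1
  expect_equal(bias_function(0, items), 0.2)

  # constant difficulty bias: D/I collapses to the constant and the only
  # other surviving term is J2 with weight delta_b^2
  many <- random_error_items(12, seed = 23)
  many$se_a <- 0; many$se_b <- 0; many$cov_ab <- 0; many$delta_a <- 0
  many$delta_b <- 0.37
  for (th in c(-2, 0, 1.5)) {
    p <- prob_2pl(th, many$a, many$b)
    info <- item_info(th, many$a, many$b)
    j2 <- sum(many$a * (p - 0.5) * info * 0.37^2)
    expect_equal(bias_function(th, many), 0.37 + j2 / sum(info))
  }
  # in the small-bias limit the correction is the constant itself
  many$delta_b <- 1e-4
  for (th in c(-2, 0, 1.5))
    expect_equal(bias_function(th, many), 1e-4, tolerance = 1e-4)
})

test_that("the error part of the bias function is additive-homogeneous", {
  items <- random_error_items(10, seed = 24)
  items$delta_a <- 0; items$delta_b <- 0
  doubled <- items
  doubled$se_a <- sqrt(2) * items$se_a
  doubled$se_b <- sqrt(2) * items$se_b
  doubled$cov_ab <- 2 * items$cov_ab
  for (th in c(-1.5, 0.2, 2)) {
    expect_equal(bias_function(th, doubled), 2 * bias_function(th, items))
  }
})

test_that("the bias function is continuous where information is positive", {
  items <- random_error_items(8, seed = 25)
  th <- seq(-5, 5, by = 0.01)
  B <- bias_function(th, items)
  expect_true(all(is.finite(B)))
  expect_lt(max(abs(diff(B))), 0.1)
})

test_that("cWLE equals WLE minus the bias at the WLE, capped and clipped", {
  items <- random_error_items(10, seed = 26)
  u <- withr::with_seed(26, rbinom(10, 1, 0.6))

  # zero-error inputs: cWLE is the WLE
  clean <- items
  clean$se_a <- 0; clean$se_b <- 0; clean$cov_ab <- 0
  clean$delta_a <- 0; clean$delta_b <- 0
  expect_equal(cwle(clean, u)$theta, wle(clean, u)$theta)

  # constant small difficulty bias: shift by that constant (first order)
  shifted <- clean
  shifted$delta_b <- 0.3
  expect_equal(cwle(shifted, u)$theta, wle(shifted, u)$theta - 0.3,
               tolerance = 0.01)
  shifted$delta_b <- 1e-3
  expect_equal(cwle(shifted, u)$theta, wle(shifted, u)$theta - 1e-3,
               tolerance = 1e-6)

  # general errors: independent re-evaluation of the correction
  w <- wle(items, u)$theta
  expect_equal(cwle(items, u)$theta, w - bias_function(w, items),
               tolerance = 1e-10)

  # cap: enormous error inputs cannot move the estimate by more than 2
  wild <- items
  wild$se_b <- 20
  est <- cwle(wild, u)
  expect_lte(abs(est$correction), 2)
  expect_gte(est$theta, -6)
  expect_lte(est$theta, 6)
})

test_that("cWLE converges to WLE as the error inputs shrink", {
  items <- random_error_items(10, seed = 27)
  u <- withr::with_seed(27, rbinom(10, 1, 0.5))
  w <- wle(items, u)$theta
  gaps <- vapply(c(1, 0.1, 0.01, 0.001), function(sc) {
    sm <- items
    sm$se_a <- sc * items$se_a; sm$se_b <- sc * items$se_b
    sm$cov_ab <- sc^2 * items$cov_ab
    sm$delta_a <- sc * items$delta_a; sm$delta_b <- sc * items$delta_b
    abs(cwle(sm, u)$theta - w)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 1e-3)
})
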