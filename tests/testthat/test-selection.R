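test_that("maximum-information selection picks the most informative
           remaining item", {
  pool <- tibble::tibble(item_id = c("lo", "hi"), a = c(1, 2), b = c(0.5, 0.5))
  expect_identical(select_mi(pool, 0.5), "hi")
  expect_identical(select_mi(pool, 0.5, administered = "hi"), "lo")
  expect_error(select_mi(pool, 0.5, administered = c("lo", "hi")),
               class = "calicat_pool_exhausted")
})

test_that("MI selection matches brute-force maximization on large pools", {
  pool <- generate_item_pool(300, seed = 31)
  withr::with_seed(32, {
    for (k in 1:20) {
      th <- runif(1, -3.5, 3.5)
      admin <- sample(pool$item_id, sample(0:40, 1))
      expect_identical(select_mi(pool, th, admin), oracle_mi(pool, th, admin))
    }
  })
})

test_that("BMI selection reduces to MI under degenerate draws and matches the
           brute-force average otherwise", {
  pool <- generate_item_pool(120, seed = 33)
  store <- degenerate_store(pool, S = 25)
  withr::with_seed(34, {
    for (k in 1:10) {
      th <- runif(1, -3, 3)
      admin <- sample(pool$item_id, sample(0:30, 1))
      expect_identical(select_bmi(store, rep(th, 25), admin),
                       select_mi(pool, th, admin))
    }
  })

  # full ranking equality under degenerate draws
  th <- 1.2
  crit <- bmi_criterion(store, rep(th, 25))
  expect_equal(unname(crit), item_info(th, pool$a, pool$b), tolerance = 1e-12)

  # random draws against the double-loop oracle
  small <- generate_item_pool(40, seed = 35)
  S <- 200
  ds <- withr::with_seed(36, draw_store(
    matrix(rlnorm(S * 40, 0, 0.4), S, 40),
    matrix(rnorm(S * 40), S, 40),
    small$item_id))
  thd <- withr::with_seed(37, rnorm(S, 0.5, 0.4))
  expect_equal(bmi_criterion(ds, thd), oracle_bmi_criterion(ds, thd),
               tolerance = 1e-12)

  # S = 1 is MI at that single draw
  one <- draw_store(matrix(small$a, 1), matrix(small$b, 1), small$item_id)
  expect_identical(select_bmi(one, 0.8), select_mi(small, 0.8))
})

test_that("selection is invariant to item ordering", {
  pool <- generate_item_pool(50, seed = 38)
  perm <- withr::with_seed(39, sample(50))
  expect_identical(select_mi(pool, 1.1), select_mi(pool[perm, ], 1.1))
  ds <- degenerate_store(pool, S = 10)
  ds_perm <- draw_store(ds$a[, perm], ds$b[, perm], ds$item_id[perm])
  expect_identical(select_bmi(ds, rep(1.1, 10)),
                   select_bmi(ds_perm, rep(1.1, 10)))
})

test_that("the selected item's criterion dominates the remaining set", {
  pool <- generate_item_pool(80, seed = 40)
  ds <- normal_draw_store(dplyr::mutate(pool, se_a = 0.2, se_b = 0.2),
                          S = 100, seed = 41)
  thd <- withr::with_seed(42, rnorm(100, -1, 0.5))
  admin <- pool$item_id[1:10]
  pick <- select_bmi(ds, thd, admin)
  crit <- bmi_criterion(ds, thd)
  remaining <- setdiff(pool$item_id, admin)
  expect_gte(crit[pick], max(crit[remaining]) - 1e-12)
  expect_false(pick %in% admin)
})

test_that("normal pseudo-draws have the requested moments and positivity", {
  expect_equal(make_normal_draws(1.7, 0, 50), rep(1.7, 50))
  x <- withr::with_seed(43, make_normal_draws(1, 0.2, 100000))
  expect_lt(abs(mean(x) - 1), 0.0026)  # 4 sigma / sqrt(n)
  expect_equal(sd(x), 0.2, tolerance = 0.01)
  y <- withr::with_seed(44,
    make_normal_draws(0.05, 0.5, 2000, positive = TRUE, quiet = TRUE))
  expect_true(all(y >= 0.01))
  expect_error(make_normal_draws(1, -0.1, 10))
})

test_that("draw stores validate their structure", {
  expect_error(draw_store(matrix(1, 2, 2), matrix(1, 3, 2), c("a", "b")))
  expect_error(draw_store(matrix(-1, 2, 2), matrix(1, 2, 2), c("a", "b")))
  ds <- draw_store(matrix(1, 2, 2), matrix(0, 2, 2), c("a", "b"))
  tbl <- tibble::as_tibble(ds)
  expect_equal(nrow(tbl), 4)
  expect_named(tbl, c("item_id", "draw", "a", "b"))
})
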