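test_that("a session administers exactly t distinct items with a full trace", {
  sc <- small_calibration()
  cfg <- cat_config("none", test_length = 12)
  res <- administer_cat(sc$pool, sc$calibrated, cfg, true_theta = 0.5,
                        seed = 501)
  expect_length(res$items, 12)
  expect_false(anyDuplicated(res$items) > 0)
  expect_equal(nrow(res$trace), 12)
  expect_true(all(res$responses %in% c(0L, 1L)))
  expect_equal(res$theta_hat, res$trace$est[12])
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$test_length, 12)
})

test_that("the conventional track reproduces an independent reference
           implementation item for item", {
  sc <- small_calibration()
  cal <- sc$calibrated
  truth <- sc$pool
  for (case in list(c(seed = 502, theta = 1.5), c(seed = 503, theta = -2),
                    c(seed = 504, theta = 0))) {
    res <- administer_cat(truth, cal, cat_config("none", test_length = 12),
                          case[["theta"]], seed = case[["seed"]])
    ref_items <- character(0)
    ref_u <- integer(0)
    withr::with_seed(case[["seed"]], {
      est <- 0
      for (t in 1:12) {
        id <- oracle_mi(cal, est, ref_items)
        ref_items <- c(ref_items, id)
        i <- match(id, truth$item_id)
        p <- plogis(truth$a[i] * (case[["theta"]] - truth$b[i]))
        ref_u <- c(ref_u, as.integer(runif(1) < p))
        j <- match(ref_items, cal$item_id)
        est <- oracle_wle_precise(cal$a[j], cal$b[j], ref_u)
      }
    })
    expect_identical(res$items, ref_items)
    expect_identical(res$responses, ref_u)
  }
})

test_that("provisional estimates depend only on the items answered so far", {
  sc <- small_calibration()
  res <- administer_cat(sc$pool, sc$calibrated,
                        cat_config("cwle", test_length = 10), 1, seed = 505)
  for (t in c(3, 7, 10)) {
    idx <- match(res$items[seq_len(t)], sc$calibrated$item_id)
    redo <- cwle(sc$calibrated[idx, ], res$responses[seq_len(t)])
    expect_equal(res$trace$est[t], redo$theta)
  }
})

test_that("approach and artifact requirements are enforced", {
  sc <- small_calibration()
  expect_error(administer_cat(sc$pool, sc$calibrated,
                              cat_config("bayes", test_length = 5), 0),
               "draw store")
  expect_error(administer_cat(sc$pool, NULL,
                              cat_config("none", test_length = 5), 0),
               "calibrated")
  bare <- sc$calibrated[, c("item_id", "a", "b")]
  expect_error(administer_cat(sc$pool, bare,
                              cat_config("cwle", test_length = 5), 0),
               "error columns")
  expect_error(administer_cat(sc$pool, sc$calibrated,
                              cat_config("none", test_length = 1000), 0),
               "pool size")
})

test_that("conditions have the right shape and are bit-reproducible", {
  sc <- small_calibration()
  cfg <- cat_config("none", test_length = 8)
  levels <- seq(-3, 3, by = 0.5)
  out <- run_condition(sc$pool, sc$calibrated, cfg, levels, 3, seed = 506)
  expect_equal(nrow(out), 13 * 3)
  expect_setequal(unique(out$true_theta), levels)
  out2 <- run_condition(sc$pool, sc$calibrated, cfg, levels, 3, seed = 506)
  expect_identical(out, out2)
})

test_that("the Bayesian track is consistent under error-free draws", {
  sc <- small_calibration()
  store <- degenerate_store(sc$pool, S = 300)
  cfg <- cat_config("bayes", test_length = 40, S = 300)
  out <- run_condition(sc$pool, NULL, cfg, 0, 200, draws = store, seed = 507)
  expect_lt(abs(mean(out$theta_hat)), 0.1)
  expect_lt(mean((out$theta_hat)^2), 0.2)
})

test_that("a Bayesian session updates its posterior state item by item", {
  sc <- small_calibration()
  store <- normal_draw_store(sc$calibrated, S = 400, joint = TRUE, seed = 508)
  res <- administer_cat(sc$pool, NULL, cat_config("bayes", test_length = 10,
                                                  S = 400),
                        1, draws = store, seed = 509)
  expect_length(res$items, 10)
  # posterior spread shrinks over the session
  expect_lt(res$trace$se[10], 1.5)
  expect_equal(res$theta_hat, res$trace$est[10], tolerance = 1e-9)
})
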