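#' Hierarchical Bayesian 2PL calibration
#'
#' Samples the joint posterior of all item parameters under a hierarchical
#' 2PL model: abilities are standard normal, and the per-item pair
#' \eqn{(\log a_i, b_i)} follows a bivariate normal hierarchy built from
#' grand means, scales and the Cholesky factor of the 2x2 item-parameter
#' correlation matrix,
#' \deqn{(\log a_i, b_i) = (\mu_a + \tau_a v_{i1},\; \mu_b + \tau_b v_{i2}),
#'   \quad v_i = L_\Omega \zeta_i, \quad \zeta_i \sim N(0, I_2).}
#' The log link keeps discriminations positive. Priors:
#' \eqn{\mu_a \sim N(0,1)}, \eqn{\mu_b \sim N(0,2)} (variance 2);
#' \eqn{\tau_a, \tau_b} half-Cauchy(0,1); \eqn{L_\Omega \sim LKJ(4)} — for a
#' 2x2 correlation, density \eqn{\propto (1-\rho^2)^3}.
#'
#' Sampling is adaptive random-walk Metropolis-within-Gibbs in the centred
#' parameterization (the z-scores are implicit): vectorized per-respondent
#' ability updates, vectorized per-item \eqn{(\log a, b)} updates with
#' per-item proposal covariances learned during warmup, and hyperparameter
#' sweeps whose conditionals involve only the item-level summary (no data
#' pass). Split-Rhat is computed for every item parameter across chains; any
#' value at or above 1.05 triggers a convergence warning naming the
#' offending parameters.
#'
#' @param data A [simulate_calibration_data()] object or respondent x item
#'   0/1 matrix with `NA` for structural missingness.
#' @param S Number of stored post-burn-in joint draws (must not exceed
#'   `chains * (iter - warmup)`).
#' @param chains Number of chains (default 4).
#' @param iter Iterations per chain (default 1250).
#' @param warmup Burn-in iterations per chain (default `iter / 2`).
#' @param seed Optional integer seed (applied locally).
#' @return Object of class `bayes_2pl`: `items` (tibble of posterior means
#'   and SDs: `item_id`, `a`, `b`, `se_a`, `se_b`, `cov_ab`), `draws` (a
#'   [draw_store()] of `S` joint draws), `rhat` (tibble `param`, `rhat`),
#'   `accept` (acceptance rates).
#' @export
fit_2pl_bayes_hier <- function(data, S = 2000, chains = 4, iter = 1250,
                               warmup = floor(iter / 2), seed = NULL) {
  U <- if (inherits(data, "calib_data")) data$responses else as.matrix(data)
  if (is.null(colnames(U))) colnames(U) <- sprintf("i%04d", seq_len(ncol(U)))
  n_correct <- colSums(U == 1L, na.rm = TRUE)
  n_obs <- colSums(!is.na(U))
  if (any(n_correct == 0 | n_correct == n_obs))
    abort("Items with all-correct or all-incorrect responses cannot be calibrated.")
  if (!is.null(seed)) withr::local_seed(seed)
  kept <- iter - warmup
  if (S > chains * kept)
    abort("`S` exceeds the number of retained draws (`chains * (iter - warmup)`).")
  item_id <- colnames(U)
  R <- nrow(U); I <- ncol(U)
  storage.mode(U) <- "double"

  lp_tau <- function(lt) stats::dcauchy(exp(lt), 0, 1, log = TRUE) + log(2) + lt
  # bivariate-normal hierarchy term for (log a_i, b_i), summed over items
  hier_lp <- function(la, b, mu_a, mu_b, lta, ltb, zr) {
    rho <- tanh(zr)
    v1 <- (la - mu_a) / exp(lta)
    v2 <- (b - mu_b) / exp(ltb)
    -length(la) * (lta + ltb + 0.5 * log(1 - rho^2)) -
      sum(v1^2 - 2 * rho * v1 * v2 + v2^2) / (2 * (1 - rho^2))
  }
  hyper_prior <- function(mu_a, mu_b, lta, ltb, zr) {
    rho <- tanh(zr)
    dnorm(mu_a, 0, 1, log = TRUE) + dnorm(mu_b, 0, sqrt(2), log = TRUE) +
      lp_tau(lta) + lp_tau(ltb) + 4 * log(1 - rho^2)
  }

  run_chain <- function(chain_id) {
    theta <- rnorm(R, 0, 0.5)
    pbar <- n_correct / n_obs
    la <- rnorm(I, 0, 0.2)
    b <- -stats::qlogis(pmin(pmax(pbar, 0.02), 0.98)) + rnorm(I, 0, 0.2)
    mu_a <- 0; mu_b <- 0; lta <- log(0.5); ltb <- log(0.5); zr <- 0

    sc_theta <- 0.8; sc_h <- c(ha = 0.15, hb = 0.15, rho = 0.3)
    acc_theta <- 0; try_theta <- 0
    acc_h <- c(ha = 0, hb = 0, rho = 0); try_h <- acc_h
    # per-item shaped proposals for (log a, b), learned during warmup
    Lz <- cbind(rep(0.3, I), rep(0, I), rep(0.3, I))
    zsc <- rep(1, I)
    acc_z <- rep(0, I); try_z <- 0
    zs1 <- zs2 <- zs11 <- zs12 <- zs22 <- rep(0, I); zn <- 0L

    keep_a <- matrix(NA_real_, kept, I)
    keep_b <- matrix(NA_real_, kept, I)
    for (it in seq_len(iter)) {
      a <- exp(la)
      # abilities, vectorized over respondents
      cl <- cpp_masked_ll(U, theta, a, b)$row
      prop <- theta + sc_theta * rnorm(R)
      clp <- cpp_masked_ll(U, prop, a, b)$row
      lr <- clp - cl + dnorm(prop, log = TRUE) - dnorm(theta, log = TRUE)
      take <- log(runif(R)) < lr
      theta[take] <- prop[take]
      acc_theta <- acc_theta + mean(take); try_theta <- try_theta + 1

      # item parameters, vectorized over items, per-item shaped proposals
      cl <- cpp_masked_ll(U, theta, a, b)$col
      z1 <- rnorm(I); z2 <- rnorm(I)
      la_p <- la + zsc * Lz[, 1] * z1
      b_p <- pmin(pmax(b + zsc * (Lz[, 2] * z1 + Lz[, 3] * z2), -8), 8)
      clp <- cpp_masked_ll(U, theta, exp(la_p), b_p)$col
      rho <- tanh(zr); ta <- exp(lta); tb <- exp(ltb)
      pr_cur <- hier_pair_lp(la, b, mu_a, mu_b, ta, tb, rho)
      pr_prop <- hier_pair_lp(la_p, b_p, mu_a, mu_b, ta, tb, rho)
      take <- log(runif(I)) < clp - cl + pr_prop - pr_cur
      la[take] <- la_p[take]; b[take] <- b_p[take]
      acc_z <- acc_z + take; try_z <- try_z + 1
      zs1 <- zs1 + la; zs2 <- zs2 + b
      zs11 <- zs11 + la^2; zs12 <- zs12 + la * b; zs22 <- zs22 + b^2
      zn <- zn + 1L

      # hyperparameters: data-free conditionals, several cheap sweeps
      for (sweep in 1:3) {
        for (block in c("ha", "hb", "rho")) {
          pm <- c(mu_a = mu_a, mu_b = mu_b, lta = lta, ltb = ltb, zr = zr)
          if (block == "ha") {
            pm["mu_a"] <- mu_a + sc_h["ha"] * rnorm(1)
            pm["lta"] <- lta + sc_h["ha"] * rnorm(1)
          } else if (block == "hb") {
            pm["mu_b"] <- mu_b + sc_h["hb"] * rnorm(1)
            pm["ltb"] <- ltb + sc_h["hb"] * rnorm(1)
          } else {
            pm["zr"] <- zr + sc_h["rho"] * rnorm(1)
          }
          lr <- hier_lp(la, b, pm["mu_a"], pm["mu_b"], pm["lta"], pm["ltb"],
                        pm["zr"]) +
            hyper_prior(pm["mu_a"], pm["mu_b"], pm["lta"], pm["ltb"], pm["zr"]) -
            hier_lp(la, b, mu_a, mu_b, lta, ltb, zr) -
            hyper_prior(mu_a, mu_b, lta, ltb, zr)
          if (is.finite(lr) && log(runif(1)) < lr) {
            mu_a <- unname(pm["mu_a"]); mu_b <- unname(pm["mu_b"])
            lta <- unname(pm["lta"]); ltb <- unname(pm["ltb"])
            zr <- unname(pm["zr"])
            acc_h[block] <- acc_h[block] + 1
          }
          try_h[block] <- try_h[block] + 1
        }
      }

      # proposal adaptation during warmup
      if (it <= warmup && it %% 25 == 0) {
        sc_theta <- min(max(sc_theta * exp(acc_theta / try_theta - 0.3),
                            1e-3), 5)
        acc_theta <- 0; try_theta <- 0
        for (nm in names(sc_h)) {
          sc_h[nm] <- min(max(sc_h[nm] * exp(acc_h[nm] / try_h[nm] - 0.3),
                              1e-3), 5)
        }
        acc_h[] <- 0; try_h[] <- 0
        zsc <- pmin(pmax(zsc * exp(acc_z / try_z - 0.35), 0.05), 5)
        acc_z[] <- 0; try_z <- 0
        if (zn > 100L) {
          m1 <- zs1 / zn; m2 <- zs2 / zn
          c11 <- pmax(zs11 / zn - m1^2, 1e-4)
          c12 <- zs12 / zn - m1 * m2
          c22 <- pmax(zs22 / zn - m2^2, 1e-4)
          l11 <- sqrt(c11)
          l21 <- c12 / l11
          l22 <- sqrt(pmax(c22 - l21^2, 1e-6))
          Lz <- (2.4 / sqrt(2)) * cbind(l11, l21, l22)
        }
      }
      if (it > warmup) {
        keep_a[it - warmup, ] <- exp(la)
        keep_b[it - warmup, ] <- b
      }
    }
    list(a = keep_a, b = keep_b,
         accept = c(theta = acc_theta / max(try_theta, 1),
                    items = mean(acc_z) / max(try_z, 1),
                    acc_h / pmax(try_h, 1)))
  }

  res <- lapply(seq_len(chains), run_chain)
  rhat_a <- vapply(seq_len(I), function(i)
    split_rhat(sapply(res, function(ch) ch$a[, i])), numeric(1))
  rhat_b <- vapply(seq_len(I), function(i)
    split_rhat(sapply(res, function(ch) ch$b[, i])), numeric(1))
  rhat <- tibble(
    param = c(paste0("a[", item_id, "]"), paste0("b[", item_id, "]")),
    rhat = c(rhat_a, rhat_b)
  )
  bad <- rhat$param[!is.na(rhat$rhat) & rhat$rhat >= 1.05]
  if (length(bad))
    warn(paste0("Split-Rhat >= 1.05 for: ",
                paste(head(bad, 10), collapse = ", "),
                if (length(bad) > 10) " ..." else ""),
         class = "calicat_rhat_warning")

  A <- do.call(rbind, lapply(res, `[[`, "a"))
  B <- do.call(rbind, lapply(res, `[[`, "b"))
  idx <- round(seq(1, nrow(A), length.out = S))
  items <- tibble(
    item_id = item_id,
    a = colMeans(A), b = colMeans(B),
    se_a = apply(A, 2, sd), se_b = apply(B, 2, sd),
    cov_ab = vapply(seq_len(I), function(i) cov(A[, i], B[, i]), numeric(1))
  )
  structure(
    list(items = items, draws = draw_store(A[idx, , drop = FALSE],
                                           B[idx, , drop = FALSE], item_id),
         rhat = rhat, accept = lapply(res, `[[`, "accept"),
         chains = chains, iter = iter, warmup = warmup),
    class = "bayes_2pl"
  )
}

# per-item bivariate-normal hierarchy log density (vector over items)
hier_pair_lp <- function(la, b, mu_a, mu_b, ta, tb, rho) {
  v1 <- (la - mu_a) / ta
  v2 <- (b - mu_b) / tb
  -(v1^2 - 2 * rho * v1 * v2 + v2^2) / (2 * (1 - rho^2))
}

#' @export
print.bayes_2pl <- function(x, ...) {
  cat("Hierarchical Bayesian 2PL fit:", nrow(x$items), "items,", x$chains,
      "chains x", x$iter, "iterations (", x$warmup, "warmup ), max split-Rhat",
      round(max(x$rhat$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' @rdname fit_2pl_bayes_hier
#' @param x A `bayes_2pl` object.
#' @param ... Unused.
#' @export
tidy.bayes_2pl <- function(x, ...) x$items

#' @rdname fit_2pl_bayes_hier
#' @export
glance.bayes_2pl <- function(x, ...) {
  tibble(n_items = nrow(x$items), chains = x$chains, iter = x$iter,
         warmup = x$warmup, S = x$draws$S,
         max_rhat = max(x$rhat$rhat, na.rm = TRUE))
}
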