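# Independent oracles used to cross-check package computations. These share
# no code with the implementation paths they verify.

# weighted-likelihood argmax by coarse-to-fine grid search over [-6, 6]
oracle_wle_grid <- function(a, b, u, fine = 1e-4) {
  wll <- function(th) {
    x <- outer(a, th) - a * b
    p <- plogis(x)
    # stable log-probabilities: saturated p would give 0 * -Inf otherwise
    ll <- colSums(u * plogis(x, log.p = TRUE) +
                    (1 - u) * plogis(-x, log.p = TRUE))
    info <- colSums(a^2 * p * (1 - p))
    ll + 0.5 * log(info)
  }
  g1 <- seq(-6, 6, by = 0.01)
  k <- which.max(wll(g1))
  g2 <- seq(max(g1[k] - 0.02, -6), min(g1[k] + 0.02, 6), by = fine)
  g2[which.max(wll(g2))]
}

# brute-force maximum-information selection (simple loop)
oracle_mi <- function(pool, theta, administered = character()) {
  best_id <- NA_character_
  best_val <- -Inf
  for (i in seq_len(nrow(pool))) {
    if (pool$item_id[i] %in% administered) next
    p <- 1 / (1 + exp(-pool$a[i] * (theta - pool$b[i])))
    val <- pool$a[i]^2 * p * (1 - p)
    if (val > best_val) {
      best_val <- val
      best_id <- pool$item_id[i]
    }
  }
  best_id
}

# brute-force BMI criterion: double loop over items and draws
oracle_bmi_criterion <- function(draws, theta_draws) {
  S <- draws$S
  vals <- numeric(length(draws$item_id))
  for (i in seq_along(draws$item_id)) {
    acc <- 0
    for (s in seq_len(S)) {
      p <- 1 / (1 + exp(-draws$a[s, i] * (theta_draws[s] - draws$b[s, i])))
      acc <- acc + draws$a[s, i]^2 * p * (1 - p)
    }
    vals[i] <- acc / S
  }
  setNames(vals, draws$item_id)
}

# posterior mean of theta by direct quadrature: normal prior x draw-averaged
# single-item Bernoulli likelihood on a fine grid
oracle_posterior_mean_quad <- function(mu, sigma, u, a_draws, b_draws,
                                       n_grid = 2001) {
  g <- seq(-6, 6, length.out = n_grid)
  lbar <- vapply(g, function(th) {
    p <- 1 / (1 + exp(-a_draws * (th - b_draws)))
    mean(if (u == 1) p else 1 - p)
  }, numeric(1))
  w <- dnorm(g, mu, sigma) * lbar
  sum(g * w) / sum(w)
}

# independent marginal ML fit: direct quasi-Newton maximization of the
# quadrature-approximated marginal log-likelihood over all item parameters
oracle_marginal_ml <- function(U, start_a, start_b, n_quad = 61) {
  nodes <- seq(-6, 6, length.out = n_quad)
  w <- dnorm(nodes); w <- w / sum(w)
  I <- ncol(U)
  obs <- !is.na(U)
  Uz <- U; Uz[!obs] <- 0

  mll <- function(par) {
    a <- par[seq_len(I)]; b <- par[I + seq_len(I)]
    x <- outer(a, nodes) - a * b
    lp <- plogis(x, log.p = TRUE)
    lq <- plogis(-x, log.p = TRUE)
    LL <- Uz %*% lp + (obs - Uz) %*% lq
    m <- apply(LL, 1, max)
    sum(log(exp(LL - m) %*% w) + m)
  }
  grad <- function(par) {
    a <- par[seq_len(I)]; b <- par[I + seq_len(I)]
    x <- outer(a, nodes) - a * b
    P <- plogis(x)
    lp <- plogis(x, log.p = TRUE)
    lq <- plogis(-x, log.p = TRUE)
    LL <- Uz %*% lp + (obs - Uz) %*% lq
    m <- apply(LL, 1, max)
    W <- exp(LL - m) * rep(w, each = nrow(U))
    W <- W / rowSums(W)
    ga <- gb <- numeric(I)
    for (i in seq_len(I)) {
      rows <- obs[, i]
      resid <- outer(Uz[rows, i], rep(1, n_quad)) -
        rep(P[i, ], each = sum(rows))
      ew <- W[rows, , drop = FALSE]
      ga[i] <- sum(ew * resid * rep(nodes - b[i], each = sum(rows)))
      gb[i] <- -a[i] * sum(ew * resid)
    }
    c(ga, gb)
  }
  opt <- optim(c(start_a, start_b), mll, grad, method = "BFGS",
               control = list(fnscale = -1, maxit = 500, reltol = 1e-12))
  list(a = unname(opt$par[seq_len(I)]), b = unname(opt$par[I + seq_len(I)]),
       value = opt$value, convergence = opt$convergence)
}

# high-precision WLE via direct optimization of the weighted log-likelihood
# (independent of the package's root-finding on the weighted score)
oracle_wle_precise <- function(a, b, u) {
  wll <- function(th) {
    p <- plogis(a * (th - b))
    sum(u * log(p) + (1 - u) * log(1 - p)) +
      0.5 * log(sum(a^2 * p * (1 - p)))
  }
  g <- seq(-6, 6, by = 0.05)
  k <- which.max(vapply(g, wll, numeric(1)))
  lo <- max(g[k] - 0.1, -6); hi <- min(g[k] + 0.1, 6)
  if (k == 1) return(-6)
  if (k == length(g)) return(6)
  optimize(wll, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}
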