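#' Marginal maximum likelihood calibration of the 2PL model
#'
#' Concurrent Bock–Aitkin EM calibration of all items in a (possibly linked)
#' design, maximizing the marginal likelihood with the latent ability fixed at
#' N(0, 1) for scale identification. Structural missingness (cells outside a
#' respondent's form) is treated as ignorable. The latent distribution is
#' integrated on `n_quad` equally spaced quadrature nodes over \[-6, 6\] with
#' standard-normal weights.
#'
#' Items answered all-correct or all-incorrect by every respondent who saw
#' them cannot be calibrated; they are excluded with a warning and listed in
#' the `excluded` field of the result.
#'
#' Standard errors and the per-item sampling covariance of (a, b) come from
#' the empirical cross-product (outer product of per-respondent marginal
#' scores) approximation to the observed information, block-diagonal by item.
#'
#' @param data A [simulate_calibration_data()] object, or a respondent x item
#'   0/1 matrix with `NA` for not-administered cells and item ids as column
#'   names.
#' @param n_quad Number of quadrature nodes (default 61).
#' @param tol EM convergence tolerance: maximum absolute parameter change
#'   (default 1e-4).
#' @param max_cycles Maximum EM cycles (default 500); non-convergence is an
#'   error carrying the iteration trace.
#' @param start Optional warm start: data frame with `item_id`, `a`, `b`.
#' @return Object of class `mml_2pl` with fields `items` (tibble `item_id`,
#'   `a`, `b`, `se_a`, `se_b`, `cov_ab`), `loglik`, `cycles`, `converged`,
#'   `excluded`.
#' @export
fit_2pl_mml <- function(data, n_quad = 61, tol = 1e-4, max_cycles = 500,
                        start = NULL) {
  U <- if (inherits(data, "calib_data")) data$responses else as.matrix(data)
  if (is.null(colnames(U))) colnames(U) <- sprintf("i%04d", seq_len(ncol(U)))
  obs <- !is.na(U)
  n_obs_item <- colSums(obs)
  if (any(n_obs_item == 0)) abort("Every item needs observed responses.")
  n_correct <- colSums(U == 1L, na.rm = TRUE)
  degenerate <- n_correct == 0 | n_correct == n_obs_item
  excluded <- colnames(U)[degenerate]
  if (length(excluded)) {
    warn(paste0("Excluding ", length(excluded),
                " item(s) with all-correct or all-incorrect responses: ",
                paste(excluded, collapse = ", ")))
    U <- U[, !degenerate, drop = FALSE]
    obs <- obs[, !degenerate, drop = FALSE]
  }
  item_id <- colnames(U)
  I <- ncol(U)
  nodes <- seq(THETA_RANGE[1], THETA_RANGE[2], length.out = n_quad)
  lw <- dnorm(nodes, log = TRUE)
  lw <- lw - log(sum(exp(lw)))
  K <- n_quad

  # group respondents by observation pattern (test form) for fast E-steps
  key <- apply(obs, 1L, function(z) paste(which(z), collapse = ","))
  groups <- lapply(split(seq_len(nrow(U)), key), function(rows) {
    cols <- which(obs[rows[1L], ])
    list(rows = rows, cols = cols,
         u = matrix(U[rows, cols], nrow = length(rows)))
  })

  # starting values
  if (!is.null(start)) {
    idx <- match(item_id, start$item_id)
    a <- start$a[idx]; b <- start$b[idx]
    if (anyNA(a) || anyNA(b)) abort("`start` must cover every item.")
  } else {
    pbar <- n_correct[!degenerate] / n_obs_item[!degenerate]
    a <- rep(1, I)
    b <- -stats::qlogis(pmin(pmax(pbar, 0.02), 0.98))
  }

  e_step <- function(a, b) {
    x <- outer(a, nodes) - a * b
    lp <- plogis(x, log.p = TRUE)
    lq <- plogis(-x, log.p = TRUE)
    r <- matrix(0, I, K)
    nexp <- matrix(0, I, K)
    loglik <- 0
    for (g in groups) {
      Rg <- nrow(g$u)
      LL <- g$u %*% lp[g$cols, , drop = FALSE] +
        (1 - g$u) %*% lq[g$cols, , drop = FALSE] + rep(lw, each = Rg)
      mx <- LL[cbind(seq_len(Rg), max.col(LL))]
      W <- exp(LL - mx)
      den <- rowSums(W)
      loglik <- loglik + sum(log(den) + mx)
      W <- W / den
      r[g$cols, ] <- r[g$cols, ] + crossprod(g$u, W)
      nexp[g$cols, ] <- nexp[g$cols, ] + rep(colSums(W), each = length(g$cols))
    }
    list(r = r, nexp = nexp, loglik = loglik)
  }

  # exact box-constrained solve, used only for the rare items the C++
  # M-step cannot certify as optimal
  m_step_fallback <- function(r_k, n_k, a_i, b_i) {
    Qf <- function(par) {
      eta <- par[1] * (nodes - par[2])
      -sum(r_k * plogis(eta, log.p = TRUE) +
             (n_k - r_k) * plogis(-eta, log.p = TRUE))
    }
    opt <- stats::optim(c(a_i, b_i), Qf, method = "L-BFGS-B",
                        lower = c(0.05, -6), upper = c(10, 6))
    opt$par
  }

  # Exact conditional marginal log-likelihood maximization for one item given
  # all others: coordinate ascent used to finish off ridge items for which
  # plain EM converges only geometrically.
  refine_item <- function(i, a, b) {
    x <- outer(a, nodes) - a * b
    lp <- plogis(x, log.p = TRUE)
    lq <- plogis(-x, log.p = TRUE)
    bases <- list(); us <- list()
    for (g in groups) {
      j <- match(i, g$cols)
      if (is.na(j)) next
      Rg <- nrow(g$u)
      LL <- g$u %*% lp[g$cols, , drop = FALSE] +
        (1 - g$u) %*% lq[g$cols, , drop = FALSE] + rep(lw, each = Rg)
      cell_i <- outer(g$u[, j], lp[i, ]) + outer(1 - g$u[, j], lq[i, ])
      bases[[length(bases) + 1L]] <- LL - cell_i
      us[[length(us) + 1L]] <- g$u[, j]
    }
    negll <- function(par) {
      xi <- par[1] * (nodes - par[2])
      lpi <- plogis(xi, log.p = TRUE)
      lqi <- plogis(-xi, log.p = TRUE)
      tot <- 0
      for (k in seq_along(bases)) {
        LL <- bases[[k]] + outer(us[[k]], lpi) + outer(1 - us[[k]], lqi)
        mx <- LL[cbind(seq_len(nrow(LL)), max.col(LL))]
        tot <- tot + sum(log(rowSums(exp(LL - mx))) + mx)
      }
      -tot
    }
    opt <- stats::optim(c(a[i], b[i]), negll, method = "L-BFGS-B",
                        lower = c(0.05, -6), upper = c(10, 6))
    opt$par
  }

  cycles <- 0L
  converged <- FALSE
  trace <- numeric(0)
  loglik <- NA_real_
  d_prev <- NULL
  ll_prev <- -Inf
  a_safe <- b_safe <- NULL
  backoff <- 0L
  repeat {
    cycles <- cycles + 1L
    es <- e_step(a, b)
    # an accelerated jump that broke EM monotonicity is reverted; plain EM
    # resumes for a stretch before acceleration is attempted again
    if (!is.null(a_safe) && es$loglik < ll_prev - 1e-10) {
      a <- a_safe; b <- b_safe
      a_safe <- b_safe <- NULL
      backoff <- 25L
      d_prev <- NULL
      es <- e_step(a, b)
    }
    a_safe <- b_safe <- NULL
    loglik <- es$loglik
    ll_prev <- loglik
    new <- cpp_mstep_2pl(es$r, es$nexp, nodes, a, b, 0.05, 10, -6, 6)
    for (i in which(new[3, ] > 0)) {
      par <- m_step_fallback(es$r[i, ], es$nexp[i, ], new[1, i], new[2, i])
      new[1, i] <- par[1]; new[2, i] <- par[2]
    }
    d_cur <- c(new[1, ] - a, new[2, ] - b)
    delta <- max(abs(d_cur))
    a <- new[1, ]; b <- new[2, ]
    # Aitken-type acceleration every third cycle: geometric EM tails are
    # extrapolated, which cuts slow ridge convergence by orders of magnitude
    if (!is.null(d_prev) && backoff == 0L && cycles %% 3 == 0) {
      r <- sqrt(sum(d_cur^2) / sum(d_prev^2))
      if (is.finite(r) && r > 0 && r < 1) {
        boost <- min(r / (1 - r), 9)
        a_safe <- a; b_safe <- b
        a <- pmin(pmax(a + boost * d_cur[seq_len(I)], 0.05), 10)
        b <- pmin(pmax(b + boost * d_cur[I + seq_len(I)], -6), 6)
      }
    }
    if (backoff > 0L) backoff <- backoff - 1L
    d_prev <- d_cur
    trace[cycles] <- delta
    if (delta < tol) { converged <- TRUE; break }
    if (cycles >= max_cycles) break
    # finish off slow ridge items by exact conditional maximization
    if (cycles %% 40 == 0L && delta < 0.05) {
      stragglers <- which(pmax(abs(d_cur[seq_len(I)]),
                               abs(d_cur[I + seq_len(I)])) > tol / 2)
      for (i in head(stragglers, 20L)) {
        par <- refine_item(i, a, b)
        a[i] <- par[1]; b[i] <- par[2]
      }
      a_safe <- b_safe <- NULL
      ll_prev <- -Inf
      d_prev <- NULL
    }
  }
  if (!converged) {
    abort(paste0("EM did not converge in ", max_cycles,
                 " cycles (last max change ", signif(trace[cycles], 3), ")."),
          class = "calicat_em_nonconvergence", em_trace = trace)
  }

  # empirical cross-product information, block-diagonal by item
  x <- outer(a, nodes) - a * b
  P <- plogis(x)
  info <- matrix(0, I, 3)  # saa, sab, sbb accumulators
  for (g in groups) {
    Rg <- nrow(g$u)
    lp <- plogis(x[g$cols, , drop = FALSE], log.p = TRUE)
    lq <- plogis(-x[g$cols, , drop = FALSE], log.p = TRUE)
    LL <- g$u %*% lp + (1 - g$u) %*% lq + rep(lw, each = Rg)
    mx <- LL[cbind(seq_len(Rg), max.col(LL))]
    W <- exp(LL - mx); W <- W / rowSums(W)
    Pg <- P[g$cols, , drop = FALSE]
    EP <- W %*% t(Pg)
    EPT <- W %*% t(Pg * rep(nodes, each = length(g$cols)))
    Eth <- drop(W %*% nodes)
    for (j in seq_along(g$cols)) {
      i <- g$cols[j]
      s_a <- g$u[, j] * (Eth - b[i]) - (EPT[, j] - b[i] * EP[, j])
      s_b <- -a[i] * (g$u[, j] - EP[, j])
      info[i, ] <- info[i, ] +
        c(sum(s_a^2), sum(s_a * s_b), sum(s_b^2))
    }
  }
  se_a <- se_b <- cov_ab <- rep(NA_real_, I)
  for (i in seq_len(I)) {
    det <- info[i, 1] * info[i, 3] - info[i, 2]^2
    if (is.finite(det) && det > 0) {
      se_a[i] <- sqrt(info[i, 3] / det)
      se_b[i] <- sqrt(info[i, 1] / det)
      cov_ab[i] <- -info[i, 2] / det
    }
  }

  structure(
    list(
      items = tibble(item_id = item_id, a = a, b = b,
                     se_a = se_a, se_b = se_b, cov_ab = cov_ab),
      loglik = loglik, cycles = cycles, converged = converged,
      excluded = excluded, n_quad = n_quad, tol = tol
    ),
    class = "mml_2pl"
  )
}

#' @export
print.mml_2pl <- function(x, ...) {
  cat("2PL marginal maximum likelihood fit:", nrow(x$items), "items,",
      x$cycles, "EM cycles, log-likelihood", round(x$loglik, 2), "\n")
  if (length(x$excluded))
    cat("Excluded degenerate items:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_2pl_mml
#' @param x An `mml_2pl` object.
#' @param ... Unused.
#' @export
tidy.mml_2pl <- function(x, ...) x$items

#' @rdname fit_2pl_mml
#' @export
glance.mml_2pl <- function(x, ...) {
  tibble(logLik = x$loglik, n_items = nrow(x$items), cycles = x$cycles,
         converged = x$converged, n_excluded = length(x$excluded))
}
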