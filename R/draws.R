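#' Draw stores of joint item-parameter draws
#'
#' A draw store holds, for every item, an ordered sequence of `S` joint draws
#' of (a, b) — posterior draws from a Bayesian calibration or normal
#' pseudo-draws around point estimates. Draw index `s` aligns across items, so
#' column `s` of the store is one joint draw of the whole pool.
#'
#' @param a,b `S x I` matrices of draws (columns are items).
#' @param item_id Character vector of item ids (length I).
#' @return Object of class `draw_store`.
#' @export
draw_store <- function(a, b, item_id) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    abort("`a` and `b` draw matrices must have identical dimensions.")
  if (length(item_id) != ncol(a))
    abort("`item_id` must have one entry per draw-matrix column.")
  if (any(a <= 0)) abort("All discrimination draws must be positive.")
  colnames(a) <- colnames(b) <- item_id
  structure(list(a = a, b = b, item_id = as.character(item_id),
                 S = nrow(a)),
            class = "draw_store")
}

#' @export
print.draw_store <- function(x, ...) {
  cat("Draw store:", x$S, "joint (a, b) draws for", length(x$item_id),
      "items\n")
  invisible(x)
}

#' @rdname draw_store
#' @param x A `draw_store`.
#' @param ... Unused.
#' @export
as_tibble.draw_store <- function(x, ...) {
  tibble(
    item_id = rep(x$item_id, each = x$S),
    draw = rep(seq_len(x$S), times = length(x$item_id)),
    a = as.vector(x$a),
    b = as.vector(x$b)
  )
}

#' Normal draws around a point estimate
#'
#' `S` independent normal draws with mean `point` and SD `se`. With
#' `positive = TRUE` (used for discrimination parameters), draws below 0.01
#' are resampled until all are admissible (a message reports how many).
#'
#' @param point Point estimate (mean of the draws).
#' @param se Standard error (SD of the draws), `>= 0`; `se = 0` gives `S`
#'   copies of `point`.
#' @param S Number of draws.
#' @param positive Resample draws below 0.01?
#' @param quiet Suppress the resampling message.
#' @return Numeric vector of length `S`.
#' @export
make_normal_draws <- function(point, se, S, positive = FALSE, quiet = FALSE) {
  if (se < 0) abort("`se` must be nonnegative.")
  x <- rnorm(S, point, se)
  if (positive) {
    n_resampled <- 0L
    while (any(bad <- x < 0.01)) {
      n_resampled <- n_resampled + sum(bad)
      x[bad] <- rnorm(sum(bad), point, se)
      if (se == 0 && point < 0.01) {
        x[] <- 0.01
        break
      }
    }
    if (n_resampled > 0L && !quiet)
      inform(paste0("Resampled ", n_resampled,
                    " non-positive discrimination draw(s)."))
  }
  x
}

#' Normal pseudo-draw store from a calibrated pool
#'
#' Builds a [draw_store()] by drawing each item's parameters from normal
#' distributions centred at the point estimates with SDs equal to the
#' standard errors. By default a and b are drawn independently (the form used
#' by the cWLE + BMI selection track); with `joint = TRUE` the per-item error
#' covariance `cov_ab` is honoured via a bivariate normal, giving a
#' normal-approximation stand-in for a posterior draw store.
#'
#' @param calibrated Calibrated pool tibble with `item_id`, `a`, `b`, `se_a`,
#'   `se_b` and (for `joint = TRUE`) `cov_ab`.
#' @param S Number of draws per item.
#' @param joint Use the per-item (a, b) error covariance?
#' @param seed Optional integer seed (applied locally).
#' @return A `draw_store`.
#' @export
normal_draw_store <- function(calibrated, S, joint = FALSE, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  I <- nrow(calibrated)
  A <- matrix(NA_real_, S, I)
  B <- matrix(NA_real_, S, I)
  for (i in seq_len(I)) {
    if (joint) {
      # Cholesky of [[se_a^2, cov], [cov, se_b^2]], clamped to valid corr
      sa <- calibrated$se_a[i]; sb <- calibrated$se_b[i]
      rho <- if (sa > 0 && sb > 0)
        max(min(calibrated$cov_ab[i] / (sa * sb), 0.999), -0.999) else 0
      z1 <- rnorm(S); z2 <- rnorm(S)
      A[, i] <- calibrated$a[i] + sa * z1
      B[, i] <- calibrated$b[i] + sb * (rho * z1 + sqrt(1 - rho^2) * z2)
      bad <- A[, i] < 0.01
      while (any(bad)) {
        z1 <- rnorm(sum(bad)); z2 <- rnorm(sum(bad))
        A[bad, i] <- calibrated$a[i] + sa * z1
        B[bad, i] <- calibrated$b[i] + sb * (rho * z1 + sqrt(1 - rho^2) * z2)
        bad <- A[, i] < 0.01
      }
    } else {
      A[, i] <- make_normal_draws(calibrated$a[i], calibrated$se_a[i], S,
                                  positive = TRUE, quiet = TRUE)
      B[, i] <- make_normal_draws(calibrated$b[i], calibrated$se_b[i], S)
    }
  }
  draw_store(A, B, calibrated$item_id)
}
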