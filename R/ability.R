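#' Warm's weighted likelihood estimate of ability
#'
#' Maximizes the weighted likelihood \eqn{L(\theta)\sqrt{I(\theta)}}
#' (equivalently, log-likelihood plus half the log test information) over the
#' working range \[-6, 6\]. The weighting removes the first-order bias of the
#' ML estimate and keeps the estimate finite for all-correct and all-incorrect
#' response patterns. Interior solutions are located by safeguarded root
#' finding on the weighted score; when no sign change exists the estimate is
#' refined around the grid argmax (boundary solutions are reported at the
#' boundary).
#'
#' @param items Data frame of administered items with columns `a`, `b`
#'   (calibrated point estimates), aligned row-for-row with `responses`.
#' @param responses Integer 0/1 vector of responses.
#' @return One-row tibble: `theta` (estimate), `se` (\eqn{1/\sqrt{I(\hat\theta)}}),
#'   `method = "WLE"`.
#' @export
wle <- function(items, responses) {
  check_scored(items, responses)
  th <- wle_point(items$a, items$b, responses)
  tibble(theta = th,
         se = 1 / sqrt(test_info(items, th)),
         method = "WLE")
}

# numeric kernel shared by wle() and the CAT runner
wle_point <- function(a, b, u, grid_by = 0.1) {
  g <- seq(THETA_RANGE[1], THETA_RANGE[2], by = grid_by)
  x <- outer(a, g) - a * b
  lp <- plogis(x, log.p = TRUE)
  lq <- plogis(-x, log.p = TRUE)
  P <- plogis(x)
  ll <- colSums(u * lp + (1 - u) * lq)
  info_g <- colSums(a^2 * P * (1 - P))
  wll <- ll + 0.5 * log(info_g)
  k <- which.max(wll)
  lo <- g[max(k - 1L, 1L)]
  hi <- g[min(k + 1L, length(g))]
  score <- function(th) {
    p <- plogis(a * (th - b))
    inf <- sum(a^2 * p * (1 - p))
    dinf <- sum(a^3 * p * (1 - p) * (1 - 2 * p))
    sum(a * (u - p)) + dinf / (2 * inf)
  }
  s_lo <- score(lo); s_hi <- score(hi)
  if (is.finite(s_lo) && is.finite(s_hi) && s_lo > 0 && s_hi < 0) {
    uniroot(score, c(lo, hi), tol = 1e-9)$root
  } else if (k == 1L || k == length(g)) {
    g[k]
  } else {
    optimize(function(th) {
      p_lp <- plogis(a * (th - b), log.p = TRUE)
      p_lq <- plogis(-a * (th - b), log.p = TRUE)
      p <- plogis(a * (th - b))
      sum(u * p_lp + (1 - u) * p_lq) +
        0.5 * log(sum(a^2 * p * (1 - p)))
    }, c(lo, hi), maximum = TRUE, tol = 1e-9)$maximum
  }
}

#' Measurement-error bias function of the WLE
#'
#' Approximate bias \eqn{B(\theta) = [D(\theta) + J(\theta)] / I(\theta)} of
#' the naive WLE when the administered items' parameters are estimates rather
#' than known values. \eqn{D} carries the item-parameter biases
#' \eqn{(\delta_a, \delta_b)}; \eqn{J = J_1 + J_2 + J_3} carries the squared
#' errors, with \eqn{J_1} weighted by \eqn{\sigma_a^2 + \delta_a^2},
#' \eqn{J_2} by \eqn{\sigma_b^2 + \delta_b^2} and \eqn{J_3} by
#' \eqn{\sigma_{ab} + \delta_a\delta_b}. With all error inputs zero the bias
#' is identically zero.
#'
#' @param theta Ability value(s) at which to evaluate the bias.
#' @param items Data frame of administered items with plug-in point estimates
#'   `a`, `b` and error metadata `se_a`, `se_b`, `cov_ab`, `delta_a`,
#'   `delta_b` (missing error columns are taken as zero).
#' @return Numeric vector of bias values, one per element of `theta`.
#' @export
bias_function <- function(theta, items) {
  er <- error_inputs(items)
  a <- items$a; b <- items$b
  vapply(theta, function(th) {
    p <- plogis(a * (th - b))
    Ii <- a^2 * p * (1 - p)
    I <- sum(Ii)
    if (!is.finite(I) || I <= 0)
      abort("Degenerate test information: B(theta) undefined.",
            class = "calicat_degenerate_information")
    res <- th - b
    curv <- 1 - a * res * (p - 0.5)
    D <- sum(Ii * er$delta_b) - sum((res / a) * Ii * er$delta_a)
    J1 <- sum((res / a^2) * curv * Ii * (er$var_a + er$delta_a^2))
    J2 <- sum(a * (p - 0.5) * Ii * (er$var_b + er$delta_b^2))
    J3 <- sum((2 / a) * curv * Ii * (er$cov_ab + er$delta_a * er$delta_b))
    (D + J1 + J2 + J3) / I
  }, numeric(1))
}

error_inputs <- function(items) {
  n <- nrow(items)
  grab <- function(col) if (col %in% names(items)) items[[col]] else rep(0, n)
  se_a <- grab("se_a"); se_b <- grab("se_b")
  if (any(se_a < 0) || any(se_b < 0)) abort("Standard errors must be >= 0.")
  list(var_a = se_a^2, var_b = se_b^2, cov_ab = grab("cov_ab"),
       delta_a = grab("delta_a"), delta_b = grab("delta_b"))
}

#' Bias-corrected weighted likelihood estimate (cWLE)
#'
#' Computes the WLE, evaluates the measurement-error bias function at the WLE,
#' and subtracts it: \eqn{\hat\theta_{cWLE} = \hat\theta_{WLE} -
#' \hat B(\hat\theta_{WLE})}. The correction is applied once (no iteration);
#' its magnitude is capped at `cap` before subtraction to guard against the
#' near-zero test information of very short provisional tests, and the result
#' is clipped to the working range \[-6, 6\]. The SE is reported at the
#' corrected point.
#'
#' @inheritParams bias_function
#' @param responses Integer 0/1 vector aligned with `items`.
#' @param cap Maximum correction magnitude (default 2).
#' @return One-row tibble: `theta`, `se`, `method = "cWLE"`, `correction`
#'   (the subtracted bias, after capping).
#' @export
cwle <- function(items, responses, cap = 2) {
  check_scored(items, responses)
  th_wle <- wle_point(items$a, items$b, responses)
  B <- bias_function(th_wle, items)
  Bc <- sign(B) * min(abs(B), cap)
  th <- min(max(th_wle - Bc, THETA_RANGE[1]), THETA_RANGE[2])
  tibble(theta = th,
         se = 1 / sqrt(test_info(items, th)),
         method = "cWLE",
         correction = Bc)
}

check_scored <- function(items, responses) {
  if (length(responses) < 1L) abort("At least one response is required.")
  if (nrow(items) != length(responses))
    abort("`items` and `responses` must align row-for-row.")
  if (!all(responses %in% c(0L, 1L))) abort("Responses must be 0/1.")
  check_item_params(items$a, items$b)
  invisible(TRUE)
}
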