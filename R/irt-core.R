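#' Two-parameter logistic response probability
#'
#' Probability of a correct response under the 2PL item response model,
#' \deqn{P(u = 1 \mid \theta, a, b) = \frac{\exp(a(\theta - b))}{1 + \exp(a(\theta - b))},}
#' where `a` is the item discrimination and `b` the item difficulty on the
#' ability metric. The logistic is evaluated in a numerically stable form, so
#' large \eqn{|a(\theta - b)|} does not overflow.
#'
#' `theta` and the item parameters are recycled against each other, so a scalar
#' ability with vectors `a`, `b` gives one probability per item.
#'
#' @param theta Ability value(s) on the standard-normal metric of the
#'   calibration population.
#' @param a Discrimination parameter(s), strictly positive.
#' @param b Difficulty parameter(s).
#' @return Numeric vector of probabilities in (0, 1).
#' @examples
#' prob_2pl(0, a = 1, b = 0)   # 0.5 at theta = b
#' prob_2pl(1, a = 2, b = 0)   # 1 / (1 + exp(-2))
#' @export
prob_2pl <- function(theta, a, b) {
  check_item_params(a, b)
  if (!all(is.finite(theta))) abort("`theta` must be finite.")
  plogis(a * (theta - b))
}

#' Fisher information of a 2PL item
#'
#' \eqn{I(\theta) = a^2 P(\theta)(1 - P(\theta))}, maximized at
#' \eqn{\theta = b} with value \eqn{a^2 / 4}.
#'
#' @inheritParams prob_2pl
#' @return Nonnegative numeric vector.
#' @export
item_info <- function(theta, a, b) {
  p <- prob_2pl(theta, a, b)
  a^2 * p * (1 - p)
}

#' Test information of an item set
#'
#' Sum of [item_info()] over the rows of `items`. An empty item set has zero
#' information.
#'
#' @param items Data frame with columns `a` and `b`, one row per item.
#' @param theta Single ability value.
#' @return Nonnegative scalar.
#' @export
test_info <- function(items, theta) {
  if (nrow(items) == 0L) return(0)
  sum(item_info(theta, items$a, items$b))
}

# derivative of test information wrt theta: sum a^3 P (1 - P)(1 - 2P)
test_info_deriv <- function(items, theta) {
  if (nrow(items) == 0L) return(0)
  p <- prob_2pl(theta, items$a, items$b)
  sum(items$a^3 * p * (1 - p) * (1 - 2 * p))
}

#' Simulate dichotomous 2PL responses
#'
#' Bernoulli draws with success probability [prob_2pl()], one per row of
#' `items`. Randomness comes from the current RNG stream unless `seed` is
#' given, in which case the stream is set locally and restored afterwards.
#'
#' @inheritParams test_info
#' @param seed Optional integer seed applied locally via [withr::local_seed()].
#' @return Integer vector of 0/1 responses, one per item.
#' @export
simulate_response <- function(items, theta, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  p <- prob_2pl(theta, items$a, items$b)
  as.integer(runif(length(p)) < p)
}

check_item_params <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b)))
    abort("Item parameters must be finite.")
  if (any(a <= 0)) abort("Discrimination `a` must be strictly positive.")
  invisible(TRUE)
}

# working ability range used by every optimizer / grid in the package
THETA_RANGE <- c(-6, 6)
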