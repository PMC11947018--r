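#' Maximum-information item selection
#'
#' Returns the not-yet-administered item maximizing Fisher information at the
#' current provisional ability point estimate, using the calibrated point
#' parameters. Exact criterion ties are broken uniformly at random using the
#' current RNG stream; the stream is only consumed when a tie actually occurs,
#' so tie-free selection sequences are reproducible independently of it.
#'
#' @param pool Calibrated pool tibble with `item_id`, `a`, `b`.
#' @param theta_hat Provisional ability point estimate.
#' @param administered Character vector of already-administered item ids.
#' @return A single `item_id`.
#' @export
select_mi <- function(pool, theta_hat, administered = character()) {
  remaining <- !(pool$item_id %in% administered)
  if (!any(remaining))
    abort("Item pool exhausted.", class = "calicat_pool_exhausted")
  crit <- rep(-Inf, nrow(pool))
  crit[remaining] <- item_info(theta_hat, pool$a[remaining], pool$b[remaining])
  pick_argmax(pool$item_id, crit)
}

#' Bayesian maximum-information item selection
#'
#' Bayesian version of the MI criterion: for each remaining item the Fisher
#' information is averaged over `S` draw pairs, with ability draw
#' \eqn{\theta^{(s)}} paired to item-parameter draw \eqn{\xi^{(s)}} by draw
#' index, \deqn{S^{-1}\sum_s I_i(\theta^{(s)}; a_i^{(s)}, b_i^{(s)}).}
#' With all draws degenerate at point estimates this reduces exactly to
#' [select_mi()]. Ties are broken as in [select_mi()].
#'
#' @param draws A [draw_store()] of item-parameter draws (posterior draws or
#'   normal pseudo-draws), `S` draws per item.
#' @param theta_draws Numeric vector of `S` ability draws.
#' @param administered Character vector of already-administered item ids.
#' @return A single `item_id`.
#' @export
select_bmi <- function(draws, theta_draws, administered = character()) {
  if (length(theta_draws) != draws$S)
    abort("`theta_draws` must have one draw per stored item-parameter draw.")
  remaining <- !(draws$item_id %in% administered)
  if (!any(remaining))
    abort("Item pool exhausted.", class = "calicat_pool_exhausted")
  crit <- cpp_bmi_criterion(draws$a, draws$b, theta_draws)
  crit[!remaining] <- -Inf
  pick_argmax(draws$item_id, crit)
}

# argmax with uniform random tie-breaking; RNG consumed only on actual ties
pick_argmax <- function(ids, crit) {
  best <- which(crit == max(crit))
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  ids[best]
}

#' Per-item BMI criterion values
#'
#' The draw-averaged information values that [select_bmi()] maximizes,
#' returned for every item (useful for diagnostics and testing).
#'
#' @inheritParams select_bmi
#' @return Named numeric vector, one value per item.
#' @export
bmi_criterion <- function(draws, theta_draws) {
  if (length(theta_draws) != draws$S)
    abort("`theta_draws` must have one draw per stored item-parameter draw.")
  setNames(cpp_bmi_criterion(draws$a, draws$b, theta_draws), draws$item_id)
}
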