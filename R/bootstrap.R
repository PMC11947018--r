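#' Bootstrap calibration-error and bias estimates for item parameters
#'
#' Nonparametric bootstrap of the MML calibration: respondents are resampled
#' with replacement within their test form (preserving the linked design),
#' the 2PL is refit on each replication (warm-started at the full-data
#' estimates), and per item the replication-to-replication covariance of
#' \eqn{(\hat a, \hat b)} estimates the calibration-error covariance
#' \eqn{\Sigma_i}, while the mean bootstrap estimate minus the full-data
#' estimate estimates the biases \eqn{(\delta_a, \delta_b)}.
#'
#' Replications in which some item becomes all-correct or all-incorrect are
#' redrawn (up to `retry_cap` attempts per replication, with a message).
#'
#' @param data A [simulate_calibration_data()] object.
#' @param fit The full-data [fit_2pl_mml()] fit of `data`.
#' @param n_reps Number of bootstrap replications (default 200).
#' @param retry_cap Maximum redraws per replication for degenerate resamples.
#' @param seed Optional integer seed (applied locally).
#' @return Calibrated-pool tibble: `item_id`, `a`, `b` (full-data estimates),
#'   `se_a`, `se_b`, `cov_ab` (bootstrap SDs / covariance), `delta_a`,
#'   `delta_b` (bootstrap bias estimates).
#' @export
bootstrap_item_errors <- function(data, fit, n_reps = 200, retry_cap = 20,
                                  seed = NULL) {
  if (!inherits(data, "calib_data")) abort("`data` must be a `calib_data`.")
  if (!inherits(fit, "mml_2pl")) abort("`fit` must be an `mml_2pl` fit.")
  if (!is.null(seed)) withr::local_seed(seed)
  U <- data$responses
  keep <- setdiff(colnames(U), fit$excluded)
  U <- U[, keep, drop = FALSE]
  form <- data$respondents$form
  form_rows <- split(seq_len(nrow(U)), form)
  item_id <- fit$items$item_id
  boot_a <- matrix(NA_real_, n_reps, length(item_id))
  boot_b <- matrix(NA_real_, n_reps, length(item_id))
  redraws <- 0L
  for (r in seq_len(n_reps)) {
    for (try in seq_len(retry_cap)) {
      rows <- unlist(lapply(form_rows, function(z)
        z[sample.int(length(z), length(z), replace = TRUE)]),
        use.names = FALSE)
      Ub <- U[rows, , drop = FALSE]
      nc <- colSums(Ub, na.rm = TRUE)
      no <- colSums(!is.na(Ub))
      if (all(nc > 0 & nc < no)) break
      redraws <- redraws + 1L
      if (try == retry_cap)
        abort("Bootstrap retry cap reached: degenerate items in every resample.")
    }
    bf <- fit_2pl_mml(Ub, n_quad = fit$n_quad, tol = fit$tol,
                      start = fit$items)
    idx <- match(item_id, bf$items$item_id)
    boot_a[r, ] <- bf$items$a[idx]
    boot_b[r, ] <- bf$items$b[idx]
  }
  if (redraws > 0)
    inform(paste0("Redrew ", redraws, " degenerate bootstrap resample(s)."))
  out <- tibble(
    item_id = item_id,
    a = fit$items$a,
    b = fit$items$b,
    se_a = apply(boot_a, 2, sd),
    se_b = apply(boot_b, 2, sd),
    cov_ab = vapply(seq_along(item_id),
                    function(i) cov(boot_a[, i], boot_b[, i]), numeric(1)),
    delta_a = colMeans(boot_a) - fit$items$a,
    delta_b = colMeans(boot_b) - fit$items$b
  )
  attr(out, "replicates") <- list(a = boot_a, b = boot_b)
  out
}
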