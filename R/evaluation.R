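#' Conditional bias of ability estimates
#'
#' Mean signed error \eqn{N^{-1}\sum_j (\hat\theta_j - \theta)} of final
#' ability estimates at one fixed true ability level.
#'
#' @param estimates Numeric vector of final ability estimates.
#' @param true_theta The common true ability of these testees.
#' @return Scalar bias.
#' @export
conditional_bias <- function(estimates, true_theta) {
  if (length(estimates) < 1L) abort("At least one estimate is required.")
  mean(estimates - true_theta)
}

#' Conditional mean squared error of ability estimates
#'
#' Mean squared error \eqn{N^{-1}\sum_j (\hat\theta_j - \theta)^2} at one
#' fixed true ability level. Always at least the squared conditional bias.
#'
#' @inheritParams conditional_bias
#' @return Scalar MSE.
#' @export
conditional_mse <- function(estimates, true_theta) {
  if (length(estimates) < 1L) abort("At least one estimate is required.")
  mean((estimates - true_theta)^2)
}

#' Summarize simulated conditions by true ability level
#'
#' Conditional bias and MSE per true ability level (and any further grouping
#' columns present, e.g. `approach`), with Monte Carlo standard errors: for
#' the bias the SE of the mean error, for the MSE the SE of the mean squared
#' error (delta method / SE of the mean of squared errors). The `+/- 2 SE`
#' band convention of simulation reports corresponds to twice these columns.
#'
#' @param results Tibble of session results with columns `true_theta`,
#'   `theta_hat` and optionally `approach` (as produced by [run_condition()]).
#' @param ... Additional grouping columns (tidy-select, e.g. factor columns of
#'   a crossed design).
#' @return Tibble with `bias`, `mse`, `n`, `se_bias`, `se_mse` per group x
#'   ability level.
#' @export
condition_summary <- function(results, ...) {
  grp <- c(intersect(c("approach", "test_length", "n_per_item"),
                     names(results)), "true_theta")
  results |>
    mutate(err = .data$theta_hat - .data$true_theta) |>
    group_by(dplyr::across(dplyr::all_of(grp)), ...) |>
    summarise(
      bias = mean(.data$err),
      mse = mean(.data$err^2),
      n = dplyr::n(),
      se_bias = sd(.data$err) / sqrt(dplyr::n()),
      se_mse = sd(.data$err^2) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Relative bias reduction versus a baseline approach
#'
#' Per true ability level, the percentage reduction in absolute conditional
#' bias of each approach relative to the baseline,
#' \deqn{100\,(1 - |bias_{approach}| / |bias_{baseline}|).}
#' Levels where the baseline bias is exactly zero are reported as `NA` (the
#' reduction is undefined there). The summary attribute reports, per
#' approach, the most extreme (maximum) reduction over levels.
#'
#' @param summary_tbl A [condition_summary()] tibble containing an `approach`
#'   column that includes the baseline.
#' @param baseline Name of the baseline approach (default `"none"`).
#' @return Tibble with `approach`, `true_theta`, `bias`, `baseline_bias`,
#'   `reduction_pct`; per-approach maxima in attribute `"max_reduction"`.
#' @export
bias_reduction_table <- function(summary_tbl, baseline = "none") {
  if (!baseline %in% summary_tbl$approach)
    abort(paste0("Baseline approach '", baseline, "' not present."))
  keys <- c(intersect(c("test_length", "n_per_item"), names(summary_tbl)),
            "true_theta")
  base <- summary_tbl |>
    filter(.data$approach == baseline) |>
    select(dplyr::all_of(keys), baseline_bias = "bias")
  out <- summary_tbl |>
    filter(.data$approach != baseline) |>
    left_join(base, by = keys) |>
    mutate(reduction_pct = ifelse(
      .data$baseline_bias == 0, NA_real_,
      100 * (1 - abs(.data$bias) / abs(.data$baseline_bias)))) |>
    select("approach", dplyr::all_of(keys), "bias", "baseline_bias",
           "reduction_pct")
  mx <- out |>
    group_by(.data$approach) |>
    summarise(max_reduction = max(.data$reduction_pct, na.rm = TRUE),
              .groups = "drop")
  attr(out, "max_reduction") <- mx
  out
}
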