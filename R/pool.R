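#' Generate a synthetic 2PL item pool
#'
#' Discriminations are drawn from a lognormal distribution with log-mean
#' `meanlog` and log-SD `sdlog` (defaults logN(0, 0.25) read as log-variance
#' 0.25, i.e. log-SD 0.5), difficulties from N(`b_mean`, `b_sd`^2) (default
#' standard normal). These defaults reproduce a typical operational pool with
#' discriminations mostly between 0.4 and 2.7.
#'
#' @param n_items Number of items (>= 1).
#' @param meanlog,sdlog Log-scale mean and SD of the discrimination
#'   distribution.
#' @param b_mean,b_sd Mean and SD of the difficulty distribution.
#' @param seed Optional integer seed (applied locally).
#' @return Tibble with columns `item_id`, `a`, `b`.
#' @export
generate_item_pool <- function(n_items, meanlog = 0, sdlog = 0.5,
                               b_mean = 0, b_sd = 1, seed = NULL) {
  if (!is.numeric(n_items) || length(n_items) != 1L || n_items < 1)
    abort("`n_items` must be a single count >= 1.")
  if (!is.null(seed)) withr::local_seed(seed)
  n_items <- as.integer(n_items)
  tibble(
    item_id = sprintf("i%04d", seq_len(n_items)),
    a = rlnorm(n_items, meanlog = meanlog, sdlog = sdlog),
    b = rnorm(n_items, mean = b_mean, sd = b_sd)
  )
}

#' Build a circularly linked calibration design
#'
#' Items are randomly partitioned into `n_clusters` clusters of `cluster_size`
#' items. Test form f is the union of clusters f and f + 1, with form
#' `n_clusters` closing the circle (clusters `n_clusters` and 1), so there are
#' exactly `n_clusters` forms and every item appears in exactly two forms.
#'
#' @param pool Item pool tibble (needs `item_id`); its size must equal
#'   `n_clusters * cluster_size`.
#' @param n_clusters Number of item clusters (and forms).
#' @param cluster_size Items per cluster.
#' @param seed Optional integer seed (applied locally).
#' @return An object of class `linked_design`: list with `clusters` (tibble
#'   `item_id`, `cluster`), `forms` (tibble `form`, `cluster_1`, `cluster_2`),
#'   and `form_items` (named list of item-id vectors).
#' @export
build_linked_design <- function(pool, n_clusters = 20, cluster_size = 15,
                                seed = NULL) {
  if (nrow(pool) != n_clusters * cluster_size)
    abort("Pool size must equal `n_clusters * cluster_size`.")
  if (!is.null(seed)) withr::local_seed(seed)
  ids <- sample(pool$item_id)
  clusters <- tibble(
    item_id = ids,
    cluster = rep(seq_len(n_clusters), each = cluster_size)
  )
  forms <- tibble(
    form = seq_len(n_clusters),
    cluster_1 = seq_len(n_clusters),
    cluster_2 = c(seq_len(n_clusters)[-1], 1L)
  )
  form_items <- lapply(seq_len(n_clusters), function(f) {
    cl <- c(forms$cluster_1[f], forms$cluster_2[f])
    clusters$item_id[clusters$cluster %in% cl]
  })
  names(form_items) <- paste0("form", forms$form)
  structure(
    list(clusters = clusters, forms = forms, form_items = form_items,
         n_clusters = n_clusters, cluster_size = cluster_size),
    class = "linked_design"
  )
}

#' @export
print.linked_design <- function(x, ...) {
  cat("Linked calibration design:", x$n_clusters, "clusters of",
      x$cluster_size, "items;", nrow(x$forms), "forms of",
      2L * x$cluster_size, "items (circular overlap)\n")
  invisible(x)
}

#' Simulate linked calibration data
#'
#' Assigns `n_per_item / 2` respondents to each test form, draws their
#' abilities from N(0, 1), and simulates 2PL responses to the form's items.
#' Because every item sits in exactly two forms, each item column receives
#' exactly `n_per_item` observed responses; cells outside a respondent's form
#' are missing by design.
#'
#' @param pool Item pool tibble with `item_id`, `a`, `b` (generating values).
#' @param design A [build_linked_design()] object over the same pool.
#' @param n_per_item Even number of responses per item.
#' @param seed Optional integer seed (applied locally).
#' @return An object of class `calib_data`: list with `responses` (respondent
#'   x item matrix, `NA` = not administered), `respondents` (tibble
#'   `respondent`, `form`, `theta`), and `item_id`.
#' @export
simulate_calibration_data <- function(pool, design, n_per_item, seed = NULL) {
  if (n_per_item %% 2 != 0) abort("`n_per_item` must be even.")
  if (!is.null(seed)) withr::local_seed(seed)
  n_forms <- nrow(design$forms)
  per_form <- n_per_item / 2
  n_resp <- n_forms * per_form
  resp <- matrix(NA_integer_, nrow = n_resp, ncol = nrow(pool),
                 dimnames = list(NULL, pool$item_id))
  respondents <- tibble(
    respondent = seq_len(n_resp),
    form = rep(design$forms$form, each = per_form),
    theta = rnorm(n_resp)
  )
  pool_idx <- setNames(seq_len(nrow(pool)), pool$item_id)
  for (f in design$forms$form) {
    ids <- design$form_items[[paste0("form", f)]]
    rows <- which(respondents$form == f)
    cols <- pool_idx[ids]
    p <- plogis(outer(respondents$theta[rows], rep(1, length(cols))) *
                  rep(pool$a[cols], each = length(rows)) -
                  rep(pool$a[cols] * pool$b[cols], each = length(rows)))
    resp[rows, cols] <- matrix(as.integer(runif(length(p)) < p),
                               nrow = length(rows))
  }
  structure(
    list(responses = resp, respondents = respondents, item_id = pool$item_id),
    class = "calib_data"
  )
}

#' @export
print.calib_data <- function(x, ...) {
  cat("Calibration data:", nrow(x$responses), "respondents x",
      ncol(x$responses), "items;",
      sum(!is.na(x$responses)), "observed responses\n")
  invisible(x)
}
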