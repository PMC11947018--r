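#' Read and write item-pool tables
#'
#' Item pools and calibrated pools are stored as tab-delimited text with a
#' header row: `item_id`, `a`, `b`, and optionally `se_a`, `se_b`, `cov_ab`,
#' `delta_a`, `delta_b`. One row per item, decimal points, no thousands
#' separators.
#'
#' @param pool Pool tibble.
#' @param path File path.
#' @return `read_item_pool()` returns a tibble; `write_item_pool()` returns
#'   `path` invisibly.
#' @export
write_item_pool <- function(pool, path) {
  readr::write_tsv(pool, path)
  invisible(path)
}

#' @rdname write_item_pool
#' @export
read_item_pool <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(item_id = readr::col_character(),
                                          .default = readr::col_double()))
}

#' Read and write draw stores
#'
#' Long delimited format with columns `item_id`, `draw`, `a`, `b`; values are
#' written with 15 significant digits so a round trip is lossless at that
#' precision.
#'
#' @param draws A [draw_store()].
#' @param path File path.
#' @return `read_draw_store()` returns a `draw_store`; the writer returns
#'   `path` invisibly.
#' @export
write_draw_store <- function(draws, path) {
  tbl <- as_tibble(draws)
  tbl$a <- formatC(tbl$a, digits = 15, format = "g")
  tbl$b <- formatC(tbl$b, digits = 15, format = "g")
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_draw_store
#' @export
read_draw_store <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           item_id = readr::col_character(),
                           draw = readr::col_integer(),
                           a = readr::col_double(),
                           b = readr::col_double()))
  ids <- unique(tbl$item_id)
  S <- max(tbl$draw)
  A <- matrix(tbl$a, nrow = S)
  B <- matrix(tbl$b, nrow = S)
  draw_store(A, B, ids)
}

#' Read and write response matrices
#'
#' Respondent-by-item tables as comma-delimited text with item ids as the
#' header; empty cells are missing-by-design.
#'
#' @param data A [simulate_calibration_data()] object or response matrix.
#' @param path File path.
#' @return `read_responses()` returns a respondent x item integer matrix with
#'   `NA` for missing cells.
#' @export
write_responses <- function(data, path) {
  U <- if (inherits(data, "calib_data")) data$responses else as.matrix(data)
  readr::write_csv(as.data.frame(U), path, na = "")
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_integer()))
  as.matrix(tbl)
}

#' Export an evaluation result table
#'
#' One row per factor cell x true ability level with the conditional bias,
#' MSE, cell size and Monte Carlo SEs, as tab-delimited text.
#'
#' @param summary_tbl A [condition_summary()] tibble.
#' @param path File path.
#' @export
write_results_table <- function(summary_tbl, path) {
  readr::write_tsv(summary_tbl, path)
  invisible(path)
}
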