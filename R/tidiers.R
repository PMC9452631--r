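#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Granger-causality result
#'
#' @param x A `gc_result` from [gc_test()].
#' @param ... Unused.
#' @return Tibble with one row per direction: `direction`, `f_stat`,
#'   `p_raw`, `model_order`, `n_obs`.
#' @export
tidy.gc_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("direction", "f_stat", "p_raw", "model_order", "n_obs")]
}

#' Tidy aggregated Granger outcomes (one row per pair x direction)
#' @param x A `gc_group` from [aggregate_gc()].
#' @param ... Unused.
#' @export
tidy.gc_group <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of aggregated Granger outcomes
#'
#' @param x A `gc_group` from [aggregate_gc()].
#' @param ... Unused.
#' @return One row per direction with the group-mean significance rate.
#' @export
glance.gc_group <- function(x, ...) attr(x, "direction_means")

#' Tidy a group comparison
#' @param x A `group_comparison` from [rank_sum()] or [ks_compare()].
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) tibble::as_tibble(x)

#' One-row event-table overview
#'
#' @param x A `swr_events` table.
#' @param ... Unused.
#' @return Tibble: `n_events`, `mean_duration_ms`, `mean_amplitude`,
#'   and the co-occurrence percentage when sharp-wave flags are present.
#' @export
glance.swr_events <- function(x, ...) {
  tibble::tibble(
    n_events = nrow(x),
    mean_duration_ms = if (nrow(x)) mean(x$duration_ms) else NA_real_,
    mean_amplitude = if (nrow(x)) mean(x$amplitude) else NA_real_,
    co_occurrence_pct = attr(x, "co_occurrence_pct") %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
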