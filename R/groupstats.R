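#' Average per-session metric values within each electrode
#'
#' Electrodes recorded over several sessions contribute one value per metric:
#' the arithmetic mean over their sessions. Electrodes are treated as
#' independent statistical units downstream.
#'
#' @param data Tibble with one row per electrode x session and a numeric
#'   `value` column.
#' @param ... Grouping columns identifying an electrode (unquoted), e.g.
#'   `electrode_id, genotype, region, metric`.
#' @return Tibble with one row per group and columns `value` (mean) and
#'   `n_sessions`.
#' @export
session_average <- function(data, ...) {
  data |>
    dplyr::group_by(...) |>
    dplyr::summarise(value = mean(.data$value), n_sessions = dplyr::n(),
                     .groups = "drop")
}

#' Two-sample Wilcoxon rank-sum comparison
#'
#' Two-sided. The exact null distribution is used for small untied samples
#' (`n_a + n_b <= 20`, no ties); otherwise the normal approximation with tie
#' and continuity correction.
#'
#' @param a,b Numeric vectors (e.g. per-electrode session-averaged metrics).
#' @return One-row tibble of class `group_comparison`: `test`, `statistic`
#'   (Mann-Whitney U for group a), `p_value`, group sizes, means and
#'   standard errors.
#' @export
rank_sum <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both groups need >= 1 value", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 20) && !ties
  wt <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  comparison_row("rank_sum", unname(wt$statistic), wt$p.value, a, b)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided: `D = sup |ECDF_a - ECDF_b|`, asymptotic p-value.
#'
#' @inheritParams rank_sum
#' @return One-row `group_comparison` tibble (statistic = D).
#' @export
ks_compare <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both groups need >= 1 value", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  comparison_row("ks", unname(kt$statistic), kt$p.value, a, b)
}

comparison_row <- function(test, statistic, p, a, b) {
  out <- tibble::tibble(
    test = test, statistic = statistic, p_value = p,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    se_a = stats::sd(a) / sqrt(length(a)),
    se_b = stats::sd(b) / sqrt(length(b))
  )
  class(out) <- c("group_comparison", class(out))
  out
}

#' Compare two groups, pooling sexes when they do not differ
#'
#' Mirrors the screening used for mixed-sex cohorts: within each group the
#' two sexes are first compared by rank-sum; if neither within-group sex
#' difference is significant at `alpha`, sexes are pooled and the two groups
#' compared directly. If a sex difference is found, the comparison is run
#' per sex and both rows returned.
#'
#' @param data Tibble with columns `value`, `group` (2 levels), `sex`.
#' @param alpha Level for the sex-difference screen.
#' @return A `group_comparison` tibble (one row if pooled, one per sex
#'   otherwise) with a `stratum` column.
#' @export
compare_pooling_sexes <- function(data, alpha = 0.05) {
  stopifnot(all(c("value", "group", "sex") %in% names(data)))
  groups <- unique(data$group)
  if (length(groups) != 2) stop("`group` must have exactly 2 levels", call. = FALSE)
  sex_p <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::group_map(function(df, key) {
      sx <- unique(df$sex)
      if (length(sx) != 2) return(1)
      rank_sum(df$value[df$sex == sx[1]], df$value[df$sex == sx[2]])$p_value
    })
  if (all(unlist(sex_p) >= alpha)) {
    out <- rank_sum(data$value[data$group == groups[1]],
                    data$value[data$group == groups[2]])
    out$stratum <- "pooled"
    return(out)
  }
  out <- purrr::map(unique(data$sex), function(sx) {
    d <- data[data$sex == sx, ]
    row <- rank_sum(d$value[d$group == groups[1]], d$value[d$group == groups[2]])
    row$stratum <- sx
    row
  })
  dplyr::bind_rows(out)
}

#' Duration-fraction histogram and cumulative curve
#'
#' Bins event durations, normalizes the histogram to sum to 1, and
#' accumulates it into a nondecreasing cumulative-fraction curve ending at 1
#' (the standard way short- vs long-ripple prevalence is displayed).
#'
#' @param events Event table from [detect_events()], or a numeric vector of
#'   durations in ms.
#' @param bin_ms Histogram bin width, ms.
#' @return Tibble of class `duration_curve`: `duration_ms` (right bin edge),
#'   `fraction`, `cumulative`.
#' @export
duration_fraction_curve <- function(events, bin_ms = 5) {
  d <- if (is.numeric(events)) events else events$duration_ms
  if (length(d) == 0) stop("no events: duration curve undefined", call. = FALSE)
  edges <- seq(0, (max(d) %/% bin_ms + 1) * bin_ms, by = bin_ms)
  h <- graphics::hist(d, breaks = edges, plot = FALSE, right = TRUE)
  frac <- h$counts / length(d)
  out <- tibble::tibble(duration_ms = edges[-1], fraction = frac,
                        cumulative = cumsum(frac))
  class(out) <- c("duration_curve", class(out))
  out
}
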