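#' Event-sparsified envelope series
#'
#' Keeps the envelope z-value wherever it exceeds the detection threshold and
#' zeroes it elsewhere, producing the sparse series fed to the Granger
#' causality test. No immobility gating is applied here: all supra-threshold
#' bins enter, regardless of running speed, so the series does not become too
#' sparse for autoregressive modeling.
#'
#' @param envz An [ripple_envelope_z()] result.
#' @param threshold_sd Sparsification threshold (envelope SDs).
#' @return Object of class `sparse_z`: list with `values`, `fs`, `threshold`,
#'   provenance fields, and `empty` (TRUE when no bin survived).
#' @export
sparsify <- function(envz, threshold_sd = 5.0) {
  v <- ifelse(envz$z > threshold_sd, envz$z, 0)
  structure(
    list(values = v, fs = envz$fs, threshold = threshold_sd,
         empty = !any(v > 0), region = envz$region,
         electrode_id = envz$electrode_id, session_id = envz$session_id),
    class = "sparse_z"
  )
}

#' @export
print.sparse_z <- function(x, ...) {
  cat(sprintf("<sparse_z> %s/%s: %d samples @ %g Hz, %.3g%% nonzero%s\n",
              x$session_id, x$electrode_id, length(x$values), x$fs,
              100 * mean(x$values > 0), if (x$empty) " (EMPTY)" else ""))
  invisible(x)
}

as_gc_series <- function(x) {
  if (inherits(x, "sparse_z")) x$values else as.numeric(x)
}

# Design matrix bookkeeping for a bivariate VAR conditioned on `p0` presample
# values: response rows t = p0+1 .. n, regressors [1, x lags 1..P, y lags 1..P].
var_design <- function(x, y, max_order) {
  n <- length(x)
  stopifnot(length(y) == n, n > max_order + 2)
  rows <- (max_order + 1):n
  N <- length(rows)
  Z <- matrix(1, N, 1 + 2 * max_order)
  for (k in seq_len(max_order)) {
    Z[, 1 + k] <- x[rows - k]
    Z[, 1 + max_order + k] <- y[rows - k]
  }
  Y <- cbind(x[rows], y[rows])
  list(Z = Z, Y = Y, N = N, P = max_order)
}

# residual sum-of-squares matrix for the regression of Y on Z[, idx],
# computed from precomputed Gram blocks
rss_from_gram <- function(G, C, S, idx) {
  Gs <- G[idx, idx, drop = FALSE]
  Cs <- C[idx, , drop = FALSE]
  beta <- tryCatch(solve(Gs, Cs), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  S - crossprod(Cs, beta)
}

#' Select the VAR model order for a series pair
#'
#' Fits a bivariate VAR(p) by conditional least squares for every
#' `p = 1..max_order` on the common sample (all fits condition on the first
#' `max_order` values, so information criteria are comparable) and returns
#' the order minimizing AIC or BIC; ties go to the smallest order.
#'
#' @param x,y `sparse_z` objects or plain numeric series of equal length.
#' @param criterion `"AIC"` or `"BIC"`.
#' @param max_order Largest candidate order.
#' @return The selected order (integer).
#' @export
select_order <- function(x, y, criterion = c("AIC", "BIC"), max_order = 50) {
  criterion <- match.arg(criterion)
  xv <- as_gc_series(x)
  yv <- as_gc_series(y)
  if (length(xv) <= 10 * max_order) {
    stop("series too short for the requested `max_order`", call. = FALSE)
  }
  if (all(xv == xv[1]) || all(yv == yv[1])) {
    stop("degenerate input: constant series", call. = FALSE)
  }
  d <- var_design(xv, yv, max_order)
  G <- crossprod(d$Z)
  C <- crossprod(d$Z, d$Y)
  S <- crossprod(d$Y)
  P <- d$P
  ic <- vapply(seq_len(max_order), function(p) {
    idx <- c(1L, 1L + seq_len(p), 1L + P + seq_len(p))
    rss <- rss_from_gram(G, C, S, idx)
    if (is.null(rss)) return(Inf)
    sig <- rss / d$N
    ld <- determinant(sig, logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)
    pen <- if (criterion == "AIC") 2 / d$N else log(d$N) / d$N
    as.numeric(ld$modulus) + pen * (4 * p + 2)
  }, double(1))
  if (all(!is.finite(ic))) stop("degenerate input: singular VAR regression", call. = FALSE)
  which.min(ic)
}

#' Bivariate Granger causality test
#'
#' Tests both directions with nested autoregressions estimated by conditional
#' least squares. For the direction x -> y, the restricted model regresses y
#' on its own `order` lags (plus intercept); the full model adds x's lags.
#' The statistic is `F = ((RSS_r - RSS_f)/order) / (RSS_f/(N - 2*order - 1))`
#' with `N` the number of response samples, referred to an
#' `F(order, N - 2*order - 1)` null.
#'
#' @param x,y `sparse_z` objects or numeric series of equal length.
#' @param order VAR order (>= 1); series must be longer than `10 * order`.
#' @param alpha Nominal level stored alongside the raw p-values (used by
#'   [aggregate_gc()] after FDR correction).
#' @param labels Length-2 direction labels, defaults taken from the inputs'
#'   regions when available.
#' @return A tibble of class `gc_result`, one row per direction, with
#'   `direction`, `f_stat`, `p_raw`, `model_order`, `n_obs`, `alpha`.
#' @export
gc_test <- function(x, y, order, alpha = 0.05, labels = NULL) {
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  xv <- as_gc_series(x)
  yv <- as_gc_series(y)
  if (length(xv) != length(yv)) stop("series lengths differ", call. = FALSE)
  if (length(xv) <= 10 * order) stop("series too short for this order", call. = FALSE)
  if (is.null(labels)) {
    labels <- c(if (inherits(x, "sparse_z")) x$region else "x",
                if (inherits(y, "sparse_z")) y$region else "y")
  }
  d <- var_design(xv, yv, order)
  G <- crossprod(d$Z)
  C <- crossprod(d$Z, d$Y)
  S <- crossprod(d$Y)
  P <- order
  one_direction <- function(resp_col, own_cols, other_cols, dir_label) {
    full_idx <- c(1L, own_cols, other_cols)
    restr_idx <- c(1L, own_cols)
    rss_f_m <- rss_from_gram(G, C, S, full_idx)
    rss_r_m <- rss_from_gram(G, C, S, restr_idx)
    if (is.null(rss_f_m) || is.null(rss_r_m)) {
      stop(sprintf("rank-deficient design for direction %s", dir_label), call. = FALSE)
    }
    rss_f <- rss_f_m[resp_col, resp_col]
    rss_r <- rss_r_m[resp_col, resp_col]
    df2 <- d$N - 2 * order - 1
    if (rss_f <= d$N * .Machine$double.eps * stats::var(d$Y[, resp_col])) {
      stop(sprintf("rank-deficient design for direction %s", dir_label), call. = FALSE)
    }
    f <- ((rss_r - rss_f) / order) / (rss_f / df2)
    tibble::tibble(direction = dir_label, f_stat = f,
                   p_raw = stats::pf(f, order, df2, lower.tail = FALSE),
                   model_order = as.integer(order), n_obs = d$N, alpha = alpha)
  }
  own_x <- 1L + seq_len(P)
  own_y <- 1L + P + seq_len(P)
  out <- dplyr::bind_rows(
    one_direction(2L, own_y, own_x, paste0(labels[1], "->", labels[2])),
    one_direction(1L, own_x, own_y, paste0(labels[2], "->", labels[1]))
  )
  class(out) <- c("gc_result", class(out))
  out
}

#' Convenience: order selection plus GC test for one electrode pair
#'
#' @inheritParams gc_test
#' @inheritParams select_order
#' @return A `gc_result` tibble (see [gc_test()]) with the selected order.
#' @export
gc_pair <- function(x, y, criterion = c("AIC", "BIC"), max_order = 50,
                    alpha = 0.05, labels = NULL) {
  p <- select_order(x, y, criterion = criterion, max_order = max_order)
  gc_test(x, y, order = p, alpha = alpha, labels = labels)
}

#' Aggregate Granger outcomes over sessions and electrode pairs
#'
#' Benjamini-Hochberg FDR correction is applied within each session across
#' its whole family of tests (all pairs x both directions); a test is
#' significant iff its adjusted p-value is below `alpha`. Binary
#' significances are then averaged over sessions within each
#' (pair, direction), giving per-pair mean significance rates in `[0, 1]`.
#' Rows with missing p-values (e.g. pairs whose sparse series were empty)
#' are dropped with a message.
#'
#' @param outcomes Tibble with columns `session_id`, `pair_id`, `direction`,
#'   `p_raw` (e.g. stacked [gc_test()] results).
#' @param alpha Significance level applied to FDR-adjusted p-values.
#' @return Tibble of class `gc_group`: `pair_id`, `direction`,
#'   `mean_significance`, `n_sessions`; per-direction group means stored in
#'   attribute `direction_means`.
#' @export
aggregate_gc <- function(outcomes, alpha = 0.05) {
  stopifnot(all(c("session_id", "pair_id", "direction", "p_raw") %in% names(outcomes)))
  if (nrow(outcomes) == 0) stop("empty outcome grid", call. = FALSE)
  dropped <- sum(!is.finite(outcomes$p_raw))
  if (dropped > 0) {
    message(sprintf("dropping %d outcome(s) without a p-value (empty sparse series)", dropped))
    outcomes <- dplyr::filter(outcomes, is.finite(.data$p_raw))
    if (nrow(outcomes) == 0) stop("no usable outcomes after dropping empties", call. = FALSE)
  }
  adj <- outcomes |>
    dplyr::group_by(.data$session_id) |>
    dplyr::mutate(p_fdr = stats::p.adjust(.data$p_raw, method = "BH"),
                  significant = as.integer(.data$p_fdr < alpha)) |>
    dplyr::ungroup()
  per_pair <- adj |>
    dplyr::group_by(.data$pair_id, .data$direction) |>
    dplyr::summarise(mean_significance = mean(.data$significant),
                     n_sessions = dplyr::n(), .groups = "drop")
  dm <- per_pair |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(group_mean = mean(.data$mean_significance), .groups = "drop")
  attr(per_pair, "direction_means") <- dm
  attr(per_pair, "alpha") <- alpha
  class(per_pair) <- c("gc_group", class(per_pair))
  per_pair
}
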