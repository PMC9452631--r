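#' Cross-correlogram of MEC SWRs around CA1 SWRs
#'
#' For every reference (CA1) event peak at time `t`, target (MEC) event peaks
#' `u` with `u - t` in `[-window_ms, +window_ms]` increment the bin containing
#' the lag `u - t`. Counts are normalized by the session's total immobile
#' time, giving a rate in counts per second of immobility per bin. Negative
#' lag means the target (MEC) event precedes the reference (CA1) event.
#'
#' @param ref_events Reference event table (conventionally CA1).
#' @param target_events Target event table (conventionally MEC).
#' @param mask [immobility_mask()] supplying the immobile-time normalizer, or
#'   a single positive number of immobile seconds (useful when working with
#'   event catalogs directly).
#' @param window_ms Half-width of the lag window, ms.
#' @param bin_ms Bin width, ms; bins are centered on multiples of `bin_ms`.
#' @return A tibble of class `cross_correlogram` with columns `lag_ms`
#'   (bin centers) and `rate`; attributes `n_reference`, `n_target`,
#'   `immobile_s`, `bin_ms`.
#' @export
cross_correlogram <- function(ref_events, target_events, mask,
                              window_ms = 100, bin_ms = 5) {
  ti <- if (inherits(mask, "immobility_mask")) immobile_duration(mask) else as.numeric(mask)
  if (length(ti) != 1 || !is.finite(ti) || ti <= 0) {
    stop("zero immobile time: correlogram normalizer undefined", call. = FALSE)
  }
  nb <- floor(window_ms / bin_ms)
  centers <- seq(-nb, nb) * bin_ms
  counts <- numeric(length(centers))
  if (nrow(ref_events) > 0 && nrow(target_events) > 0) {
    tt <- sort(target_events$peak_time)
    w <- window_ms / 1000
    for (t in ref_events$peak_time) {
      lo <- findInterval(t - w - 1e-12, tt) + 1L
      hi <- findInterval(t + w + 1e-12, tt)
      if (hi >= lo) {
        lag_ms <- (tt[lo:hi] - t) * 1000
        b <- round(lag_ms / bin_ms) + nb + 1L
        b <- b[b >= 1 & b <= length(centers)]
        for (j in b) counts[j] <- counts[j] + 1
      }
    }
  }
  out <- tibble::tibble(lag_ms = centers, rate = counts / ti)
  attr(out, "n_reference") <- nrow(ref_events)
  attr(out, "n_target") <- nrow(target_events)
  attr(out, "immobile_s") <- ti
  attr(out, "bin_ms") <- bin_ms
  class(out) <- c("cross_correlogram", class(out))
  out
}

#' Peak lag of a cross-correlogram
#'
#' The rate profile is boxcar-smoothed over `smooth_bins` bins (odd; 1
#' disables smoothing) and the center of the argmax bin is returned. Ties are
#' broken toward the smallest absolute lag, then toward the negative
#' (target-leads) side. An all-zero correlogram has no defined peak and
#' returns `NA`.
#'
#' @param xc A [cross_correlogram()].
#' @param smooth_bins Odd boxcar width in bins.
#' @return Peak lag in ms (negative = target precedes reference), or `NA`.
#' @export
peak_lag <- function(xc, smooth_bins = 3) {
  if (attr(xc, "n_reference") == 0 || all(xc$rate == 0)) return(NA_real_)
  if (smooth_bins %% 2 == 0) stop("`smooth_bins` must be odd", call. = FALSE)
  r <- if (smooth_bins > 1) boxcar_smooth(xc$rate, smooth_bins) else xc$rate
  best <- which(r == max(r))
  if (length(best) > 1) {
    lag <- xc$lag_ms[best]
    best <- best[order(abs(lag), lag)][1]
  }
  xc$lag_ms[best]
}
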