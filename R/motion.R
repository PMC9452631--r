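#' Running speed from a position track
#'
#' Positions are boxcar-smoothed over `smooth_window` seconds (to suppress
#' tracker jitter at the 50 Hz fix rate), then differentiated: interior
#' samples use central differences, the endpoints one-sided differences.
#' Speed is the Euclidean norm of the velocity, cm/s.
#'
#' @param track A [position_track()].
#' @param smooth_window Boxcar width in seconds; 0 disables smoothing.
#' @return A tibble of class `speed_series` with columns `time`, `speed`.
#' @export
compute_speed <- function(track, smooth_window = 0.4) {
  if (nrow(track) < 2) stop("need at least 2 position samples", call. = FALSE)
  if (smooth_window < 0) stop("`smooth_window` must be >= 0", call. = FALSE)
  if (any(diff(track$time) == 0)) stop("duplicate position timestamps", call. = FALSE)
  x <- track$x
  y <- track$y
  tm <- track$time
  if (smooth_window > 0) {
    dt <- stats::median(diff(tm))
    k <- max(1L, round(smooth_window / dt))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1) {
      x <- boxcar_smooth(x, k)
      y <- boxcar_smooth(y, k)
    }
  }
  n <- length(tm)
  vx <- numeric(n)
  vy <- numeric(n)
  idx <- 2:(n - 1)
  vx[idx] <- (x[idx + 1] - x[idx - 1]) / (tm[idx + 1] - tm[idx - 1])
  vy[idx] <- (y[idx + 1] - y[idx - 1]) / (tm[idx + 1] - tm[idx - 1])
  vx[1] <- (x[2] - x[1]) / (tm[2] - tm[1])
  vy[1] <- (y[2] - y[1]) / (tm[2] - tm[1])
  vx[n] <- (x[n] - x[n - 1]) / (tm[n] - tm[n - 1])
  vy[n] <- (y[n] - y[n - 1]) / (tm[n] - tm[n - 1])
  out <- tibble::tibble(time = tm, speed = sqrt(vx^2 + vy^2))
  class(out) <- c("speed_series", class(out))
  out
}

# centered moving average with edge truncation (window shrinks at the ends)
boxcar_smooth <- function(v, k) {
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  n <- length(v)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Immobility mask on the LFP clock
#'
#' Resamples running speed to the LFP sample times by previous-value hold
#' (the mask is piecewise constant between tracker fixes) and marks samples
#' with speed strictly below `threshold` cm/s as immobile. LFP samples
#' before the first or after the last tracker fix are marked mobile
#' (excluded from detection and from the immobile-time normalizer).
#'
#' @param speed A `speed_series` from [compute_speed()].
#' @param lfp The [lfp_trace()] whose clock the mask should follow.
#' @param threshold Immobility threshold, cm/s. Strict `<` comparison.
#' @return Logical vector of class `immobility_mask`, one element per LFP
#'   sample, with attributes `fs` and `total_immobile_s`.
#' @export
immobility_mask <- function(speed, lfp, threshold = 2.0) {
  t_lfp <- sample_time(lfp, seq_along(lfp$samples) - 1)
  if (max(speed$time) < t_lfp[1] || min(speed$time) > t_lfp[length(t_lfp)]) {
    stop("speed series and LFP trace do not overlap in time", call. = FALSE)
  }
  # previous-value hold: index of last fix at or before each LFP sample
  idx <- findInterval(t_lfp, speed$time)
  mask <- idx >= 1 & t_lfp <= max(speed$time)
  mask[mask] <- speed$speed[idx[mask]] < threshold
  structure(mask,
            fs = lfp$fs,
            total_immobile_s = sum(mask) / lfp$fs,
            class = "immobility_mask")
}

#' Total immobile time covered by a mask, seconds
#' @param mask An [immobility_mask()].
#' @return Seconds of immobility.
#' @export
immobile_duration <- function(mask) attr(mask, "total_immobile_s")
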