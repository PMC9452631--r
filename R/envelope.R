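#' Ripple-band envelope z-score
#'
#' Band-pass filters the trace with a zero-phase 4th-order Butterworth
#' (applied forward and backward, so event timing is not shifted), takes the
#' magnitude of the discrete-time analytic signal (Hilbert envelope), and
#' z-scores it: `z = (envelope - mu) / sigma`. `mu` and `sigma` are estimated
#' over the normalization epoch — the whole session by default, or only
#' immobile samples — always excluding the first and last 0.5 s where filter
#' transients live.
#'
#' @param lfp An [lfp_trace()]; needs `fs > 2 * band[2]` and >= 1 s of data.
#' @param band Pass band in Hz, `c(low, high)`. Ripple band 150-250 Hz by
#'   default; use `c(1, 50)` for sharp waves.
#' @param norm_epoch `"whole_session"` or `"immobile_only"`.
#' @param mask [immobility_mask()], required when `norm_epoch = "immobile_only"`.
#' @param squared If `TRUE`, use the squared envelope (power) instead of the
#'   magnitude before z-scoring.
#' @param edge_exclude_s Seconds trimmed from each end for mu/sigma estimation.
#' @return An object of class `envelope_z`: list with `z`, `fs`, `t0`, `band`,
#'   `mu`, `sigma`, and provenance fields.
#' @export
#' @examples
#' lfp <- lfp_trace(rnorm(4000), fs = 2000)
#' ez <- ripple_envelope_z(lfp)
#' c(mean(ez$z[1001:3000]), sd(ez$z[1001:3000]))
ripple_envelope_z <- function(lfp, band = c(150, 250),
                              norm_epoch = c("whole_session", "immobile_only"),
                              mask = NULL, squared = FALSE, edge_exclude_s = 0.5) {
  norm_epoch <- match.arg(norm_epoch)
  if (lfp$fs <= 2 * band[2]) {
    stop(sprintf("sampling rate %g Hz cannot resolve band up to %g Hz (Nyquist)",
                 lfp$fs, band[2]), call. = FALSE)
  }
  if (lfp_duration(lfp) < 1) stop("trace shorter than 1 s", call. = FALSE)
  if (stats::sd(lfp$samples) == 0) {
    stop("degenerate signal: constant trace", call. = FALSE)
  }
  filtered <- bandpass_zero_phase(lfp$samples, lfp$fs, band)
  # the FFT analytic signal assumes circularity; reflect-pad and trim so the
  # envelope is transient-free at both ends
  n <- length(filtered)
  np <- min(n - 1, ceiling(0.5 * lfp$fs))
  padded <- c(2 * filtered[1] - filtered[(np + 1):2], filtered,
              2 * filtered[n] - filtered[(n - 1):(n - np)])
  env <- Mod(analytic_signal(padded))[(np + 1):(np + n)]
  if (squared) env <- env^2
  n <- length(env)
  edge <- min(round(edge_exclude_s * lfp$fs), (n - 2) %/% 2)
  core <- (edge + 1):(n - edge)
  if (norm_epoch == "immobile_only") {
    if (is.null(mask)) stop("`mask` required for immobile_only normalization", call. = FALSE)
    core <- core[mask[core]]
    if (length(core) < 2) stop("no immobile samples in normalization epoch", call. = FALSE)
  }
  mu <- mean(env[core])
  sigma <- stats::sd(env[core])
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate signal: envelope has zero variance", call. = FALSE)
  }
  structure(
    list(z = (env - mu) / sigma, fs = lfp$fs, t0 = lfp$t0, band = band,
         mu = mu, sigma = sigma, squared = squared,
         edge_exclude_s = edge / lfp$fs,
         region = lfp$region, electrode_id = lfp$electrode_id,
         session_id = lfp$session_id),
    class = "envelope_z"
  )
}

#' @export
print.envelope_z <- function(x, ...) {
  cat(sprintf("<envelope_z> %s/%s band %g-%g Hz: %d samples @ %g Hz (mu=%.3g, sigma=%.3g)\n",
              x$session_id, x$electrode_id, x$band[1], x$band[2],
              length(x$z), x$fs, x$mu, x$sigma))
  invisible(x)
}

# zero-phase 4th-order Butterworth band-pass (forward-backward), with
# odd-symmetric reflection padding at both ends to suppress edge transients
bandpass_zero_phase <- function(x, fs, band, order = 4) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  n <- length(x)
  np <- min(n - 1, max(3 * ceiling(fs / band[1]), ceiling(0.5 * fs)))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(np + 1):(np + n)]
}

# discrete-time analytic signal via the FFT construction:
# zero the negative frequencies, double the positive ones
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}
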