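#' Detect sharp-wave ripple events from an envelope z-series
#'
#' Events are maximal runs of samples whose envelope z-score exceeds
#' `threshold_sd` (the classical 5-sigma criterion). Runs separated by less
#' than `merge_gap_ms` are merged into one event; events shorter than
#' `min_duration_ms` are discarded. When an immobility mask is supplied, an
#' event is kept iff the sample at its envelope peak falls in an immobile
#' period (speed < 2 cm/s). Event intervals are half-open `[start, end)`;
#' duration is the supra-threshold extent of the merged run.
#'
#' Events whose peak falls inside the envelope's filter-settling margin (the
#' first/last `edge_exclude_s` of the trace, 0.5 s by default) are discarded:
#' boundary transients of the zero-phase filter and analytic signal are not
#' interpretable as physiology.
#'
#' @param envz An [ripple_envelope_z()] result.
#' @param mask Optional [immobility_mask()] of the same length; `NULL` skips
#'   the gate (all events kept).
#' @param threshold_sd Detection threshold in envelope SDs.
#' @param merge_gap_ms Runs closer than this are fused.
#' @param min_duration_ms Events shorter than this are dropped.
#' @return A tibble of class `swr_events` with columns `start`, `end`,
#'   `peak_time` (s), `duration_ms`, `amplitude` (peak z), and provenance
#'   columns; detection parameters stored as attribute `params`.
#' @export
detect_events <- function(envz, mask = NULL, threshold_sd = 5.0,
                          merge_gap_ms = 10, min_duration_ms = 5) {
  z <- envz$z
  fs <- envz$fs
  if (!is.null(mask) && length(mask) != length(z)) {
    stop("mask and envelope must have the same length", call. = FALSE)
  }
  runs <- supra_runs(z > threshold_sd,
                     merge_gap = round(merge_gap_ms / 1000 * fs),
                     min_len = ceiling(min_duration_ms / 1000 * fs))
  if (nrow(runs) == 0) {
    ev <- empty_event_table(envz)
  } else {
    peak_idx <- vapply(seq_len(nrow(runs)), function(k) {
      i <- runs$first[k]:runs$last[k]
      i[which.max(z[i])]
    }, integer(1))
    keep <- if (is.null(mask)) rep(TRUE, nrow(runs)) else as.logical(mask[peak_idx])
    edge_n <- round((envz$edge_exclude_s %||% 0) * fs)
    if (edge_n > 0) {
      keep <- keep & peak_idx > edge_n & peak_idx <= length(z) - edge_n
    }
    runs <- runs[keep, , drop = FALSE]
    peak_idx <- peak_idx[keep]
    ev <- tibble::tibble(
      start = envz$t0 + (runs$first - 1) / fs,
      end = envz$t0 + runs$last / fs,
      peak_time = envz$t0 + (peak_idx - 1) / fs,
      duration_ms = (runs$last - runs$first + 1) / fs * 1000,
      amplitude = z[peak_idx],
      region = envz$region,
      electrode_id = envz$electrode_id,
      session_id = envz$session_id
    )
  }
  attr(ev, "params") <- list(threshold_sd = threshold_sd,
                             merge_gap_ms = merge_gap_ms,
                             min_duration_ms = min_duration_ms,
                             band = envz$band, fs = fs,
                             sigma = envz$sigma, mu = envz$mu)
  class(ev) <- c("swr_events", class(ev))
  ev
}

empty_event_table <- function(envz = NULL) {
  tibble::tibble(start = double(), end = double(), peak_time = double(),
                 duration_ms = double(), amplitude = double(),
                 region = character(), electrode_id = character(),
                 session_id = character())
}

# maximal TRUE runs (1-based first/last), with gap merging and a minimum
# length applied after merging
supra_runs <- function(above, merge_gap = 0, min_len = 1) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  first <- starts[r$values]
  last <- ends[r$values]
  if (length(first) > 1 && merge_gap > 0) {
    gap <- first[-1] - last[-length(last)] - 1L
    new_event <- c(TRUE, gap >= merge_gap)
    head_pos <- which(new_event)
    tail_pos <- c(head_pos[-1] - 1L, length(last))
    first <- first[head_pos]
    last <- last[tail_pos]
  }
  len <- last - first + 1L
  keep <- len >= max(min_len, 1L)
  data.frame(first = as.integer(first[keep]), last = as.integer(last[keep]))
}

#' Per-event power spectral density metrics
#'
#' For each event, a raw (unfiltered) snippet centered on the event peak and
#' padded to at least `pad_ms` is analyzed with a Hann-windowed periodogram.
#' The mean power is the average of `10*log10(PSD)` (dB/Hz, PSD in uV^2/Hz)
#' over the frequency bins inside `band`; the frequency peak is the bin with
#' maximal PSD inside `band`.
#'
#' @param events An event table from [detect_events()].
#' @param lfp The source [lfp_trace()].
#' @param band Analysis band in Hz.
#' @param pad_ms Minimum snippet length, ms.
#' @return `events` with columns `mean_power_db` and `freq_peak` added.
#' @export
add_event_spectra <- function(events, lfp, band = c(150, 250), pad_ms = 64) {
  if (nrow(events) == 0) {
    events$mean_power_db <- double()
    events$freq_peak <- double()
    return(events)
  }
  res <- purrr::map(seq_len(nrow(events)), function(k) {
    event_spectrum(lfp, events$start[k], events$end[k], band = band, pad_ms = pad_ms)
  })
  events$mean_power_db <- purrr::map_dbl(res, "mean_power_db")
  events$freq_peak <- purrr::map_dbl(res, "freq_peak")
  events
}

#' PSD summary of one event window
#'
#' @param lfp An [lfp_trace()].
#' @param start,end Event interval, seconds.
#' @inheritParams add_event_spectra
#' @return List with `mean_power_db` (dB/Hz) and `freq_peak` (Hz).
#' @export
event_spectrum <- function(lfp, start, end, band = c(150, 250), pad_ms = 64) {
  fs <- lfp$fs
  n <- length(lfp$samples)
  need <- ceiling(pad_ms / 1000 * fs)
  i0 <- time_index(lfp, start) + 1L
  i1 <- time_index(lfp, end - 1e-12) + 1L
  if (i1 < i0 || i1 - i0 < 1) stop("event window shorter than 2 samples", call. = FALSE)
  # symmetric padding about the event to reach the spectral support window
  extra <- max(0L, need - (i1 - i0 + 1L))
  i0 <- max(1L, i0 - ceiling(extra / 2))
  i1 <- min(n, i0 + max(need, i1 - i0 + 1L) - 1L)
  i0 <- max(1L, i1 - max(need, 2L) + 1L)
  x <- lfp$samples[i0:i1]
  ps <- hann_psd(x, fs)
  in_band <- ps$freq >= band[1] & ps$freq <= band[2]
  if (!any(in_band)) stop("no frequency bins inside band", call. = FALSE)
  psd <- ps$psd[in_band]
  list(mean_power_db = mean(10 * log10(pmax(psd, .Machine$double.xmin))),
       freq_peak = ps$freq[in_band][which.max(psd)])
}

# single-taper Hann periodogram; one-sided PSD in input-units^2 per Hz
hann_psd <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xw <- (x - mean(x)) * w
  X <- stats::fft(xw)
  nf <- floor(n / 2) + 1L
  scale <- 1 / (fs * sum(w^2))
  psd <- scale * Mod(X[1:nf])^2
  # double all bins except DC and (for even n) Nyquist to make it one-sided
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  list(freq = (0:(nf - 1)) * fs / n, psd = psd * dbl)
}

#' Flag sharp-wave co-occurrence for each ripple event
#'
#' Sharp waves are detected independently with the same envelope-threshold
#' machinery on the slow band (1-50 Hz by default, 5 sigma). A ripple event is
#' flagged `has_sharp_wave` iff some sharp-wave peak lies within
#' `+/- window_ms` of the ripple peak (peak-to-peak comparison).
#'
#' @param events Ripple event table from [detect_events()].
#' @param lfp The source [lfp_trace()].
#' @param sw_band Sharp-wave band, Hz.
#' @param sw_threshold_sd Sharp-wave detection threshold (envelope SDs).
#' @param window_ms Co-occurrence window, ms.
#' @return `events` with logical column `has_sharp_wave` added and attribute
#'   `co_occurrence_pct` (percentage of events flagged).
#' @export
sharp_wave_flags <- function(events, lfp, sw_band = c(1, 50),
                             sw_threshold_sd = 5.0, window_ms = 30) {
  sw_env <- ripple_envelope_z(lfp, band = sw_band)
  sw <- detect_events(sw_env, mask = NULL, threshold_sd = sw_threshold_sd,
                      merge_gap_ms = 10, min_duration_ms = 0)
  w <- window_ms / 1000
  flag <- if (nrow(events) == 0) logical(0) else {
    vapply(events$peak_time,
           function(t) any(abs(sw$peak_time - t) <= w + 1e-12),
           logical(1))
  }
  events$has_sharp_wave <- flag
  attr(events, "co_occurrence_pct") <- if (nrow(events)) 100 * mean(flag) else NA_real_
  events
}

#' Session-level SWR summary
#'
#' SWR density is the event count divided by total immobile time (events/s),
#' the same quantity called "abundance" in parts of the literature.
#' `fraction_long` is the fraction of events with duration strictly greater
#' than `long_cutoff_ms` (long-duration ripples, the class most relevant to
#' memory consolidation).
#'
#' @param events Event table from [detect_events()].
#' @param mask [immobility_mask()] used during detection (supplies the
#'   immobile-time normalizer).
#' @param long_cutoff_ms Duration cutoff, ms (strict `>`).
#' @return One-row tibble: `n_events`, `density_hz`, `mean_duration_ms`,
#'   `fraction_long`.
#' @export
swr_summary <- function(events, mask, long_cutoff_ms = 25) {
  ti <- immobile_duration(mask)
  if (!is.finite(ti) || ti <= 0) {
    stop("zero immobile time: SWR density undefined", call. = FALSE)
  }
  tibble::tibble(
    n_events = nrow(events),
    density_hz = nrow(events) / ti,
    mean_duration_ms = if (nrow(events)) mean(events$duration_ms) else NA_real_,
    fraction_long = if (nrow(events)) mean(events$duration_ms > long_cutoff_ms) else NA_real_
  )
}
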