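#' Configuration for the synthetic dual-site session generator
#'
#' Defaults describe a realistic awake linear-track recording: 1/f background
#' LFP at 2 kHz, transient 200 Hz ripple bursts with lognormal envelope
#' widths riding on slow biphasic sharp waves, ripples confined to immobile
#' epochs, and a controllable CA1-MEC event-time coupling. Negative
#' `coupling_lag_ms` means MEC events precede CA1 events.
#'
#' @param fs LFP sampling rate, Hz.
#' @param duration Session length, s.
#' @param noise_exponent Spectral exponent of the 1/f^a background.
#' @param noise_sd Background SD, uV.
#' @param ripple_rate CA1 ripple rate, events per second of immobile time.
#' @param ripple_freq Ripple carrier frequency, Hz (inside 150-250).
#' @param ripple_width_median_ms,ripple_width_sdlog Lognormal envelope-width
#'   (FWHM) distribution, ms.
#' @param ripple_amp Burst peak amplitude in units of `noise_sd`.
#' @param sw_prob Probability that a ripple carries a co-injected sharp wave.
#' @param sw_amp Sharp-wave amplitude in units of `noise_sd`.
#' @param sw_width_ms Sharp-wave Gaussian width (SD), ms.
#' @param coupling_lag_ms Mean MEC-minus-CA1 event lag, ms (negative = MEC
#'   leads, as in healthy animals).
#' @param coupling_jitter_ms SD of the per-event lag jitter, ms.
#' @param coupled_fraction Fraction of CA1 events with a coupled MEC partner.
#' @param mobile_block_s,immobile_block_s Alternating mobility schedule, s
#'   (sessions start immobile).
#' @param mobile_speed Running speed during mobile blocks, cm/s.
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#' @return A `synth_config` list.
#' @export
synth_config <- function(fs = 2000, duration = 600,
                         noise_exponent = 1.0, noise_sd = 30,
                         ripple_rate = 0.1, ripple_freq = 200,
                         ripple_width_median_ms = 30, ripple_width_sdlog = 0.35,
                         ripple_amp = 8,
                         sw_prob = 0.95, sw_amp = 8, sw_width_ms = 15,
                         coupling_lag_ms = -8.9, coupling_jitter_ms = 5,
                         coupled_fraction = 0.8,
                         mobile_block_s = 30, immobile_block_s = 30,
                         mobile_speed = 10, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$fs > 0, cfg$duration > 0, cfg$noise_sd >= 0,
            cfg$ripple_rate >= 0, cfg$coupled_fraction >= 0,
            cfg$coupled_fraction <= 1, cfg$ripple_freq >= 150,
            cfg$ripple_freq <= 250, cfg$coupling_jitter_ms >= 0)
  class(cfg) <- "synth_config"
  cfg
}

#' Cohort presets for the generator
#'
#' `"wt"` emulates healthy coordination: most CA1 ripples have an MEC partner
#' leading by 8.9 ms on average. `"ad"` emulates the impaired phenotype: a
#' smaller coupled fraction with MEC events trailing CA1 by 23.2 ms.
#'
#' @param preset `"wt"` or `"ad"`.
#' @param ... Overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_preset <- function(preset = c("wt", "ad"), ...) {
  preset <- match.arg(preset)
  over <- list(...)
  base <- if (preset == "wt") {
    list(coupling_lag_ms = -8.9, coupling_jitter_ms = 5, coupled_fraction = 0.8)
  } else {
    list(coupling_lag_ms = 23.2, coupling_jitter_ms = 5, coupled_fraction = 0.5)
  }
  do.call(synth_config, utils::modifyList(base, over))
}

# alternating immobility schedule; sessions start immobile
mobility_schedule <- function(cfg) {
  blocks <- list()
  t <- 0
  immobile <- TRUE
  while (t < cfg$duration) {
    len <- if (immobile) cfg$immobile_block_s else cfg$mobile_block_s
    blocks[[length(blocks) + 1]] <- tibble::tibble(
      start = t, end = min(t + len, cfg$duration), immobile = immobile)
    t <- t + len
    immobile <- !immobile
  }
  dplyr::bind_rows(blocks)
}

# seeded 1/f^a Gaussian background via spectral shaping
pink_noise <- function(n, fs, exponent, sd_target) {
  if (sd_target == 0) return(numeric(n))
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- pmax(f, 1)^(-exponent / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  mag <- amp * sqrt(-2 * log(stats::runif(nf)))
  half <- mag * exp(1i * phase)
  spec <- complex(n)
  spec[2:(nf + 1)] <- half
  if (n %% 2 == 0) {
    spec[nf + 1] <- Re(spec[nf + 1])
    if (nf >= 2) spec[n:(n - nf + 2)] <- Conj(half[1:(nf - 1)])
  } else {
    spec[n:(n - nf + 1)] <- Conj(half)
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * sd_target / stats::sd(x)
}

# Poisson event times confined to immobile blocks, with an edge margin and a
# refractory spacing so injected events never overlap
poisson_immobile_times <- function(schedule, rate, margin = 0.1, refractory = 0.25) {
  times <- c()
  for (k in seq_len(nrow(schedule))) {
    if (!schedule$immobile[k]) next
    lo <- schedule$start[k] + margin
    hi <- schedule$end[k] - margin
    if (hi <= lo) next
    n <- stats::rpois(1, rate * (hi - lo))
    if (n > 0) times <- c(times, stats::runif(n, lo, hi))
  }
  times <- sort(times)
  if (length(times) > 1) {
    keep <- c(TRUE, diff(times) >= refractory)
    while (!all(keep)) {
      times <- times[keep]
      keep <- c(TRUE, diff(times) >= refractory)
    }
  }
  times
}

# add a Gaussian-envelope sinusoid (the ripple burst); width_ms is the
# envelope FWHM
add_ripple <- function(x, fs, t_center, width_ms, amp_uv, freq) {
  s <- width_ms / 1000 / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * s * fs)
  ic <- round(t_center * fs)
  idx <- max(0, ic - half):min(length(x) - 1, ic + half)
  tt <- idx / fs - t_center
  x[idx + 1] <- x[idx + 1] +
    amp_uv * exp(-tt^2 / (2 * s^2)) * cos(2 * pi * freq * tt)
  x
}

# biphasic slow transient (Gaussian-derivative), band-limited to ~1-50 Hz
add_sharp_wave <- function(x, fs, t_center, width_ms, amp_uv) {
  s <- width_ms / 1000
  half <- ceiling(5 * s * fs)
  ic <- round(t_center * fs)
  idx <- max(0, ic - half):min(length(x) - 1, ic + half)
  tt <- idx / fs - t_center
  shape <- -tt / s * exp(0.5 - tt^2 / (2 * s^2))  # unit peak magnitude
  x[idx + 1] <- x[idx + 1] + amp_uv * shape
  x
}

#' Generate a paired CA1/MEC synthetic session
#'
#' Produces two LFP traces with injected ripple bursts and sharp waves on a
#' 1/f background, a 50 Hz position track realizing the mobility schedule,
#' and the ground-truth event catalog. CA1 events follow a Poisson process
#' thinned to immobile epochs; a configured fraction of MEC events is placed
#' at the CA1 time plus a jittered lag (negative mean = MEC leads), the rest
#' independently. The same seed reproduces the session bit-identically.
#'
#' @param cfg A [synth_config()].
#' @param lfp If `FALSE`, skip waveform synthesis and return only the truth
#'   catalog, schedule and position track (fast path for event-level studies).
#' @return List with elements `ca1`, `mec` ([lfp_trace()]s, when `lfp`),
#'   `position` ([position_track()]), `truth` (tibble: `region`, `peak_time`,
#'   `width_ms`, `amplitude`, `has_sharp_wave`, `partner`), `schedule`.
#' @export
generate_session <- function(cfg, lfp = TRUE) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  schedule <- mobility_schedule(cfg)
  immobile_total <- sum((schedule$end - schedule$start)[schedule$immobile])
  if (cfg$ripple_rate * immobile_total < 1) {
    warning("expected fewer than one ripple in this configuration", call. = FALSE)
  }

  ca1_times <- poisson_immobile_times(schedule, cfg$ripple_rate)
  n_ca1 <- length(ca1_times)
  coupled <- if (n_ca1) stats::runif(n_ca1) < cfg$coupled_fraction else logical(0)
  mec_coupled <- ca1_times[coupled] + cfg$coupling_lag_ms / 1000 +
    stats::rnorm(sum(coupled), 0, cfg$coupling_jitter_ms / 1000)
  mec_indep <- poisson_immobile_times(schedule,
                                      cfg$ripple_rate * (1 - cfg$coupled_fraction))
  mec_partner <- c(which(coupled), rep(NA_integer_, length(mec_indep)))
  mec_times <- c(mec_coupled, mec_indep)
  ord <- order(mec_times)
  mec_times <- mec_times[ord]
  mec_partner <- mec_partner[ord]
  in_range <- mec_times > 0.1 & mec_times < cfg$duration - 0.1
  mec_times <- mec_times[in_range]
  mec_partner <- mec_partner[in_range]
  # enforce non-overlap on the MEC side too
  if (length(mec_times) > 1) {
    keep <- c(TRUE, diff(mec_times) >= 0.25)
    while (!all(keep)) {
      mec_times <- mec_times[keep]
      mec_partner <- mec_partner[keep]
      keep <- c(TRUE, diff(mec_times) >= 0.25)
    }
  }

  truth_region <- function(times, partner, region) {
    n <- length(times)
    tibble::tibble(
      region = region,
      peak_time = times,
      width_ms = stats::rlnorm(n, log(cfg$ripple_width_median_ms),
                               cfg$ripple_width_sdlog),
      amplitude = cfg$ripple_amp * stats::runif(n, 0.9, 1.1),
      has_sharp_wave = stats::runif(n) < cfg$sw_prob,
      partner = partner
    )
  }
  truth <- dplyr::bind_rows(
    truth_region(ca1_times, rep(NA_integer_, n_ca1), "CA1"),
    truth_region(mec_times, mec_partner, "MEC")
  )

  # 50 Hz position track: stationary in immobile blocks, constant-speed
  # shuttling along a 1 m track otherwise
  tr_t <- seq(0, cfg$duration - 1 / 50, by = 1 / 50)
  x <- numeric(length(tr_t))
  pos <- 0
  dir <- 1
  dt <- 1 / 50
  imm_flags <- schedule$immobile[pmax(findInterval(tr_t, schedule$start), 1)]
  for (i in seq_along(tr_t)) {
    if (i > 1 && !imm_flags[i]) {
      pos <- pos + dir * cfg$mobile_speed * dt
      if (pos > 100) { pos <- 200 - pos; dir <- -1 }
      if (pos < 0) { pos <- -pos; dir <- 1 }
    }
    x[i] <- pos
  }
  position <- position_track(tr_t, x, rep(0, length(tr_t)), fs_nominal = 50)

  out <- list(position = position, truth = truth, schedule = schedule,
              config = cfg)
  if (lfp) {
    n <- round(cfg$duration * cfg$fs)
    synth_trace <- function(region) {
      sig <- pink_noise(n, cfg$fs, cfg$noise_exponent, cfg$noise_sd)
      ev <- truth[truth$region == region, ]
      for (k in seq_len(nrow(ev))) {
        sig <- add_ripple(sig, cfg$fs, ev$peak_time[k], ev$width_ms[k],
                          ev$amplitude[k] * cfg$noise_sd, cfg$ripple_freq)
        if (ev$has_sharp_wave[k]) {
          sig <- add_sharp_wave(sig, cfg$fs, ev$peak_time[k], cfg$sw_width_ms,
                                cfg$sw_amp * cfg$noise_sd)
        }
      }
      lfp_trace(sig, fs = cfg$fs, t0 = 0, region = region,
                electrode_id = paste0(tolower(region), "_t1"),
                session_id = sprintf("synth_seed%d", cfg$seed))
    }
    out$ca1 <- synth_trace("CA1")
    out$mec <- synth_trace("MEC")
  }
  out
}

#' Score detections against a ground-truth catalog
#'
#' Greedy one-to-one matching: candidate (truth, detection) pairs within
#' `tol_ms` are assigned in order of increasing |timing error|, each event
#' used at most once. Precision is `NA` when there are no detections.
#'
#' @param truth Truth tibble for one region (from [generate_session()]).
#' @param detected Event table from [detect_events()].
#' @param tol_ms Matching tolerance on peak times, ms.
#' @return List: `recall`, `precision`, `n_matched`, `lag_error_ms` (signed
#'   detected-minus-truth timing errors of the matches).
#' @export
score_detection <- function(truth, detected, tol_ms = 20) {
  tt <- truth$peak_time
  dt <- detected$peak_time
  if (length(dt) == 0) {
    return(list(recall = 0, precision = NA_real_, n_matched = 0L,
                lag_error_ms = numeric(0)))
  }
  pairs <- expand.grid(i = seq_along(tt), j = seq_along(dt))
  pairs$err <- (dt[pairs$j] - tt[pairs$i]) * 1000
  pairs <- pairs[abs(pairs$err) <= tol_ms, ]
  pairs <- pairs[order(abs(pairs$err)), ]
  used_t <- logical(length(tt))
  used_d <- logical(length(dt))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_t[i] && !used_d[j]) {
      used_t[i] <- TRUE
      used_d[j] <- TRUE
      keep[k] <- TRUE
    }
  }
  matches <- tibble::tibble(truth_idx = pairs$i[keep], det_idx = pairs$j[keep],
                            err_ms = pairs$err[keep])
  list(recall = sum(used_t) / length(tt),
       precision = sum(used_d) / length(dt),
       n_matched = sum(used_t),
       lag_error_ms = matches$err_ms,
       matches = matches)
}
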