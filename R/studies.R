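#' Validation studies on the synthetic generator
#'
#' These functions run the package's standard self-validation experiments:
#' each one generates seeded synthetic sessions, pushes them through the
#' analysis pipeline, and measures how well a known ground-truth quantity is
#' recovered. They back the test suite and the reproduction script, and are
#' exported so users can rerun any study at other seeds or sizes.
#'
#' @param seed Integer seed.
#' @param duration Session length, s.
#' @param ripple_rate Events per immobile second.
#' @param criterion Order-selection criterion, `"AIC"` or `"BIC"`.
#' @param max_order Largest candidate VAR order.
#' @param n Series length for white-noise calibration runs.
#' @param order VAR order for white-noise calibration runs.
#' @name validation-studies
NULL

#' @describeIn validation-studies Detector fidelity: recall/precision of
#'   5-sigma detection against the ground-truth catalog on a strong-burst
#'   session, plus the SWR density and its truth-derived counterpart.
#' @export
study_detection <- function(seed = 1, duration = 1800, ripple_rate = 0.1) {
  cfg <- synth_config(duration = duration, ripple_rate = ripple_rate, seed = seed)
  ses <- generate_session(cfg)
  mask <- immobility_mask(compute_speed(ses$position), ses$ca1)
  ev <- detect_events(ripple_envelope_z(ses$ca1), mask)
  truth <- ses$truth[ses$truth$region == "CA1", ]
  sc <- score_detection(truth, ev)
  smry <- swr_summary(ev, mask)
  list(recall = sc$recall, precision = sc$precision,
       n_truth = nrow(truth), n_detected = nrow(ev),
       density_hz = smry$density_hz,
       matched_density_hz = sc$n_matched / immobile_duration(mask),
       events = ev, truth = truth, mask = mask, score = sc)
}

#' @describeIn validation-studies Null calibration: false-detection rate
#'   (events per immobile second) on a ripple-free session.
#' @export
study_null_rate <- function(seed = 1, duration = 600) {
  cfg <- synth_config(duration = duration, ripple_rate = 0, seed = seed)
  ses <- suppressWarnings(generate_session(cfg))
  mask <- immobility_mask(compute_speed(ses$position), ses$ca1)
  ev <- detect_events(ripple_envelope_z(ses$ca1), mask)
  list(false_rate_hz = nrow(ev) / immobile_duration(mask), n_false = nrow(ev))
}

#' @describeIn validation-studies Duration recovery: Spearman correlation
#'   between estimated event durations and the injected envelope widths.
#' @export
study_duration_recovery <- function(seed = 1, duration = 1800,
                                    ripple_rate = 0.25) {
  st <- study_detection(seed, duration, ripple_rate)
  m <- st$score$matches
  est <- st$events$duration_ms[m$det_idx]
  inj <- st$truth$width_ms[m$truth_idx]
  list(spearman_rho = stats::cor(est, inj, method = "spearman"),
       n_events = length(est))
}

#' @describeIn validation-studies Lag recovery: fraction of seeded runs in
#'   which the cross-correlogram peak lag lands within one bin of the
#'   injected coupling lag, per cohort preset. Event-level (no waveforms).
#' @param preset Generator preset, `"wt"` or `"ad"`.
#' @param n_runs Number of seeded runs.
#' @export
study_lag_recovery <- function(preset = "wt", n_runs = 100, seed = 1,
                               duration = 3600, ripple_rate = 0.15) {
  true_lag <- if (preset == "wt") -8.9 else 23.2
  lags <- vapply(seq_len(n_runs), function(k) {
    cfg <- synth_preset(preset, duration = duration, ripple_rate = ripple_rate,
                        seed = seed * 10000 + k)
    ses <- generate_session(cfg, lfp = FALSE)
    ca1 <- ses$truth[ses$truth$region == "CA1", ]
    mec <- ses$truth[ses$truth$region == "MEC", ]
    ti <- sum((ses$schedule$end - ses$schedule$start)[ses$schedule$immobile])
    xc <- cross_correlogram(event_table_from_truth(ca1),
                            event_table_from_truth(mec, "MEC"), mask = ti)
    peak_lag(xc)
  }, numeric(1))
  list(hit_rate = mean(abs(lags - true_lag) <= 5, na.rm = TRUE),
       mean_lag_ms = mean(lags, na.rm = TRUE), lags_ms = lags,
       true_lag_ms = true_lag)
}

event_table_from_truth <- function(truth, region = "CA1") {
  tibble::tibble(start = truth$peak_time, end = truth$peak_time + 1e-3,
                 peak_time = truth$peak_time,
                 duration_ms = truth$width_ms, amplitude = truth$amplitude,
                 region = region, electrode_id = "truth", session_id = "truth")
}

#' @describeIn validation-studies Directed-influence study: Granger
#'   causality over simulated electrode pairs with MEC-leads coupling,
#'   aggregated to per-direction mean significance, with the rank-sum
#'   comparison between directions and the median F-ratio asymmetry.
#' @param n_pairs Number of simulated electrode pairs.
#' @export
study_gc_directionality <- function(n_pairs = 20, seed = 1, duration = 240,
                                    ripple_rate = 0.1, criterion = "AIC",
                                    max_order = 50) {
  rows <- purrr::map(seq_len(n_pairs), function(k) {
    cfg <- synth_preset("wt", duration = duration, ripple_rate = ripple_rate,
                        seed = seed * 10000 + k)
    ses <- generate_session(cfg)
    sm <- sparsify(ripple_envelope_z(ses$mec))
    sc <- sparsify(ripple_envelope_z(ses$ca1))
    if (sm$empty || sc$empty) return(NULL)
    res <- gc_pair(sm, sc, criterion = criterion, max_order = max_order)
    res$session_id <- sprintf("s%03d", k)
    res$pair_id <- sprintf("pair%03d", k)
    res
  })
  out <- dplyr::bind_rows(rows)
  agg <- aggregate_gc(out)
  dm <- attr(agg, "direction_means")
  fwd <- agg$mean_significance[agg$direction == "MEC->CA1"]
  rev_ <- agg$mean_significance[agg$direction == "CA1->MEC"]
  p_dir <- tryCatch(rank_sum(fwd, rev_)$p_value, error = function(e) NA_real_)
  f_ratio <- stats::median(out$f_stat[out$direction == "MEC->CA1"]) /
    stats::median(out$f_stat[out$direction == "CA1->MEC"])
  list(mean_sig_fwd = dm$group_mean[dm$direction == "MEC->CA1"],
       mean_sig_rev = dm$group_mean[dm$direction == "CA1->MEC"],
       ranksum_p = p_dir, f_ratio = f_ratio, outcomes = out, per_pair = agg)
}

#' @describeIn validation-studies Type-I calibration of the GC F-test on
#'   independent white-noise pairs: raw per-direction rejection rate at
#'   alpha = 0.05.
#' @export
study_gc_null <- function(n_runs = 1000, seed = 1, n = 1200, order = 5) {
  rej <- vapply(seq_len(n_runs), function(k) {
    set.seed(seed * 100000 + k)
    r <- gc_test(stats::rnorm(n), stats::rnorm(n), order = order)
    c(r$p_raw[1] < 0.05, r$p_raw[2] < 0.05)
  }, logical(2))
  list(rejection_rate = mean(rej), n_tests = length(rej))
}

#' @describeIn validation-studies Sharp-wave co-occurrence recovery: with a
#'   configured co-injection probability, the measured co-occurrence
#'   percentage among detected ripples.
#' @param sw_prob Co-injection probability.
#' @export
study_sw_cooccurrence <- function(seed = 1, duration = 3600,
                                  ripple_rate = 0.25, sw_prob = 0.9) {
  cfg <- synth_config(duration = duration, ripple_rate = ripple_rate,
                      sw_prob = sw_prob, seed = seed)
  ses <- generate_session(cfg)
  mask <- immobility_mask(compute_speed(ses$position), ses$ca1)
  ev <- detect_events(ripple_envelope_z(ses$ca1), mask)
  ev <- sharp_wave_flags(ev, ses$ca1)
  list(co_occurrence_pct = attr(ev, "co_occurrence_pct"), n_events = nrow(ev))
}
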