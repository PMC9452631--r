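test_that("generation is bit-identical under a fixed seed", {
  cfg <- synth_config(duration = 30, seed = 99)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$ca1$samples, b$ca1$samples)
  expect_identical(a$mec$samples, b$mec$samples)
  expect_identical(a$truth, b$truth)
  expect_identical(a$position$x, b$position$x)
})

test_that("injected burst energy is confined to the ripple band", {
  cfg <- synth_config(duration = 60, noise_sd = 1e-6, ripple_rate = 0.2,
                      sw_prob = 0, ripple_amp = 8e6, seed = 3)
  ses <- generate_session(cfg)
  x <- ses$ca1$samples - mean(ses$ca1$samples)
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  freq <- (0:(n - 1)) * 2000 / n
  half <- freq > 0 & freq <= 1000
  in_band <- half & freq >= 150 & freq <= 250
  expect_gte(sum(pw[in_band]) / sum(pw[half]), 0.90)
})

test_that("realized event rate matches the configured Poisson rate", {
  counts <- vapply(1:12, function(seed) {
    ses <- generate_session(synth_config(duration = 600, ripple_rate = 0.2,
                                         seed = seed), lfp = FALSE)
    sum(ses$truth$region == "CA1")
  }, numeric(1))
  ti <- 300  # half the session is immobile
  lambda <- 0.2 * (ti - 0.2 * 10)  # edge margins trim 0.2 s per 30 s block
  expect_lt(abs(mean(counts) - lambda) / lambda, 0.25)
})

test_that("truth events sit inside immobile epochs of the session", {
  ses <- generate_session(synth_config(duration = 300, ripple_rate = 0.3,
                                       seed = 5), lfp = FALSE)
  sched <- ses$schedule
  ca1 <- ses$truth$peak_time[ses$truth$region == "CA1"]
  in_immobile <- vapply(ca1, function(t) {
    any(sched$immobile & sched$start <= t & t < sched$end)
  }, logical(1))
  expect_true(all(in_immobile))
  expect_true(all(ses$truth$peak_time > 0 & ses$truth$peak_time < 300))
  # no two same-region events closer than the refractory spacing
  expect_true(all(diff(sort(ca1)) >= 0.25))
})

test_that("coupled MEC events realize the configured lag distribution", {
  ses <- generate_session(synth_preset("wt", duration = 3000, ripple_rate = 0.3,
                                       seed = 6), lfp = FALSE)
  tr <- ses$truth
  mec <- tr[tr$region == "MEC" & !is.na(tr$partner), ]
  ca1 <- tr[tr$region == "CA1", ]
  lags_ms <- (mec$peak_time - ca1$peak_time[mec$partner]) * 1000
  expect_gt(length(lags_ms), 100)
  expect_equal(mean(lags_ms), -8.9, tolerance = 1.5)
  expect_equal(sd(lags_ms), 5, tolerance = 1.5)
})

test_that("detector scoring handles perfect, empty, and noisy detections", {
  truth <- tibble::tibble(peak_time = seq(10, 109, by = 1))
  perfect <- events_from_peaks(truth$peak_time)
  s <- score_detection(truth, perfect)
  expect_equal(s$recall, 1)
  expect_equal(s$precision, 1)

  none <- events_from_peaks(numeric(0))
  s0 <- score_detection(truth, none)
  expect_equal(s0$recall, 0)
  expect_true(is.na(s0$precision))

  spurious <- events_from_peaks(c(truth$peak_time, seq(200, 209)))
  s2 <- score_detection(truth, spurious)
  expect_equal(s2$precision, 100 / 110, tolerance = 1e-9)
  expect_equal(s2$recall, 1)
})

test_that("matching is one-to-one and respects the tolerance", {
  truth <- tibble::tibble(peak_time = c(10, 10.05))
  det <- events_from_peaks(c(10.004, 10.046, 30))
  s <- score_detection(truth, det, tol_ms = 20)
  expect_equal(s$n_matched, 2)
  expect_equal(s$recall, 1)
  expect_equal(s$precision, 2 / 3)
  far <- events_from_peaks(10.5)
  expect_equal(score_detection(truth, far)$n_matched, 0)
})

test_that("a ripple-free configuration warns and yields silent traces", {
  expect_warning(ses <- generate_session(synth_config(duration = 60,
                                                      ripple_rate = 0,
                                                      seed = 7)),
                 "fewer than one")
  expect_equal(nrow(ses$truth), 0)
  ez <- ripple_envelope_z(ses$ca1)
  ev <- detect_events(ez, mask = NULL)
  expect_lte(nrow(ev), 1)  # at most a stray noise excursion
})
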