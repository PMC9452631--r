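# shared fixtures, all generated in code

# trace with a flat-noise floor and optional injected 200 Hz bursts
burst_trace <- function(n_s = 10, fs = 2000, bursts = NULL, noise_sd = 1,
                        seed = 1, freq = 200) {
  set.seed(seed)
  x <- rnorm(n_s * fs, sd = noise_sd)
  if (!is.null(bursts)) {
    for (k in seq_len(nrow(bursts))) {
      tc <- bursts$t[k]
      s <- bursts$width_ms[k] / 1000 / (2 * sqrt(2 * log(2)))
      idx <- which(abs(seq_along(x) / fs - tc) < 4 * s)
      tt <- idx / fs - tc
      x[idx] <- x[idx] + bursts$amp[k] * exp(-tt^2 / (2 * s^2)) * cos(2 * pi * freq * tt)
    }
  }
  lfp_trace(x, fs = fs)
}

# envelope_z object wrapping an arbitrary z series (unit-test shim)
fake_envz <- function(z, fs = 2000, t0 = 0, region = "CA1") {
  structure(list(z = z, fs = fs, t0 = t0, band = c(150, 250), mu = 0,
                 sigma = 1, squared = FALSE, region = region,
                 electrode_id = "e1", session_id = "s1"),
            class = "envelope_z")
}

# mask of given length, all immobile unless stated
fake_mask <- function(n, fs = 2000, immobile = rep(TRUE, n)) {
  structure(immobile, fs = fs, total_immobile_s = sum(immobile) / fs,
            class = "immobility_mask")
}

# event table from peak times only (coordination-level tests)
events_from_peaks <- function(peaks, region = "CA1") {
  tibble::tibble(start = peaks - 0.01, end = peaks + 0.01, peak_time = peaks,
                 duration_ms = 20, amplitude = 6, region = region,
                 electrode_id = "e1", session_id = "s1")
}

# brute-force run detector: explicit scan + merge loop, used as the oracle
# for detect_events
oracle_detect <- function(z, fs, threshold, merge_gap_ms, min_duration_ms) {
  above <- z > threshold
  runs <- list()
  i <- 1
  n <- length(z)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) == 0) return(data.frame(first = integer(), last = integer()))
  merge_gap <- round(merge_gap_ms / 1000 * fs)
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    prev <- merged[[length(merged)]]
    if (merge_gap > 0 && (r[1] - prev[2] - 1) < merge_gap) {
      merged[[length(merged)]] <- c(prev[1], r[2])
    } else {
      merged[[length(merged)]] <- prev
      merged[[length(merged) + 1]] <- r
    }
  }
  out <- do.call(rbind, merged)
  keep <- (out[, 2] - out[, 1] + 1) >= max(ceiling(min_duration_ms / 1000 * fs), 1)
  data.frame(first = out[keep, 1], last = out[keep, 2])
}

# full enumeration of the rank-sum null: all C(n, n_a) assignments of ranks
ranksum_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  sums <- colSums(matrix(r[combos], nrow = na))
  mean(abs(sums - na * (length(pooled) + 1) / 2) >=
         abs(obs - na * (length(pooled) + 1) / 2) - 1e-9)
}
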