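#' Construct an LFP trace
#'
#' A light container for one electrode's continuously sampled local field
#' potential. Voltages are in microvolts, time in seconds from session start.
#' Sample `i` (0-based) sits at time `t0 + i / fs`.
#'
#' @param samples Numeric vector of voltages (uV). Must be finite, length >= 2.
#' @param fs Sampling rate in Hz (> 0). Nominally 2000 Hz for tetrode LFP but
#'   always carried explicitly.
#' @param t0 Session-time of the first sample, seconds.
#' @param region Recording region, `"CA1"` or `"MEC"`.
#' @param electrode_id,session_id Provenance strings; `electrode_id` must be
#'   nonempty.
#' @return An object of class `lfp_trace`.
#' @export
#' @examples
#' lfp <- lfp_trace(sin(2 * pi * 200 * seq(0, 1, by = 1 / 2000)), fs = 2000)
#' lfp_duration(lfp)
lfp_trace <- function(samples, fs, t0 = 0, region = c("CA1", "MEC"),
                      electrode_id = "e1", session_id = "s1") {
  region <- match.arg(region)
  samples <- as.double(samples)
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (length(samples) < 2) {
    stop("an LFP trace needs at least 2 samples", call. = FALSE)
  }
  bad <- which(!is.finite(samples))
  if (length(bad) > 0) {
    stop(sprintf("non-finite sample at index %d (first of %d)", bad[1], length(bad)),
         call. = FALSE)
  }
  if (!nzchar(electrode_id)) stop("`electrode_id` must be nonempty", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, t0 = as.double(t0), region = region,
         electrode_id = electrode_id, session_id = session_id),
    class = "lfp_trace"
  )
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %s/%s region=%s: %d samples @ %g Hz (%.2f s from t0=%g)\n",
              x$session_id, x$electrode_id, x$region, length(x$samples), x$fs,
              lfp_duration(x), x$t0))
  invisible(x)
}

#' Trace duration in seconds
#' @param lfp An [lfp_trace()].
#' @return Duration (s) = n samples / fs.
#' @export
lfp_duration <- function(lfp) length(lfp$samples) / lfp$fs

#' Convert between sample index and session time
#'
#' Indices are 0-based; `sample_time(lfp, i)` is exactly `t0 + i / fs`.
#' `time_index` returns the 0-based index of the sample covering time `t`
#' (floor), so the two are inverse for integer indices.
#'
#' @param lfp An [lfp_trace()].
#' @param i 0-based sample index (vectorized).
#' @param t Session time in seconds (vectorized).
#' @return Numeric times, or integer indices.
#' @export
sample_time <- function(lfp, i) lfp$t0 + i / lfp$fs

#' @rdname sample_time
#' @export
time_index <- function(lfp, t) as.integer(floor((t - lfp$t0) * lfp$fs + 1e-9))

#' Read an LFP trace from CSV
#'
#' Accepts either a single-column file of voltages (with `fs` declared by the
#' caller) or a two-column `time,value` file. An optional linear `scale`
#' (uV per stored unit) converts raw acquisition counts to microvolts.
#'
#' @param path CSV file path.
#' @param fs Sampling rate (Hz); required for value-only files, used as a
#'   consistency check otherwise.
#' @param scale Multiplicative conversion to uV applied to stored values.
#' @param t0,region,electrode_id,session_id Passed to [lfp_trace()].
#' @return An [lfp_trace()].
#' @export
read_lfp <- function(path, fs = NULL, scale = 1, t0 = 0, region = "CA1",
                     electrode_id = "e1", session_id = "s1") {
  if (!file.exists(path)) stop(sprintf("LFP file not found: %s", path), call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double()))
  if (ncol(df) == 1) {
    if (is.null(fs)) stop("value-only LFP file: `fs` must be declared", call. = FALSE)
    values <- df[[1]]
  } else {
    tm <- df[[intersect(c("time", "t"), names(df))[1]]]
    values <- df[["value"]]
    if (is.null(tm) || is.null(values)) {
      stop("multi-column LFP file needs columns `time` and `value`", call. = FALSE)
    }
    dt <- stats::median(diff(tm))
    if (is.null(fs)) fs <- 1 / dt
    t0 <- tm[1]
  }
  bad <- which(!is.finite(values))
  if (length(bad) > 0) {
    stop(sprintf("missing/NaN LFP sample at row %d of %s", bad[1], path), call. = FALSE)
  }
  lfp_trace(values * scale, fs = fs, t0 = t0, region = region,
            electrode_id = electrode_id, session_id = session_id)
}

#' Write an LFP trace to CSV (value-only)
#' @param lfp An [lfp_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lfp <- function(lfp, path) {
  readr::write_csv(tibble::tibble(value = lfp$samples), path)
  invisible(path)
}
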