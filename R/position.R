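#' Read a head-position track from CSV
#'
#' Overhead tracking (nominally 50 Hz) records either one or two head-stage
#' LEDs. Two-LED files (`time,x1,y1,x2,y2`) are reduced to a single head
#' position at the midpoint of the LEDs; rows where either LED is missing are
#' dropped with a warning. Single-LED files (`time,x,y`) pass through.
#' Positions are in cm, time in seconds.
#'
#' @param path CSV file path.
#' @param fs_nominal Nominal tracker rate (Hz), stored as an attribute.
#' @return A tibble of class `position_track` with columns `time`, `x`, `y`.
#' @export
read_position <- function(path, fs_nominal = 50) {
  if (!file.exists(path)) stop(sprintf("position file not found: %s", path), call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double()))
  two_led <- all(c("x1", "y1", "x2", "y2") %in% names(df))
  if (two_led) {
    keep <- stats::complete.cases(df[, c("x1", "y1", "x2", "y2")])
    if (any(!keep)) {
      warning(sprintf("dropped %d/%d rows with a missing LED", sum(!keep), nrow(df)),
              call. = FALSE)
    }
    df <- df[keep, ]
    out <- tibble::tibble(time = df$time,
                          x = (df$x1 + df$x2) / 2,
                          y = (df$y1 + df$y2) / 2)
  } else if (all(c("x", "y") %in% names(df))) {
    keep <- stats::complete.cases(df[, c("x", "y")])
    if (any(!keep)) {
      warning(sprintf("dropped %d/%d rows with missing position", sum(!keep), nrow(df)),
              call. = FALSE)
    }
    out <- tibble::as_tibble(df[keep, c("time", "x", "y")])
  } else {
    stop("position file needs columns time,x,y or time,x1,y1,x2,y2", call. = FALSE)
  }
  position_track(out$time, out$x, out$y, fs_nominal = fs_nominal)
}

#' Construct a position track
#'
#' @param time Strictly increasing times (s).
#' @param x,y Coordinates (cm), same length as `time`.
#' @param fs_nominal Nominal tracker rate (Hz).
#' @return A tibble of class `position_track`.
#' @export
position_track <- function(time, x, y, fs_nominal = 50) {
  if (length(time) < 2) stop("position track needs at least 2 valid rows", call. = FALSE)
  if (length(x) != length(time) || length(y) != length(time)) {
    stop("time, x, y must have equal lengths", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("position timestamps must be strictly increasing", call. = FALSE)
  }
  if (fs_nominal <= 0) stop("`fs_nominal` must be positive", call. = FALSE)
  out <- tibble::tibble(time = as.double(time), x = as.double(x), y = as.double(y))
  attr(out, "fs_nominal") <- fs_nominal
  class(out) <- c("position_track", class(out))
  out
}
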