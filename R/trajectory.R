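#' Uniformly sampled screen trajectory
#'
#' The shared representation for both the pursuit target and the gaze: an
#' ordered sequence of (x, y) screen positions on a uniform clock. Coordinates
#' follow the usual display convention (origin at the top-left corner, x
#' rightward, y downward, 0-based pixel indices); all trajectory measures are
#' orientation-agnostic, so the convention only matters for interpreting
#' positions. Positions are stored real-valued; measures that live on the
#' integer pixel lattice (colocality) snap them when needed.
#'
#' @param x,y Numeric vectors of equal length: positions in pixels.
#' @param rate_hz Sampling rate in Hz (default 60, the analysis clock).
#'
#' @return An object of class `spem_trajectory`: a list with `x`, `y`,
#'   `rate_hz` and `n` (sample count).
#' @export
#' @examples
#' tr <- trajectory(x = 0:59, y = rep(0, 60))
#' n_samples(tr)
trajectory <- function(x, y, rate_hz = 60) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("trajectory positions must not contain NA", call. = FALSE)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 rate_hz = rate_hz, n = length(x)),
            class = "spem_trajectory")
}

#' @rdname trajectory
#' @param traj A `spem_trajectory`.
#' @export
n_samples <- function(traj) {
  stopifnot(inherits(traj, "spem_trajectory"))
  traj$n
}

#' @export
print.spem_trajectory <- function(x, ...) {
  cat(sprintf("<spem_trajectory> %d samples at %g Hz (%.2f s)\n",
              x$n, x$rate_hz, x$n / x$rate_hz))
  invisible(x)
}

#' @export
as.data.frame.spem_trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(t_s = (seq_len(x$n) - 1) / x$rate_hz, x_px = x$x, y_px = x$y)
}

#' Raw gaze recording with irregular timestamps
#'
#' Consumer eye trackers deliver samples on an irregular clock (the reference
#' device has a nominal 30--60 Hz rate but an effective rate near 20 Hz).
#' `gaze_recording()` holds the raw timestamped samples before resampling;
#' timestamps must be strictly increasing and at least two samples are needed
#' for interpolation. Samples outside the screen rectangle are kept: the
#' trajectory measures tolerate them, and clipping is the caller's choice.
#'
#' @param t_s Numeric vector of timestamps in seconds, strictly increasing.
#' @param x_px,y_px Gaze position in pixels at each timestamp.
#' @param source_id Opaque subject/recording label.
#'
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(t_s, x_px, y_px, source_id = NA_character_) {
  if (length(t_s) != length(x_px) || length(t_s) != length(y_px))
    stop("'t_s', 'x_px' and 'y_px' must have equal length", call. = FALSE)
  if (length(t_s) < 2L)
    stop("a gaze recording needs at least 2 samples", call. = FALSE)
  bad <- which(diff(t_s) <= 0)
  if (length(bad) > 0L)
    stop(sprintf("timestamps must be strictly increasing; first violation at row %d (t = %g followed by t = %g)",
                 bad[1] + 1L, t_s[bad[1]], t_s[bad[1] + 1L]), call. = FALSE)
  structure(list(t_s = as.numeric(t_s), x_px = as.numeric(x_px),
                 y_px = as.numeric(y_px), source_id = source_id),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  span <- diff(range(x$t_s))
  cat(sprintf("<gaze_recording> '%s': %d samples over %.2f s (empirical rate %.1f Hz)\n",
              x$source_id, length(x$t_s), span, (length(x$t_s) - 1) / span))
  invisible(x)
}

#' Empirical sampling rate of a recording
#'
#' The loader makes no assumption about the device rate; downstream code that
#' needs a rate measures it from the timestamps.
#'
#' @param rec A [gaze_recording()].
#' @return Samples per second over the recorded span.
#' @export
empirical_rate <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  (length(rec$t_s) - 1) / diff(range(rec$t_s))
}

#' Resample an irregular recording to a uniform clock
#'
#' Strictly linear interpolation onto `round(rate_hz * duration_s)` uniformly
#' spaced samples, with the time origin at the first raw sample. No smoothing
#' is applied; an output sample that coincides with a raw timestamp reproduces
#' that raw sample exactly, and an already-uniform input at the target rate is
#' returned unchanged.
#'
#' @param rec A [gaze_recording()].
#' @param rate_hz Output rate in Hz (default 60).
#' @param duration_s Length of the output window in seconds; `round(rate_hz *
#'   duration_s)` samples are produced, so a 1 s window at 60 Hz gives samples
#'   at 0, 1/60, ..., 59/60 s. Defaults to the recorded span plus one output
#'   step, which makes resampling an already-uniform recording at its own rate
#'   the identity. The recording must cover the whole window.
#' @return A [trajectory()] at `rate_hz`.
#' @export
#' @examples
#' rec <- gaze_recording(t_s = c(0, 1), x_px = c(0, 60), y_px = c(0, 60))
#' tr <- resample_to_uniform(rec, rate_hz = 60, duration_s = 1)
#' tr$x[1:5]  # 0, 1, 2, 3, 4: linear in t
resample_to_uniform <- function(rec, rate_hz = 60, duration_s = NULL) {
  stopifnot(inherits(rec, "gaze_recording"))
  t0 <- rec$t_s[1]
  t_rel <- rec$t_s - t0
  span <- t_rel[length(t_rel)]
  if (is.null(duration_s)) duration_s <- span + 1 / rate_hz
  n_out <- round(rate_hz * duration_s)
  if (n_out < 1L) stop("requested window is empty", call. = FALSE)
  t_out <- (seq_len(n_out) - 1) / rate_hz
  if (max(t_out) > span + 1e-9)
    stop(sprintf("recording covers [0, %.4f] s after origin shift but samples up to %.4f s were requested; interval (%.4f, %.4f] is uncovered",
                 span, max(t_out), span, max(t_out)), call. = FALSE)
  x_out <- stats::approx(t_rel, rec$x_px, xout = t_out, method = "linear")$y
  y_out <- stats::approx(t_rel, rec$y_px, xout = t_out, method = "linear")$y
  trajectory(x_out, y_out, rate_hz = rate_hz)
}

#' Read and write gaze recordings as delimited text
#'
#' The on-disk format is a delimited text file with a header naming the time,
#' x and y columns (defaults `t_s`, `x_px`, `y_px`), UTF-8 encoded, `.` as the
#' decimal separator. Values are written with enough significant digits that a
#' save/load round trip reproduces the recording bit-exactly.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma; e.g. `";"` for semicolon
#'   dialects).
#' @param columns Named character vector mapping the roles `t`, `x`, `y` to
#'   header names in the file.
#' @param source_id Label for the loaded recording; defaults to the file name.
#' @return `load_gaze_csv()` returns a [gaze_recording()]; `save_gaze_csv()`
#'   invisibly returns `path`.
#' @export
load_gaze_csv <- function(path, delim = ",",
                          columns = c(t = "t_s", x = "x_px", y = "y_px"),
                          source_id = basename(path)) {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(columns), names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  gaze_recording(df[[columns[["t"]]]], df[[columns[["x"]]]], df[[columns[["y"]]]],
                 source_id = source_id)
}

#' @rdname load_gaze_csv
#' @param rec A [gaze_recording()] or [trajectory()] (trajectories are written
#'   with their implied uniform timestamps).
#' @export
save_gaze_csv <- function(rec, path, delim = ",",
                          columns = c(t = "t_s", x = "x_px", y = "y_px")) {
  if (inherits(rec, "spem_trajectory")) {
    df <- as.data.frame(rec)
  } else {
    stopifnot(inherits(rec, "gaze_recording"))
    df <- data.frame(t_s = rec$t_s, x_px = rec$x_px, y_px = rec$y_px)
  }
  names(df) <- columns[c("t", "x", "y")]
  # 17 significant digits: lossless for doubles
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  out <- vapply(seq_len(nrow(df)), function(i)
    paste(fmt(c(df[i, 1], df[i, 2], df[i, 3])), collapse = delim), character(1))
  writeLines(c(paste(names(df), collapse = delim), out), con = path)
  invisible(path)
}
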