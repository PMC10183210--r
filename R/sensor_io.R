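#' Construct a sensor time series
#'
#' Container for the calibrated, animal-frame sensor streams of one tag
#' deployment: depth (meters, positive down), triaxial acceleration (m/s^2),
#' and orientation (pitch, roll, heading in degrees), all on a uniform time
#' grid. Times are seconds from deployment start; absolute datetimes live in
#' the deployment metadata only.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param depth Numeric vector, meters positive down. Small negative values
#'   (>= -0.5 m) are tolerated as surface sensor noise.
#' @param accel n x 3 matrix of triaxial acceleration, m/s^2.
#' @param pitch,roll,heading Orientation in degrees; roll in [-180, 180],
#'   heading in [0, 360).
#' @return A list of class `sensor_series` with elements `sampling_rate`,
#'   `time`, `depth`, `accel`, `pitch`, `roll`, `heading`.
#' @export
sensor_series <- function(sampling_rate, depth, accel, pitch, roll, heading) {
  n <- length(depth)
  accel <- as.matrix(accel)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a positive number")
  if (nrow(accel) != n || ncol(accel) != 3L)
    stop("accel must be an n x 3 matrix matching depth length")
  if (length(pitch) != n || length(roll) != n || length(heading) != n)
    stop("pitch, roll, heading must match depth length")
  if (any(depth < -0.5, na.rm = TRUE))
    stop("depth below -0.5 m: sign convention is positive down")
  if (any(is.na(depth)) || any(is.na(accel)))
    stop("gaps (NA) in sensor channels are not supported")
  if (any(roll < -180 | roll > 180))
    stop("roll outside [-180, 180] degrees")
  if (any(heading < 0 | heading >= 360))
    stop("heading outside [0, 360) degrees")
  structure(list(
    sampling_rate = sampling_rate,
    time = (seq_len(n) - 1L) / sampling_rate,
    depth = as.numeric(depth),
    accel = unname(accel),
    pitch = as.numeric(pitch),
    roll = as.numeric(roll),
    heading = as.numeric(heading)
  ), class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("sensor_series: %d samples at %g Hz (%.1f s), depth %0.1f-%0.1f m\n",
              length(x$depth), x$sampling_rate,
              length(x$depth) / x$sampling_rate,
              min(x$depth), max(x$depth)))
  invisible(x)
}

#' Read a sensor series from columnar CSV
#'
#' Columns: `time_s`, `depth`, `ax`, `ay`, `az`, `pitch`, `roll`, `heading`.
#' The time column must be a strictly increasing uniform grid; its step
#' defines the sampling rate (or is checked against `sampling_rate` when
#' given).
#'
#' @param path CSV path.
#' @param sampling_rate Optional declared rate in Hz; checked against the
#'   time column.
#' @return A [sensor_series()].
#' @export
read_sensor_series <- function(path, sampling_rate = NULL) {
  d <- utils::read.csv(path)
  required <- c("time_s", "depth", "ax", "ay", "az", "pitch", "roll", "heading")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0L)
    stop("sensor file missing channel(s): ",
         paste(missing_cols, collapse = ", "))
  dt <- diff(d$time_s)
  if (any(dt <= 0)) stop("time column is not strictly increasing")
  if (length(dt) > 0 && max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("time column is not a uniform grid")
  fs <- if (length(dt) > 0) 1 / dt[1] else sampling_rate
  if (is.null(fs)) stop("cannot infer sampling rate from a single sample")
  if (!is.null(sampling_rate) && abs(fs - sampling_rate) > 1e-6 * sampling_rate)
    stop(sprintf("declared rate %g Hz does not match time grid (%g Hz)",
                 sampling_rate, fs))
  sensor_series(fs, d$depth, cbind(d$ax, d$ay, d$az), d$pitch, d$roll,
                d$heading)
}

#' Write a sensor series to columnar CSV
#'
#' @param x A [sensor_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensor_series <- function(x, path) {
  utils::write.csv(data.frame(
    time_s = x$time, depth = x$depth,
    ax = x$accel[, 1], ay = x$accel[, 2], az = x$accel[, 3],
    pitch = x$pitch, roll = x$roll, heading = x$heading
  ), path, row.names = FALSE)
  invisible(path)
}

#' Read sound events (click and prey-handling times)
#'
#' @param path CSV with columns `time_s`, `kind` (`click`/`handling`) and
#'   optionally `class` (`slow`/`fast`/`buzz`, for pre-classified clicks).
#' @return data.frame with `time_s`, `kind`, and `class` (NA when absent).
#' @export
read_sound_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "kind") %in% names(d)))
    stop("events file must have columns time_s, kind")
  if (!all(d$kind %in% c("click", "handling")))
    stop("event kind must be 'click' or 'handling'")
  if (is.null(d$class)) d$class <- NA_character_
  d[order(d$time_s), c("time_s", "kind", "class")]
}

#' Write sound events
#' @param events data.frame as from [read_sound_events()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sound_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read GPS fixes
#'
#' @param path CSV with columns `time_s`, `lat`, `lon`, and optionally
#'   `err_m` (horizontal error).
#' @return data.frame with strictly increasing `time_s`.
#' @export
read_gps_fixes <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "lat", "lon") %in% names(d)))
    stop("GPS file must have columns time_s, lat, lon")
  if (nrow(d) < 1L) stop("at least one GPS fix is required")
  if (any(diff(d$time_s) <= 0)) stop("GPS fix times must be strictly increasing")
  if (is.null(d$err_m)) d$err_m <- NA_real_
  d[, c("time_s", "lat", "lon", "err_m")]
}

#' Write GPS fixes
#' @param fixes data.frame as from [read_gps_fixes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gps_fixes <- function(fixes, path) {
  utils::write.csv(fixes, path, row.names = FALSE, na = "")
  invisible(path)
}
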