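EARTH_RADIUS_M <- 6371000

m_per_deg_lat <- function() pi * EARTH_RADIUS_M / 180

#' Dead-reckon a pseudotrack from orientation data
#'
#' Integrates heading and pitch from an origin fix to a horizontal track:
#' each sample advances the position by `speed * cos(pitch) * dt` along the
#' current heading. Positions accumulate on a local tangent plane
#' (equirectangular projection about the origin latitude -- adequate for
#' deployment extents of a few kilometers) and are converted to
#' latitude/longitude. The track is decimated to `decimate_hz` for
#' georeferencing; full sensor-rate resolution carries no positional
#' information beyond it.
#'
#' Speed defaults to a constant cruising value, optionally replaced per
#' sample by the vertical-speed heuristic `|dz/dt| / |sin(pitch)|` whenever
#' `|pitch| > 30` degrees, where the depth rate constrains the speed well.
#'
#' @param series A [sensor_series()] with heading and pitch.
#' @param speed Constant swim speed in m/s (default 1.5) or a per-sample
#'   vector.
#' @param origin data.frame row with `lat`, `lon` (and `time_s`) for the
#'   first fix.
#' @param decimate_hz Output track rate in Hz. Default 1.
#' @param use_depth_rate Apply the vertical-speed heuristic at steep pitch.
#'   Default `TRUE`.
#' @return data.frame of class `track`: `time_s`, `lat`, `lon`, with
#'   attribute `corrected = FALSE`.
#' @export
dead_reckon <- function(series, speed = 1.5, origin, decimate_hz = 1,
                        use_depth_rate = TRUE) {
  stopifnot(inherits(series, "sensor_series"))
  n <- length(series$depth)
  if (length(speed) == 1L) speed <- rep(speed, n)
  if (any(speed <= 0)) stop("speed must be positive")
  if (length(speed) != n) stop("per-sample speed must match series length")
  dt <- 1 / series$sampling_rate
  if (use_depth_rate) {
    steep <- abs(series$pitch) > 30
    dz <- c(diff(series$depth), 0) / dt
    est <- abs(dz) / abs(sin(series$pitch * pi / 180))
    speed[steep & is.finite(est)] <- est[steep & is.finite(est)]
  }
  hd <- series$heading * pi / 180
  step <- speed * cos(series$pitch * pi / 180) * dt
  x <- cumsum(step * sin(hd))  # east
  y <- cumsum(step * cos(hd))  # north
  keep <- seq(1L, n, by = max(1L, round(series$sampling_rate / decimate_hz)))
  lat <- origin$lat + y[keep] / m_per_deg_lat()
  lon <- origin$lon + x[keep] / (m_per_deg_lat() * cos(origin$lat * pi / 180))
  out <- data.frame(time_s = series$time[keep], lat = lat, lon = lon)
  attr(out, "corrected") <- FALSE
  class(out) <- c("track", "data.frame")
  out
}

#' Force a dead-reckoned track through GPS fixes
#'
#' Dead reckoning accumulates drift; periodic GPS fixes at surfacings anchor
#' it. Between consecutive fixes the position error (fix minus predicted
#' position) is distributed linearly in time, so the corrected track passes
#' exactly through every fix at its time. Before the first and after the
#' last fix a constant offset is applied.
#'
#' @param track A `track` from [dead_reckon()].
#' @param fixes data.frame with `time_s`, `lat`, `lon`; times must lie
#'   within the track's time span.
#' @return The corrected `track` (attribute `corrected = TRUE`).
#' @export
force_through_fixes <- function(track, fixes) {
  if (nrow(fixes) < 1L) stop("at least one GPS fix is required")
  if (any(fixes$time_s < min(track$time_s) | fixes$time_s > max(track$time_s)))
    stop("GPS fix outside the track time span")
  pred_lat <- stats::approx(track$time_s, track$lat, fixes$time_s)$y
  pred_lon <- stats::approx(track$time_s, track$lon, fixes$time_s)$y
  err_lat <- fixes$lat - pred_lat
  err_lon <- fixes$lon - pred_lon
  if (nrow(fixes) == 1L) {
    # a single fix pins the track with a constant shift
    corr_lat <- rep(err_lat, nrow(track))
    corr_lon <- rep(err_lon, nrow(track))
  } else {
    # piecewise-linear error in time; constant beyond the first/last fix
    corr_lat <- stats::approx(fixes$time_s, err_lat, track$time_s, rule = 2)$y
    corr_lon <- stats::approx(fixes$time_s, err_lon, track$time_s, rule = 2)$y
  }
  track$lat <- track$lat + corr_lat
  track$lon <- track$lon + corr_lon
  attr(track, "corrected") <- TRUE
  track
}

#' Read an ESRI ASCII bathymetry grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by the depth matrix,
#' rows running north to south. Depth values are meters positive down.
#'
#' @param path Path to an `.asc` file.
#' @return List of class `bathymetry_grid`: `ncols`, `nrows`, `xll`, `yll`,
#'   `cellsize`, `nodata`, and `depth` (nrows x ncols matrix, row 1 = north).
#' @export
read_bathymetry <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA
  structure(list(ncols = hdr$ncols, nrows = hdr$nrows,
                 xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize, nodata = hdr$nodata_value,
                 depth = m),
            class = "bathymetry_grid")
}

#' Write an ESRI ASCII bathymetry grid
#' @param grid A `bathymetry_grid`.
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_bathymetry <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$ncols), paste("nrows", grid$nrows),
    paste("xllcorner", format(grid$xll, digits = 12)),
    paste("yllcorner", format(grid$yll, digits = 12)),
    paste("cellsize", format(grid$cellsize, digits = 12)),
    paste("NODATA_value", grid$nodata)
  ), con)
  m <- grid$depth
  m[is.na(m)] <- grid$nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

grid_cell_index <- function(u) {
  # u: position in cell units from the lower-left corner. The containing
  # cell is ceiling(u); a position exactly on a cell boundary ties toward
  # the lower index.
  idx <- ceiling(u)
  on_boundary <- abs(u - round(u)) < 1e-12 & round(u) >= 1
  idx[on_boundary] <- round(u[on_boundary])
  idx[abs(u) < 1e-12] <- 1L  # lower-left edge belongs to the first cell
  idx[u < -1e-12] <- 0L      # outside the grid
  as.integer(idx)
}

#' Look up bathymetry at dive-start positions
#'
#' Interpolates the corrected track to each dive's start time and reads the
#' water depth from the containing grid cell (nearest-cell lookup; positions
#' exactly on a cell boundary tie toward the lower index). Positions outside
#' the grid yield missing bathymetry with a warning.
#'
#' @param track A corrected `track`.
#' @param dives A `dive_table`.
#' @param grid A `bathymetry_grid`.
#' @return The dive table with added `start_lat`, `start_lon`, and
#'   `bathymetry_m` columns.
#' @export
bathymetry_at_dives <- function(track, dives, grid) {
  if (!isTRUE(attr(track, "corrected")))
    warning("track has not been forced through GPS fixes")
  lat <- stats::approx(track$time_s, track$lat, dives$start_s, rule = 2)$y
  lon <- stats::approx(track$time_s, track$lon, dives$start_s, rule = 2)$y
  col <- grid_cell_index((lon - grid$xll) / grid$cellsize)
  row_from_bottom <- grid_cell_index((lat - grid$yll) / grid$cellsize)
  row <- grid$nrows - row_from_bottom + 1L
  ok <- col >= 1L & col <= grid$ncols & row >= 1L & row <= grid$nrows
  depth <- rep(NA_real_, nrow(dives))
  depth[ok] <- grid$depth[cbind(row[ok], col[ok])]
  if (any(!ok))
    warning(sum(!ok), " dive position(s) outside the bathymetry grid")
  dives$start_lat <- lat
  dives$start_lon <- lon
  dives$bathymetry_m <- depth
  dives
}
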