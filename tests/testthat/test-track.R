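origin <- data.frame(time_s = 0, lat = 48.5, lon = -123.2)
M_LAT <- pi * 6371000 / 180

test_that("dead reckoning integrates straight-line motion correctly", {
  # heading due north, level pitch, 1 m/s for 60 s -> 60 m north
  s <- make_series(rep(0, 61), fs = 1)
  tr <- dead_reckon(s, speed = 1, origin = origin, use_depth_rate = FALSE)
  north_m <- (tr$lat[nrow(tr)] - origin$lat) * M_LAT
  expect_equal(north_m, 61, tolerance = 1e-9)  # 61 samples of 1 s
  expect_equal(tr$lon[nrow(tr)], origin$lon, tolerance = 1e-12)

  # vertical pitch: no horizontal displacement
  s2 <- make_series(rep(10, 61), fs = 1, pitch = rep(-90, 61))
  tr2 <- dead_reckon(s2, speed = 1, origin = origin, use_depth_rate = FALSE)
  expect_equal(tr2$lat[nrow(tr2)], origin$lat, tolerance = 1e-12)

  expect_error(dead_reckon(s, speed = 0, origin = origin), "positive")
})

test_that("a closed square path returns to its origin", {
  leg <- 100  # seconds per leg at 1 m/s
  heading <- rep(c(0, 90, 180, 270), each = leg)
  s <- make_series(rep(0, length(heading)), fs = 1, heading = heading)
  tr <- dead_reckon(s, speed = 1, origin = origin, use_depth_rate = FALSE)
  end_err_m <- sqrt(((tr$lat[nrow(tr)] - origin$lat) * M_LAT)^2 +
                    ((tr$lon[nrow(tr)] - origin$lon) * M_LAT *
                       cos(origin$lat * pi / 180))^2)
  expect_lt(end_err_m / leg, 1e-6)
})

test_that("forcing through fixes distributes drift linearly in time", {
  s <- make_series(rep(0, 601), fs = 1)
  tr <- dead_reckon(s, speed = 1, origin = origin, use_depth_rate = FALSE)

  # a track already through its fixes is unchanged
  fx <- data.frame(time_s = c(0, 300, 600),
                   lat = approx(tr$time_s, tr$lat, c(0, 300, 600))$y,
                   lon = approx(tr$time_s, tr$lon, c(0, 300, 600))$y)
  tr2 <- force_through_fixes(tr, fx)
  expect_equal(tr2$lat, tr$lat, tolerance = 1e-12)
  expect_equal(tr2$lon, tr$lon, tolerance = 1e-12)

  # constant drift of d degrees at the second fix ramps linearly 0 -> d
  d <- 0.001
  fx2 <- fx
  fx2$lon[2:3] <- fx2$lon[2:3] + d
  tr3 <- force_through_fixes(tr, fx2)
  applied <- tr3$lon - tr$lon
  # comparisons at the precision left by differencing O(100)-degree
  # longitudes (~1e-14 absolute)
  expect_equal(applied[tr$time_s == 0], 0, tolerance = 1e-9)
  expect_equal(applied[tr$time_s == 150], d / 2, tolerance = 1e-9)
  expect_equal(applied[tr$time_s == 300], d, tolerance = 1e-9)
  expect_equal(applied[tr$time_s == 450], d, tolerance = 1e-9)

  # a single fix shifts the whole track by a constant
  one <- data.frame(time_s = 300, lat = fx$lat[2] + d, lon = fx$lon[2])
  tr4 <- force_through_fixes(tr, one)
  expect_equal(unique(round(tr4$lat - tr$lat, 12)), round(d, 12))

  expect_error(force_through_fixes(tr, data.frame(time_s = 1e6, lat = 0,
                                                  lon = 0)), "span")
})

test_that("corrected tracks are exact at every fix", {
  sim <- simulate_deployment(simulation_config(seed = 13, duration_h = 0.5))
  tr <- dead_reckon(sim$series, speed = sim$config$swim_speed,
                    origin = sim$fixes[1, ], use_depth_rate = FALSE)
  tr <- force_through_fixes(tr, sim$fixes)
  at <- function(v) approx(tr$time_s, v, sim$fixes$time_s)$y
  expect_lt(max(abs(at(tr$lat) - sim$fixes$lat)), 1e-9)
  expect_lt(max(abs(at(tr$lon) - sim$fixes$lon)), 1e-9)
})

test_that("corrected track error stays within the inter-fix drift bound", {
  cfg <- simulation_config(seed = 29, duration_h = 0.5, gps_error_m = 0)
  sim <- simulate_deployment(cfg)
  tr <- force_through_fixes(
    dead_reckon(sim$series, speed = cfg$swim_speed, origin = sim$fixes[1, ],
                use_depth_rate = FALSE),
    sim$fixes)
  tt <- sim$truth$true_track
  common <- intersect(tr$time_s, tt$time_s)
  rms_m <- sqrt(mean(
    ((approx(tr$time_s, tr$lat, common)$y -
        approx(tt$time_s, tt$lat, common)$y) * M_LAT)^2 +
    ((approx(tr$time_s, tr$lon, common)$y -
        approx(tt$time_s, tt$lon, common)$y) * M_LAT *
       cos(48.5 * pi / 180))^2))
  # with exact fixes and the true speed, residual error comes only from
  # dive-phase pitch effects between fixes; it must stay well under the
  # distance swum between fixes (300 s at 1.5 m/s)
  expect_lt(rms_m, 450 / 4)
})

test_that("ESRI ASCII grids round-trip and look up by containing cell", {
  g <- structure(list(ncols = 2, nrows = 2, xll = -124, yll = 48,
                      cellsize = 0.5, nodata = -9999,
                      depth = matrix(c(10, 20, 100, 300), 2, 2,
                                     byrow = TRUE)),
                 class = "bathymetry_grid")
  path <- withr::local_tempfile(fileext = ".asc")
  write_bathymetry(g, path)
  g2 <- read_bathymetry(path)
  expect_equal(g2$depth, g$depth)
  expect_equal(g2$cellsize, 0.5)

  mk_track <- function(lon, lat) {
    tr <- data.frame(time_s = c(0, 100), lat = lat, lon = lon)
    attr(tr, "corrected") <- TRUE
    class(tr) <- c("track", "data.frame")
    tr
  }
  dives <- data.frame(dive_id = 1:2, start_s = c(0, 100), end_s = c(50, 150))

  # uniform grid: every dive gets the same value
  gu <- g; gu$depth[] <- 200
  tr <- mk_track(c(-123.9, -123.1), c(48.1, 48.1))
  out <- bathymetry_at_dives(tr, dives, gu)
  expect_equal(out$bathymetry_m, c(200, 200))

  # west/east cells of the bottom row are 100 / 300
  out2 <- bathymetry_at_dives(tr, dives, g)
  expect_equal(out2$bathymetry_m, c(100, 300))

  # a position exactly on the cell-boundary meridian ties to the lower
  # (western) cell
  trb <- mk_track(c(-123.5, -123.5), c(48.1, 48.1))
  out3 <- bathymetry_at_dives(trb, dives, g)
  expect_equal(out3$bathymetry_m, c(100, 100))

  # outside the grid: missing with a warning
  tro <- mk_track(c(-130, -123.1), c(48.1, 48.1))
  expect_warning(out4 <- bathymetry_at_dives(tro, dives, g), "outside")
  expect_true(is.na(out4$bathymetry_m[1]) && out4$bathymetry_m[2] == 300)
})

test_that("bathymetry lookup is invariant to track decimation", {
  sim <- simulate_deployment(simulation_config(seed = 41, duration_h = 0.5))
  g <- structure(list(ncols = 40, nrows = 40, xll = -123.4, yll = 48.3,
                      cellsize = 0.01, nodata = -9999,
                      depth = matrix(seq_len(1600), 40, 40)),
                 class = "bathymetry_grid")
  dv <- detect_dives(sim$series)
  for (hz in c(1, 0.2)) {
    tr <- force_through_fixes(
      dead_reckon(sim$series, speed = 1.5, origin = sim$fixes[1, ],
                  decimate_hz = hz, use_depth_rate = FALSE),
      sim$fixes)
    assign(paste0("b", hz), bathymetry_at_dives(tr, dv, g)$bathymetry_m)
  }
  # same cell, or an adjacent one where the position sits near a boundary
  expect_true(mean(b1 == b0.2) >= 0.8)
})
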