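# Hand-constructed sensor series and truth-matching utilities shared by the
# test files. All fixtures are built in code; nothing is read from disk
# except the packaged deployment table.

# A sensor series with a given depth profile and otherwise bland channels.
make_series <- function(depth, fs = 1, accel = NULL, pitch = NULL,
                        roll = NULL, heading = NULL) {
  n <- length(depth)
  if (is.null(accel)) {
    accel <- matrix(0, n, 3)
    accel[, 3] <- 9.81
  }
  if (is.null(pitch)) pitch <- rep(0, n)
  if (is.null(roll)) roll <- rep(0, n)
  if (is.null(heading)) heading <- rep(0, n)
  sensor_series(fs, depth, accel, pitch, roll, heading)
}

# Trapezoidal dive profile: flat surface, linear descent to `depth`, flat
# bottom, linear ascent, flat surface; one sample per second at fs = 1.
trapezoid_depth <- function(t_total, t_start, descent_s, bottom_s, depth,
                            fs = 1) {
  t <- (seq_len(t_total * fs) - 1) / fs
  tt <- t - t_start
  dive_dur <- 2 * descent_s + bottom_s
  prof <- pmin(tt * depth / descent_s,
               pmin(depth, (dive_dur - tt) * depth / descent_s))
  pmax(prof, 0)
}

# Match detected dives to truth dives by interval containment (allowing the
# detected boundaries to extend a couple of samples beyond the scheduled
# interval); returns the truth type per detected dive, NA when unmatched.
match_truth_type <- function(detected, truth, tol = 2) {
  vapply(seq_len(nrow(detected)), function(i) {
    j <- which(truth$start_s <= detected$start_s[i] + tol &
               truth$end_s >= detected$end_s[i] - tol)
    if (length(j) == 1L) truth$type[j] else NA_character_
  }, character(1))
}

# Full kinematic + acoustic processing of one simulated deployment.
process_deployment <- function(sim) {
  dv <- detect_dives(sim$series)
  dv <- partition_phases(dv, sim$series)
  ft <- phase_features(dv, sim$series)
  su <- summarize_dive_acoustics(ft, sim$events)
  list(features = ft, summaries = su,
       truth_type = match_truth_type(ft, sim$truth$dives))
}
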