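#' Detect dives in a depth record
#'
#' A dive is a depth excursion exceeding `min_depth` bounded by surfacings
#' shallower than `surface_depth`. Boundaries are placed at the last sample
#' below `surface_depth` before the excursion and the first below after it,
#' so the reported interval includes the surfacing samples on either side.
#' Very short excursions (pressure-sensor flutter or incomplete surfacings)
#' and dives that begin during the immediate post-tagging window are
#' discarded.
#'
#' @param series A [sensor_series()].
#' @param min_depth Minimum depth (m) an excursion must exceed to count as a
#'   dive. Default 1.
#' @param surface_depth Depth (m) below which the animal is considered at the
#'   surface. Default 0.5.
#' @param min_duration Minimum dive duration (s). Default 4.
#' @param exclusion_window Dives starting within this many seconds of
#'   deployment start are excluded (short-term response to tagging).
#'   Default 300.
#' @return data.frame of class `dive_table`: `dive_id`, `start_s`, `end_s`,
#'   `max_depth_m`, plus start/end sample indices (`start_idx`, `end_idx`)
#'   used by downstream phase partitioning.
#' @export
detect_dives <- function(series, min_depth = 1, surface_depth = 0.5,
                         min_duration = 4, exclusion_window = 300) {
  stopifnot(inherits(series, "sensor_series"))
  n <- length(series$depth)
  empty <- data.frame(dive_id = integer(), start_s = numeric(),
                      end_s = numeric(), max_depth_m = numeric(),
                      start_idx = integer(), end_idx = integer())
  class(empty) <- c("dive_table", "data.frame")
  if (n / series$sampling_rate <= exclusion_window) {
    warning("series shorter than the exclusion window: no dives analyzed")
    return(empty)
  }
  wet <- series$depth >= surface_depth
  if (!any(wet)) return(empty)
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sub_start <- starts[r$values]
  sub_end <- ends[r$values]

  # bound each submerged run by its adjacent surface samples (< surface_depth);
  # ties at the threshold break toward the longer dive because the boundary
  # sample is strictly below the threshold by construction of `wet`
  b_start <- pmax(sub_start - 1L, 1L)
  b_end <- pmin(sub_end + 1L, n)

  keep <- logical(length(sub_start))
  maxd <- numeric(length(sub_start))
  for (k in seq_along(sub_start)) {
    maxd[k] <- max(series$depth[sub_start[k]:sub_end[k]])
    dur <- series$time[b_end[k]] - series$time[b_start[k]]
    keep[k] <- maxd[k] > min_depth && dur >= min_duration &&
      series$time[b_start[k]] >= exclusion_window
  }
  out <- data.frame(
    dive_id = seq_len(sum(keep)),
    start_s = series$time[b_start[keep]],
    end_s = series$time[b_end[keep]],
    max_depth_m = maxd[keep],
    start_idx = b_start[keep],
    end_idx = b_end[keep]
  )
  class(out) <- c("dive_table", "data.frame")
  out
}

#' Partition dives into descent, bottom, and ascent phases
#'
#' The bottom phase of a dive is the contiguous span from the first to the
#' last sample at or above `bottom_fraction` of the dive's maximum depth;
#' descent runs from the dive start to the first such sample and ascent from
#' the last such sample to the dive end. Every dive has at least one bottom
#' sample (its maximum), so the partition always exists; a square (instant
#' descent) profile degenerates to a descent of a single sampling interval.
#'
#' @param dives A `dive_table` from [detect_dives()].
#' @param series The same [sensor_series()] the dives were detected in.
#' @param bottom_fraction Fraction of maximum dive depth defining the bottom
#'   phase. Default 0.70.
#' @return The dive table with added columns `descent_end_s`,
#'   `ascent_start_s` and the matching sample indices `descent_end_idx`,
#'   `ascent_start_idx`.
#' @export
partition_phases <- function(dives, series, bottom_fraction = 0.70) {
  stopifnot(inherits(series, "sensor_series"))
  de_idx <- as_idx <- integer(nrow(dives))
  for (k in seq_len(nrow(dives))) {
    idx <- dives$start_idx[k]:dives$end_idx[k]
    thr <- bottom_fraction * dives$max_depth_m[k]
    bottom <- idx[series$depth[idx] >= thr]
    de_idx[k] <- bottom[1L]
    as_idx[k] <- bottom[length(bottom)]
  }
  dives$descent_end_s <- series$time[de_idx]
  dives$ascent_start_s <- series$time[as_idx]
  dives$descent_end_idx <- de_idx
  dives$ascent_start_idx <- as_idx
  dives
}

#' Jerk magnitude of a triaxial acceleration record
#'
#' Jerk is the rate of change of acceleration. Computed as the Euclidean norm
#' of the first difference of the triaxial acceleration multiplied by the
#' sampling rate; the result has one sample fewer than the input and is
#' timestamped at the leading sample of each difference.
#'
#' @param series A [sensor_series()] with at least 2 samples.
#' @return Numeric vector of jerk magnitudes (m/s^3), length `n - 1`, with a
#'   `time` attribute giving leading-sample timestamps.
#' @export
jerk_magnitude <- function(series) {
  stopifnot(inherits(series, "sensor_series"))
  if (length(series$depth) < 2L) stop("need at least 2 samples for jerk")
  da <- diff(series$accel)
  j <- sqrt(rowSums(da^2)) * series$sampling_rate
  attr(j, "time") <- series$time[-length(series$time)]
  j
}

#' Circular variance of headings
#'
#' One minus the mean resultant length of the unit vectors at the given
#' angles: 0 when all headings coincide, 1 when they cancel completely.
#' Invariant to a common rotation of all headings.
#'
#' @param headings_deg Headings in degrees (any range; angles are taken
#'   modulo 360).
#' @return Scalar in [0, 1].
#' @examples
#' circular_variance(c(0, 90, 180, 270))  # 1
#' circular_variance(c(45, 45, 45))       # 0
#' @export
circular_variance <- function(headings_deg) {
  if (length(headings_deg) == 0L) stop("at least one heading is required")
  a <- headings_deg * pi / 180
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  # clamp tiny negative round-off
  max(0, min(1, 1 - rbar))
}

#' Per-phase kinematic features of dives
#'
#' For each dive phase (descent, bottom, ascent) computes the three
#' kinematic variables predictive of prey capture:
#' \describe{
#'   \item{jerk_peak}{maximum jerk magnitude in the phase divided by the
#'     deployment-wide median jerk magnitude (a scale-free normalization
#'     across tags and sampling rates);}
#'   \item{roll}{absolute roll (degrees) at the time of the phase's jerk
#'     peak;}
#'   \item{headvar}{circular variance of heading over the phase samples.}
#' }
#'
#' @param dives A phase-partitioned dive table ([partition_phases()]).
#' @param series The matching [sensor_series()].
#' @param median_jerk Deployment-level median of [jerk_magnitude()]; computed
#'   from `series` (including surface periods) when `NULL`. Must be > 0.
#' @return The dive table with nine feature columns:
#'   `descent_jerk_peak`, `descent_roll`, `descent_headvar`, and likewise for
#'   `bottom` and `ascent`.
#' @export
phase_features <- function(dives, series, median_jerk = NULL) {
  stopifnot(inherits(series, "sensor_series"))
  if (!"descent_end_idx" %in% names(dives))
    stop("dives must be phase-partitioned first (see partition_phases)")
  jerk <- jerk_magnitude(series)
  if (is.null(median_jerk)) median_jerk <- stats::median(jerk)
  if (!is.finite(median_jerk) || median_jerk <= 0)
    stop("median jerk must be > 0 (constant-acceleration record?)")

  phases <- c("descent", "bottom", "ascent")
  for (ph in phases) {
    dives[[paste0(ph, "_jerk_peak")]] <- NA_real_
    dives[[paste0(ph, "_roll")]] <- NA_real_
    dives[[paste0(ph, "_headvar")]] <- NA_real_
  }
  nj <- length(jerk)
  for (k in seq_len(nrow(dives))) {
    bounds <- list(
      descent = c(dives$start_idx[k], dives$descent_end_idx[k]),
      bottom = c(dives$descent_end_idx[k], dives$ascent_start_idx[k]),
      ascent = c(dives$ascent_start_idx[k], dives$end_idx[k])
    )
    for (ph in phases) {
      i1 <- bounds[[ph]][1]; i2 <- bounds[[ph]][2]
      # jerk samples are timestamped at the leading sample: those fully
      # inside the phase have leading index in [i1, i2 - 1]
      ji <- i1:max(i1, i2 - 1L)
      ji <- ji[ji <= nj]
      pk <- which.max(jerk[ji])
      dives[[paste0(ph, "_jerk_peak")]][k] <- jerk[ji[pk]] / median_jerk
      dives[[paste0(ph, "_roll")]][k] <- abs(series$roll[ji[pk]])
      dives[[paste0(ph, "_headvar")]][k] <-
        circular_variance(series$heading[i1:i2])
    }
  }
  dives
}
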