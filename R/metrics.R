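#' Per-deployment foraging metrics from processed dives
#'
#' Combines a deployment record, its capture-labeled dive table, and its
#' acoustic summaries into the deployment-level foraging metrics: number of
#' prey-capture dives, capture rate (captures per deployment hour), foraging
#' efficiency (captures per hour of acoustic searching; missing when no
#' usable audio, undefined when searching time is zero), the proportions of
#' deployment time spent in capture dives and in travel/rest dives, and the
#' maximum depths and bathymetries of capture dives.
#'
#' @param record One-row `deployment_table`.
#' @param dives Capture-labeled dive table (logical `capture` column;
#'   `bathymetry_m` optional).
#' @param summaries Per-dive acoustic summaries, or `NULL` when audio could
#'   not be analyzed.
#' @return One-row data.frame: `deployment_id`, `n_capture_dives`,
#'   `capture_rate`, `searching_h`, `efficiency`, `prop_time_capture`,
#'   `prop_time_travel_rest`, plus list columns `capture_max_depths` and
#'   `capture_bathymetries`.
#' @export
compute_metrics <- function(record, dives, summaries) {
  if (record$duration_h <= 0) stop("deployment duration must be > 0")
  if (is.null(dives$capture)) stop("dives must carry a logical capture label")
  dur_s <- record$duration_h * 3600
  cap <- dives[dives$capture, , drop = FALSE]
  n_cap <- nrow(cap)
  if (is.null(summaries)) {
    search_h <- NA_real_
    tr_h <- NA_real_
  } else {
    search_h <- searching_time(dives, summaries)
    tr_h <- travel_rest_time(dives, summaries)
  }
  eff <- if (is.na(search_h) || search_h == 0) NA_real_ else n_cap / search_h
  out <- data.frame(
    deployment_id = record$deployment_id,
    n_capture_dives = n_cap,
    capture_rate = n_cap / record$duration_h,
    searching_h = search_h,
    efficiency = eff,
    prop_time_capture = sum(cap$end_s - cap$start_s) / dur_s,
    prop_time_travel_rest = if (is.na(tr_h)) NA_real_ else tr_h * 3600 / dur_s,
    stringsAsFactors = FALSE
  )
  out$capture_max_depths <- list(cap$max_depth_m)
  out$capture_bathymetries <-
    list(if (is.null(cap$bathymetry_m)) numeric() else cap$bathymetry_m)
  out
}

#' Foraging metrics directly from a deployment summary table
#'
#' When per-deployment capture counts, durations, and searching times are
#' already tabulated (as in the packaged deployment table), the rate metrics
#' follow by arithmetic without reprocessing sensor data: capture rate is
#' count over duration and efficiency is count over searching time.
#' Efficiency is missing where audio could not be analyzed and undefined
#' (missing, flagged) where searching time is exactly zero.
#'
#' @param records A `deployment_table` with `n_capture_dives`, `duration_h`,
#'   `searching_h`.
#' @return data.frame with `deployment_id`, `n_capture_dives`,
#'   `capture_rate`, `searching_h`, `efficiency`, and a logical
#'   `efficiency_defined`.
#' @export
metrics_from_table <- function(records) {
  if (anyNA(records$n_capture_dives)) {
    warning("records without capture counts skipped")
    records <- records[!is.na(records$n_capture_dives), , drop = FALSE]
  }
  eff_def <- !is.na(records$searching_h) & records$searching_h > 0
  data.frame(
    deployment_id = records$deployment_id,
    n_capture_dives = records$n_capture_dives,
    capture_rate = records$n_capture_dives / records$duration_h,
    searching_h = records$searching_h,
    efficiency = ifelse(eff_def,
                        records$n_capture_dives / records$searching_h,
                        NA_real_),
    efficiency_defined = eff_def,
    stringsAsFactors = FALSE
  )
}

#' Group summaries of a foraging metric
#'
#' Unweighted mean (each deployment counts once, regardless of duration),
#' standard error, and median of a per-deployment metric within cohort
#' groups. Groupings: population by sex, adult females by calf status, adult
#' males by mother status, or population alone. The unknown-sex deployment
#' is excluded from all sex-based groupings; demographic groupings use only
#' adults with known status; deployments with a missing metric value are
#' dropped from that metric's summaries.
#'
#' @param metrics Output of [metrics_from_table()] or row-bound
#'   [compute_metrics()].
#' @param records The matching `deployment_table`.
#' @param grouping One of `"population_sex"`, `"calf"`, `"mother"`,
#'   `"population"`.
#' @param metric Name of the metric column to summarize. Default
#'   `"capture_rate"`.
#' @return data.frame with `group`, `n`, `mean`, `se`, `median`.
#' @export
group_means <- function(metrics, records,
                        grouping = c("population_sex", "calf", "mother",
                                     "population"),
                        metric = "capture_rate") {
  grouping <- match.arg(grouping)
  m <- match(metrics$deployment_id, records$deployment_id)
  if (anyNA(m)) stop("metrics contain deployments not in records")
  rec <- records[m, ]
  key <- switch(grouping,
    population_sex = ifelse(rec$sex == "unknown", NA,
                            paste(rec$population, rec$sex)),
    population = as.character(rec$population),
    calf = ifelse(rec$adult & rec$sex == "F" &
                    rec$calf_status != "not_applicable",
                  paste(rec$population, as.character(rec$calf_status)), NA),
    mother = ifelse(rec$adult & rec$sex == "M" &
                      rec$mother_status != "not_applicable",
                    paste(rec$population, as.character(rec$mother_status)), NA)
  )
  val <- metrics[[metric]]
  if (is.null(val)) stop("no metric column named '", metric, "'")
  keep <- !is.na(key) & !is.na(val)
  key <- key[keep]; val <- val[keep]
  if (length(val) == 0L) {
    warning("no usable observations for grouping '", grouping, "'")
    return(data.frame(group = character(), n = integer(), mean = numeric(),
                      se = numeric(), median = numeric()))
  }
  agg <- function(f) tapply(val, key, f)
  out <- data.frame(
    group = names(agg(mean)),
    n = as.integer(agg(length)),
    mean = as.numeric(agg(mean)),
    se = as.numeric(tapply(val, key,
                           function(v) if (length(v) > 1)
                             stats::sd(v) / sqrt(length(v)) else NA_real_)),
    median = as.numeric(agg(stats::median)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Percent difference between two group means
#'
#' `(a / b - 1) * 100`: how much larger `a` is than the reference `b`, in
#' percent.
#'
#' @param a Group mean of interest.
#' @param b Reference group mean; must be > 0.
#' @return Percent difference.
#' @examples
#' percent_difference(2, 1)  # 100
#' @export
percent_difference <- function(a, b) {
  if (any(b <= 0)) stop("reference mean must be > 0")
  (a / b - 1) * 100
}
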