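#' Acoustically confirmed prey-capture dives
#'
#' Dives whose acoustic record contains both a buzz (terminal prey approach)
#' and prey-handling sounds (processing of captured prey) are treated as
#' confirmed captures for threshold calibration. Buzzes alone also occur in
#' unsuccessful pursuits, so handling sounds are required by default;
#' set `require_handling = FALSE` for a buzz-only rule.
#'
#' @param dives A `dive_table`.
#' @param summaries Per-dive acoustic summaries
#'   ([summarize_dive_acoustics()]), or `NULL` when no usable audio exists
#'   for the deployment.
#' @param require_handling Require handling sounds in addition to a buzz.
#'   Default `TRUE`.
#' @return Integer vector of confirmed dive ids. When `summaries` is `NULL`
#'   the result is empty and carries attribute `uncalibratable = TRUE`.
#' @export
confirmed_captures <- function(dives, summaries, require_handling = TRUE) {
  if (is.null(summaries)) {
    out <- integer()
    attr(out, "uncalibratable") <- TRUE
    return(out)
  }
  sel <- summaries$has_buzz
  if (require_handling) sel <- sel & summaries$has_handling
  summaries$dive_id[sel]
}

#' Calibrate prey-capture detection thresholds for one population
#'
#' Sets the minimum thresholds for jerk peak, roll at jerk peak, and heading
#' circular variance from acoustically confirmed capture dives, at the
#' operating point with 100% sensitivity: for each confirmed dive the phase
#' with the largest jerk peak is taken as the capture phase, and each
#' threshold is the componentwise minimum of that phase's features across
#' confirmed dives. These are the largest thresholds that still pass every
#' confirmed dive, hence the ones minimizing the false-positive rate subject
#' to perfect sensitivity. The false-positive rate is then measured on the
#' non-confirmed dives. Calibration statistics are computed only on dives at
#' or beyond `depth_cutoff`, where acoustic confirmation is reliable.
#'
#' @param features Feature table from [phase_features()] for the calibration
#'   deployments, including `max_depth_m`.
#' @param confirmed_ids Dive ids confirmed by acoustics
#'   ([confirmed_captures()]).
#' @param population Population label stored with the thresholds.
#' @param depth_cutoff Calibration depth cutoff in meters. Default 50.
#' @return List of class `threshold_set`: `population`, `jerk_min`,
#'   `roll_min`, `headvar_min`, and `calibration` (list with `tpr`, `fpr`,
#'   `depth_cutoff`, `n_confirmed`, `n_negatives`).
#' @export
calibrate_thresholds <- function(features, confirmed_ids, population,
                                 depth_cutoff = 50) {
  deep <- features[features$max_depth_m >= depth_cutoff, , drop = FALSE]
  pos <- deep[deep$dive_id %in% confirmed_ids, , drop = FALSE]
  neg <- deep[!deep$dive_id %in% confirmed_ids, , drop = FALSE]
  if (nrow(pos) == 0L)
    stop("no acoustically confirmed capture dives >= depth cutoff: ",
         "cannot calibrate thresholds")
  jp <- as.matrix(pos[, c("descent_jerk_peak", "bottom_jerk_peak",
                          "ascent_jerk_peak")])
  best <- max.col(jp, ties.method = "first")
  phase <- c("descent", "bottom", "ascent")[best]
  pick <- function(stem)
    vapply(seq_len(nrow(pos)),
           function(i) pos[[paste0(phase[i], "_", stem)]][i], numeric(1))
  thr <- structure(list(
    population = population,
    jerk_min = min(pick("jerk_peak")),
    roll_min = min(pick("roll")),
    headvar_min = min(pick("headvar")),
    calibration = NULL
  ), class = "threshold_set")
  fp <- if (nrow(neg) > 0L) mean(classify_dives(neg, thr)) else 0
  thr$calibration <- list(
    tpr = mean(classify_dives(pos, thr)),  # 1 by construction
    fpr = fp,
    depth_cutoff = depth_cutoff,
    n_confirmed = nrow(pos),
    n_negatives = nrow(neg)
  )
  thr
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("threshold_set [%s]: jerk >= %.3g, roll >= %.3g, headvar >= %.3g\n",
              x$population, x$jerk_min, x$roll_min, x$headvar_min))
  if (!is.null(x$calibration))
    cat(sprintf("  calibration: TPR %.2f, FPR %.2f (%d confirmed, %d negatives, dives >= %g m)\n",
                x$calibration$tpr, x$calibration$fpr,
                x$calibration$n_confirmed, x$calibration$n_negatives,
                x$calibration$depth_cutoff))
  invisible(x)
}

#' Classify dives as prey capture by kinematic thresholds
#'
#' A dive is classified as a prey capture when at least one of its phases
#' meets or exceeds all three thresholds simultaneously (inclusive
#' comparison). Dives of any depth are classified; the depth cutoff applies
#' only to calibration statistics.
#'
#' @param features Feature table from [phase_features()].
#' @param thresholds A `threshold_set`.
#' @return Logical vector, one element per row of `features`.
#' @export
classify_dives <- function(features, thresholds) {
  needed <- as.vector(outer(c("descent", "bottom", "ascent"),
                            c("jerk_peak", "roll", "headvar"), paste,
                            sep = "_"))
  if (!all(needed %in% names(features)))
    stop("features table lacks per-phase feature columns; ",
         "run phase_features() first")
  hit <- rep(FALSE, nrow(features))
  for (ph in c("descent", "bottom", "ascent")) {
    hit <- hit |
      (features[[paste0(ph, "_jerk_peak")]] >= thresholds$jerk_min &
       features[[paste0(ph, "_roll")]] >= thresholds$roll_min &
       features[[paste0(ph, "_headvar")]] >= thresholds$headvar_min)
  }
  if (anyNA(hit)) stop("missing phase features: cannot classify")
  hit
}

#' Confusion-matrix rates of a dive classifier
#'
#' @param predicted Logical vector of predicted capture labels.
#' @param truth Logical vector of true labels, same length.
#' @return List with `tpr` (sensitivity) and `fpr` (1 - specificity).
#' @export
evaluate_classifier <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (!any(truth)) stop("no positives in truth: TPR undefined")
  list(tpr = sum(predicted & truth) / sum(truth),
       fpr = if (any(!truth)) sum(predicted & !truth) / sum(!truth) else 0)
}
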