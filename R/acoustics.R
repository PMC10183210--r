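#' Classify echolocation clicks by inter-click interval
#'
#' Each click (except the first of a train) is classed by the interval to its
#' predecessor: buzz below 11 ms (terminal prey approach), fast from 11 to
#' 100 ms inclusive (pursuit), slow above 100 ms (searching). The first click
#' of a train inherits the class of its successor. Intervals longer than
#' `train_break` end a train, so gaps between click bouts are never counted
#' as slow intervals; a train consisting of a single isolated click is
#' classed slow (its neighbours are by definition further than the train
#' break, hence further than the slow cutoff).
#'
#' @param click_times Click times in seconds, sorted ascending.
#' @param buzz_max Buzz/fast boundary in seconds (exclusive). Default 0.011.
#' @param fast_max Fast/slow boundary in seconds (inclusive for fast).
#'   Default 0.100.
#' @param train_break Inter-click gap (s) that ends a click train.
#'   Default 2.
#' @return data.frame with `time_s` and `class`
#'   (`slow`/`fast`/`buzz`).
#' @export
classify_clicks <- function(click_times, buzz_max = 0.011, fast_max = 0.100,
                            train_break = 2) {
  n <- length(click_times)
  if (n == 0L)
    return(data.frame(time_s = numeric(), class = character()))
  if (is.unsorted(click_times, strictly = FALSE))
    stop("click times must be sorted ascending")
  # round intervals to the nearest microsecond so the class boundaries are
  # well defined despite floating-point time arithmetic
  ici <- round(diff(click_times), 6)
  cls <- rep(NA_character_, n)
  ici_class <- ifelse(ici < buzz_max, "buzz",
                      ifelse(ici <= fast_max, "fast", "slow"))
  # click i (i >= 2) is classed by its preceding interval unless that
  # interval breaks the train
  new_train <- c(TRUE, ici > train_break)
  cls[-1L][!new_train[-1L]] <- ici_class[!new_train[-1L]]
  # first click of each train inherits its successor's class; isolated
  # clicks (single-click trains) are slow
  for (i in which(new_train)) {
    if (i < n && !new_train[i + 1L]) cls[i] <- cls[i + 1L]
    else cls[i] <- "slow"
  }
  data.frame(time_s = click_times, class = cls, stringsAsFactors = FALSE)
}

#' Map sound events to dives and summarize per-dive acoustics
#'
#' Assigns each sound event to the dive whose `[start_s, end_s]` interval
#' contains its time (surface-period events are retained in the input but
#' attach to no dive) and summarizes click-class presence and counts per
#' dive. Unclassified clicks are classified first via [classify_clicks()].
#'
#' @param dives A `dive_table`.
#' @param events data.frame with `time_s`, `kind` (`click`/`handling`) and
#'   optional `class` for pre-classified clicks.
#' @return data.frame, one row per dive: `dive_id`, `has_slow`, `has_fast`,
#'   `has_buzz`, `has_handling`, `n_slow`, `n_fast`, `n_buzz`, `n_handling`.
#' @export
summarize_dive_acoustics <- function(dives, events) {
  clicks <- events[events$kind == "click", , drop = FALSE]
  if (nrow(clicks) > 0 &&
      (is.null(clicks$class) || all(is.na(clicks$class)))) {
    clicks <- merge(clicks["time_s"],
                    classify_clicks(sort(clicks$time_s)), by = "time_s")
  }
  handling <- events[events$kind == "handling", , drop = FALSE]
  out <- data.frame(dive_id = dives$dive_id, has_slow = FALSE,
                    has_fast = FALSE, has_buzz = FALSE, has_handling = FALSE,
                    n_slow = 0L, n_fast = 0L, n_buzz = 0L, n_handling = 0L)
  for (k in seq_len(nrow(dives))) {
    s <- dives$start_s[k]; e <- dives$end_s[k]
    inside <- clicks$time_s >= s & clicks$time_s <= e
    if (any(inside)) {
      cc <- clicks$class[inside]
      out$n_slow[k] <- sum(cc == "slow")
      out$n_fast[k] <- sum(cc == "fast")
      out$n_buzz[k] <- sum(cc == "buzz")
    }
    out$n_handling[k] <- sum(handling$time_s >= s & handling$time_s <= e)
  }
  out$has_slow <- out$n_slow > 0L
  out$has_fast <- out$n_fast > 0L
  out$has_buzz <- out$n_buzz > 0L
  out$has_handling <- out$n_handling > 0L
  out
}

#' Cumulative acoustic searching time
#'
#' Sums the durations of dives during which only slow echolocation clicks
#' were detected (at least one slow click, no fast clicks, buzzes, or
#' handling sounds): the conservative acoustic definition of time spent
#' scanning the environment for prey.
#'
#' @param dives A `dive_table`.
#' @param summaries Per-dive acoustic summaries
#'   ([summarize_dive_acoustics()]).
#' @return Searching time in hours.
#' @export
searching_time <- function(dives, summaries) {
  m <- match(dives$dive_id, summaries$dive_id)
  s <- summaries[m, ]
  sel <- s$has_slow & !s$has_fast & !s$has_buzz & !s$has_handling
  sum((dives$end_s - dives$start_s)[sel]) / 3600
}

#' Cumulative travel/rest time
#'
#' Sums the durations of shallow dives (maximum depth below `depth_cutoff`)
#' during which no echolocation clicks of any class and no prey-capture or
#' handling sounds were produced, and that are not classified as
#' prey-capture dives.
#'
#' @param dives A `dive_table`; if it has a logical `capture` column, capture
#'   dives are excluded.
#' @param summaries Per-dive acoustic summaries.
#' @param depth_cutoff Maximum-depth cutoff in meters. Default 30.
#' @return Travel/rest time in hours.
#' @export
travel_rest_time <- function(dives, summaries, depth_cutoff = 30) {
  m <- match(dives$dive_id, summaries$dive_id)
  s <- summaries[m, ]
  silent <- !s$has_slow & !s$has_fast & !s$has_buzz & !s$has_handling
  sel <- dives$max_depth_m < depth_cutoff & silent
  if (!is.null(dives$capture)) sel <- sel & !dives$capture
  sum((dives$end_s - dives$start_s)[sel]) / 3600
}
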