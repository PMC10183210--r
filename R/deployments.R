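#' Week-of-year label for deployment grouping
#'
#' Deployments are grouped into calendar-week blocks for use as a random
#' intercept absorbing shared short-term environmental variation (notably
#' weekly variation in salmon availability). A week here is a block of seven
#' days counted from 1 January (day-of-year 1--7 is week 1, 8--14 is week 2,
#' and so on), crossed with the calendar year, e.g. `"2010 37"`. Labels are a
#' pure function of the date: the same date always yields the same label.
#'
#' @param when `Date`, `POSIXct`, or a character vector parseable as either.
#' @return Character vector of `"YYYY WW"` labels.
#' @examples
#' week_year(as.Date("2010-09-17"))
#' @export
week_year <- function(when) {
  if (is.character(when)) when <- as.POSIXct(when, tz = "UTC")
  lt <- as.POSIXlt(when, tz = "UTC")
  paste(lt$year + 1900L, lt$yday %/% 7L + 1L)
}

#' Read a deployment summary table
#'
#' Reads the per-deployment metadata CSV: one row per tag deployment with
#' population, sex, age, deployment duration, the number of prey-capture
#' dives, demographic status (calf for adult females, mother for adult
#' males), and cumulative acoustic search time. Empty cells are kept as
#' explicit missing values -- a blank searching-time cell (audio could not be
#' analyzed) is distinct from a recorded `0`.
#'
#' Demographic codings follow the field convention: in `calf_age`, a number
#' 0--3 is the estimated age of a living calf and `"N"` means no living calf;
#' in `mother_age`, a number is the age of a living mother and `"N"` means
#' the mother has died. Both are blank where not applicable (the column only
#' applies to adults of the relevant sex).
#'
#' @param path Path to a CSV file with columns `deployment_id`,
#'   `start_datetime` (ISO-8601), `population` (`NRKW`/`SRKW`), `sex`
#'   (`F`/`M`/`Unk`), `age`, `duration_h`, `n_capture_dives`, `calf_age`,
#'   `mother_age`, `searching_h`.
#' @return A `data.frame` of class `deployment_table` with parsed columns,
#'   factor demographic status columns (`calf_status`, `mother_status`),
#'   a logical `adult` flag (age >= 12), and a derived `week_year` label.
#' @seealso [validate_cohort()], [metrics_from_table()], [week_year()]
#' @export
read_deployment_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("deployment_id", "start_datetime", "population", "sex", "age",
                "duration_h", "n_capture_dives", "calf_age", "mother_age",
                "searching_h")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stop("deployment table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(raw$deployment_id))
    stop("duplicate deployment_id: ",
         paste(unique(raw$deployment_id[duplicated(raw$deployment_id)]),
               collapse = ", "))

  parse_row_error <- function(i, what)
    stop(sprintf("malformed deployment row %d: %s", i, what))

  start <- as.POSIXct(raw$start_datetime, tz = "UTC",
                      format = "%Y-%m-%d %H:%M:%S")
  age <- suppressWarnings(as.integer(raw$age))
  dur <- suppressWarnings(as.numeric(raw$duration_h))
  ncap <- suppressWarnings(as.integer(raw$n_capture_dives))
  for (i in seq_len(nrow(raw))) {
    if (is.na(start[i])) parse_row_error(i, "unparseable start_datetime")
    if (!raw$population[i] %in% c("NRKW", "SRKW"))
      parse_row_error(i, paste0("unknown population '", raw$population[i], "'"))
    if (!raw$sex[i] %in% c("F", "M", "Unk"))
      parse_row_error(i, paste0("unknown sex '", raw$sex[i], "'"))
    if (is.na(age[i]) || age[i] < 2L) parse_row_error(i, "age missing or < 2")
    if (is.na(dur[i]) || dur[i] <= 0) parse_row_error(i, "duration must be > 0")
    if (is.na(ncap[i]) || ncap[i] < 0L)
      parse_row_error(i, "n_capture_dives missing or negative")
  }

  adult <- age >= 12L
  female <- raw$sex == "F"
  male <- raw$sex == "M"

  calf_status <- rep("not_applicable", nrow(raw))
  calf_age <- rep(NA_real_, nrow(raw))
  has_calf_info <- adult & female & raw$calf_age != ""
  calf_status[has_calf_info & raw$calf_age == "N"] <- "no_calf"
  with_calf <- has_calf_info & raw$calf_age != "N"
  calf_status[with_calf] <- "with_calf"
  calf_age[with_calf] <- suppressWarnings(as.numeric(raw$calf_age[with_calf]))
  if (any(!is.na(calf_age) & (calf_age < 0 | calf_age > 3)))
    stop("calf_age outside 0-3 years")

  mother_status <- rep("not_applicable", nrow(raw))
  mother_age <- rep(NA_real_, nrow(raw))
  has_mother_info <- adult & male & raw$mother_age != ""
  mother_status[has_mother_info & raw$mother_age == "N"] <- "mother_dead"
  alive <- has_mother_info & raw$mother_age != "N"
  mother_status[alive] <- "mother_alive"
  mother_age[alive] <- suppressWarnings(as.numeric(raw$mother_age[alive]))

  searching_h <- suppressWarnings(as.numeric(raw$searching_h))
  searching_h[raw$searching_h == ""] <- NA_real_

  out <- data.frame(
    deployment_id = raw$deployment_id,
    start_datetime = start,
    population = factor(raw$population, levels = c("NRKW", "SRKW")),
    sex = factor(ifelse(raw$sex == "Unk", "unknown", raw$sex),
                 levels = c("F", "M", "unknown")),
    age = age,
    duration_h = dur,
    n_capture_dives = ncap,
    adult = adult,
    calf_status = factor(calf_status,
                         levels = c("no_calf", "with_calf", "not_applicable")),
    calf_age = calf_age,
    mother_status = factor(mother_status,
                           levels = c("mother_alive", "mother_dead",
                                      "not_applicable")),
    mother_age = mother_age,
    searching_h = searching_h,
    week_year = week_year(start),
    stringsAsFactors = FALSE
  )
  class(out) <- c("deployment_table", "data.frame")
  out
}

#' Write a deployment table back to CSV
#'
#' Inverse of [read_deployment_table()]: writes the original CSV schema so
#' that a write/read round trip reproduces the records exactly.
#'
#' @param records A `deployment_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_deployment_table <- function(records, path) {
  fmt_num <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE))
  calf <- character(nrow(records))
  calf[records$calf_status == "no_calf"] <- "N"
  wc <- records$calf_status == "with_calf"
  calf[wc] <- fmt_num(records$calf_age[wc])
  mom <- character(nrow(records))
  mom[records$mother_status == "mother_dead"] <- "N"
  ma <- records$mother_status == "mother_alive"
  mom[ma] <- fmt_num(records$mother_age[ma])
  out <- data.frame(
    deployment_id = records$deployment_id,
    start_datetime = format(records$start_datetime, "%Y-%m-%d %H:%M:%S",
                            tz = "UTC"),
    population = as.character(records$population),
    sex = ifelse(records$sex == "unknown", "Unk", as.character(records$sex)),
    age = records$age,
    duration_h = sprintf("%.2f", records$duration_h),
    n_capture_dives = records$n_capture_dives,
    calf_age = calf,
    mother_age = mom,
    searching_h = fmt_num(records$searching_h),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Packaged deployment summary table
#'
#' Loads the deployment summary shipped with the package: 52 DTAG
#' deployments on Northern and Southern Resident killer whales (2009--2014)
#' with per-deployment durations, prey-capture dive counts, demographic
#' status, and acoustic searching time. This table anchors the package's
#' worked examples and regression tests.
#'
#' @return A `deployment_table`; see [read_deployment_table()].
#' @examples
#' d <- dtag_deployments()
#' nrow(d)   # 52
#' @export
dtag_deployments <- function() {
  read_deployment_table(system.file("extdata", "table1_deployments.csv",
                                    package = "orcaforage", mustWork = TRUE))
}

#' Summarize cohort composition
#'
#' Report-only check of a deployment table: population-by-sex counts, adult
#' subsets, and demographic completeness. Never fails; the output is meant to
#' be compared against the expected cohort structure before model fitting.
#'
#' @param records A `deployment_table`.
#' @return A list of class `cohort_validation`: `n`, `by_population_sex`
#'   (population x sex count table), `n_adult_females`,
#'   `n_adult_females_with_calf_info`, `n_adult_males`,
#'   `n_adult_males_with_mother_info`, `n_known_sex`, `total_hours`,
#'   `hours_by_population`.
#' @export
validate_cohort <- function(records) {
  if (nrow(records) == 0L) {
    tab <- table(factor(character(), levels = c("NRKW", "SRKW")),
                 factor(character(), levels = c("F", "M", "unknown")))
  } else {
    tab <- table(records$population, records$sex)
  }
  af <- records$adult & records$sex == "F"
  am <- records$adult & records$sex == "M"
  out <- list(
    n = nrow(records),
    by_population_sex = tab,
    n_adult_females = sum(af),
    n_adult_females_with_calf_info =
      sum(af & records$calf_status != "not_applicable"),
    n_adult_males = sum(am),
    n_adult_males_with_mother_info =
      sum(am & records$mother_status != "not_applicable"),
    n_known_sex = sum(records$sex != "unknown"),
    total_hours = sum(records$duration_h),
    hours_by_population = tapply(records$duration_h, records$population, sum,
                                 default = 0)
  )
  class(out) <- "cohort_validation"
  out
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort of", x$n, "deployments,",
      sprintf("%.1f h total", x$total_hours), "\n")
  print(x$by_population_sex)
  cat("Adult females:", x$n_adult_females,
      sprintf("(%d with calf status)", x$n_adult_females_with_calf_info), "\n")
  cat("Adult males:  ", x$n_adult_males,
      sprintf("(%d with mother status)", x$n_adult_males_with_mother_info),
      "\n")
  invisible(x)
}
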