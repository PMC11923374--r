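#' @importFrom rlang .data
#' @importFrom stats median quantile sd qf qnorm cor complete.cases rnorm rpois runif rlnorm
NULL

# Parse clock times given as "HH:MM" or integer minutes since midnight.
# Returns list(min = integer with NA for missing/unparseable,
#              invalid = logical, TRUE where a value parsed but is outside
#              [0, 1439] (e.g. "24:10"), unparseable = logical).
parse_clock_time <- function(x) {
  x <- trimws(as.character(x))
  n <- length(x)
  min <- rep(NA_integer_, n)
  unparseable <- rep(FALSE, n)
  blank <- is.na(x) | x == "" | toupper(x) == "NA"
  hm <- grepl("^\\d{1,2}[:.]\\d{2}$", x) & !blank
  if (any(hm)) {
    parts <- strsplit(x[hm], "[:.]")
    min[hm] <- vapply(parts, function(p) {
      as.integer(p[1]) * 60L + as.integer(p[2])
    }, integer(1))
  }
  num <- !hm & !blank & grepl("^-?\\d+$", x)
  min[num] <- as.integer(x[num])
  unparseable[!hm & !num & !blank] <- TRUE
  invalid <- !is.na(min) & (min < 0L | min > 1439L)
  list(min = min, invalid = invalid, unparseable = unparseable, blank = blank)
}

new_validation_report <- function(n_input, n_missing, n_invalid, n_partial) {
  structure(
    list(
      n_input = as.integer(n_input),
      n_dropped_missing_time = as.integer(n_missing),
      n_dropped_invalid_time = as.integer(n_invalid),
      n_dropped_partial = as.integer(n_partial),
      n_valid = as.integer(n_input - n_missing - n_invalid - n_partial)
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Diary cohort validation\n")
  cat("  participants in:        ", x$n_input, "\n")
  cat("  dropped, missing time:  ", x$n_dropped_missing_time, "\n")
  cat("  dropped, invalid time:  ", x$n_dropped_invalid_time, "\n")
  cat("  dropped, partial data:  ", x$n_dropped_partial, "\n")
  cat("  valid:                  ", x$n_valid, "\n")
  invisible(x)
}

#' Serialise a validation report as JSON
#'
#' @param report A `validation_report` from [validate_cohort()].
#' @param path Optional file path; when supplied the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
validation_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Parse diet-diary records from delimited text
#'
#' Reads long-format diary data: one row per food entry with columns
#' `participant_id`, `day`, `time`, `grams`, `kcal` and optionally `label`
#' and `slot` (a legacy broad meal-slot code recorded independently of the
#' clock time; used only by [validate_cohort()]). Times may be `HH:MM` 24-h
#' clock strings or integer minutes since midnight. A missing time is kept as
#' `NA` and an out-of-range time (e.g. `24:10`) is kept as parsed, so that
#' the cohort-level exclusion rules can observe and count them; neither
#' survives [validate_cohort()].
#'
#' Structurally malformed rows (unparseable time string, negative grams or
#' kcal, missing id or day) are dropped at parse and reported with their line
#' numbers; a missing mandatory column is a hard error.
#'
#' @param source Path to a CSV file, or a character vector of CSV lines.
#' @return A list with `records` (tibble sorted by participant, day, time,
#'   one row per retained food entry) and `problems` (tibble of dropped rows:
#'   `line`, `reason`).
#' @examples
#' txt <- c("participant_id,day,time,grams,kcal",
#'          "P1,1,08:00,100,150",
#'          "P1,1,12:30,250,300")
#' parse_diaries(txt)$records
#' @export
parse_diaries <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                           colClasses = "character", strip.white = TRUE)
  } else {
    raw <- utils::read.csv(text = paste(source, collapse = "\n"),
                           stringsAsFactors = FALSE,
                           colClasses = "character", strip.white = TRUE)
  }
  required <- c("participant_id", "day", "time", "grams", "kcal")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("diary input is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  empty_records <- tibble::tibble(
    participant_id = character(0), day = integer(0), time_min = integer(0),
    grams = numeric(0), kcal = numeric(0), label = character(0),
    slot_recorded = character(0)
  )
  if (n == 0) {
    return(list(records = empty_records,
                problems = tibble::tibble(line = integer(0), reason = character(0))))
  }
  tm <- parse_clock_time(raw$time)
  day <- suppressWarnings(as.integer(raw$day))
  grams <- suppressWarnings(as.numeric(raw$grams))
  kcal <- suppressWarnings(as.numeric(raw$kcal))

  reason <- rep(NA_character_, n)
  reason[is.na(raw$participant_id) | trimws(raw$participant_id) == ""] <- "missing participant_id"
  reason[is.na(reason) & (is.na(day) | day < 1)] <- "bad day index"
  reason[is.na(reason) & tm$unparseable] <- "unparseable time"
  reason[is.na(reason) & (is.na(grams) | grams < 0)] <- "bad grams"
  reason[is.na(reason) & (is.na(kcal) | kcal < 0)] <- "bad kcal"
  keep <- is.na(reason)

  # +1 for the header row, so `line` matches the source file
  problems <- tibble::tibble(line = which(!keep) + 1L, reason = reason[!keep])

  records <- tibble::tibble(
    participant_id = as.character(raw$participant_id)[keep],
    day = day[keep],
    time_min = tm$min[keep],
    grams = grams[keep],
    kcal = kcal[keep],
    label = if ("label" %in% names(raw)) as.character(raw$label)[keep] else NA_character_,
    slot_recorded = if ("slot" %in% names(raw)) as.character(raw$slot)[keep] else NA_character_
  )
  records <- dplyr::arrange(records, .data$participant_id, .data$day, .data$time_min)
  list(records = records, problems = problems)
}

#' Apply the cohort validity and exclusion rules
#'
#' Reproduces the exclusion cascade used when precise eating times are
#' retro-coded onto diaries whose entries already carry broad meal-slot
#' codes. A participant is dropped entirely (never a single day) when:
#'
#' 1. any record's precise time is missing (`n_dropped_missing_time`);
#' 2. otherwise, any record's time falls outside 00:00--23:59
#'    (`n_dropped_invalid_time`);
#' 3. otherwise, on any diary day the number of distinct valid precise times
#'    is smaller than the number of distinct occupied meal slots among that
#'    day's records (`n_dropped_partial`) -- the situation in which the
#'    precise record cannot account for every broad occasion, making a
#'    method comparison impossible.
#'
#' Occupied slots in rule 3 use the independently recorded `slot_recorded`
#' column where present, falling back to the slot derived from the time.
#' Each dropped participant is counted under the first rule that fires.
#'
#' @param records Record tibble from [parse_diaries()].
#' @param scheme Slot scheme for deriving slots from times.
#' @return A list with `records` (retained participants only) and `report`
#'   (a `validation_report`).
#' @export
validate_cohort <- function(records, scheme = meal_slot_scheme()) {
  scheme <- validate_slot_scheme(scheme)
  ids <- unique(records$participant_id)
  n_input <- length(ids)
  if (n_input == 0) {
    return(list(records = records, report = new_validation_report(0, 0, 0, 0)))
  }

  per_rec <- dplyr::mutate(
    records,
    time_missing = is.na(.data$time_min),
    time_invalid = !is.na(.data$time_min) &
      (.data$time_min < 0L | .data$time_min > 1439L),
    slot_occ = dplyr::if_else(
      !is.na(.data$slot_recorded) & .data$slot_recorded %in% scheme$slot,
      .data$slot_recorded,
      dplyr::if_else(!.data$time_missing & !.data$time_invalid,
                     assign_slot(pmin(pmax(dplyr::coalesce(.data$time_min, 0L), 0L), 1439L),
                                 scheme),
                     NA_character_)
    )
  )

  by_day <- dplyr::summarise(
    dplyr::group_by(per_rec, .data$participant_id, .data$day),
    n_times = dplyr::n_distinct(.data$time_min[!.data$time_missing & !.data$time_invalid]),
    n_slots = dplyr::n_distinct(.data$slot_occ[!is.na(.data$slot_occ)]),
    any_missing = any(.data$time_missing),
    any_invalid = any(.data$time_invalid),
    .groups = "drop"
  )
  by_id <- dplyr::summarise(
    dplyr::group_by(by_day, .data$participant_id),
    any_missing = any(.data$any_missing),
    any_invalid = any(.data$any_invalid),
    any_partial = any(.data$n_times < .data$n_slots),
    .groups = "drop"
  )
  status <- dplyr::mutate(
    by_id,
    status = dplyr::case_when(
      .data$any_missing ~ "missing",
      .data$any_invalid ~ "invalid",
      .data$any_partial ~ "partial",
      TRUE ~ "valid"
    )
  )
  report <- new_validation_report(
    n_input = n_input,
    n_missing = sum(status$status == "missing"),
    n_invalid = sum(status$status == "invalid"),
    n_partial = sum(status$status == "partial")
  )
  keep_ids <- status$participant_id[status$status == "valid"]
  kept <- dplyr::filter(records, .data$participant_id %in% keep_ids)
  list(records = kept, report = report)
}
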