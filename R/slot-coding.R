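#' The seven-slot broad meal-period scheme
#'
#' Diet-diary entry systems used by several UK cohorts coded the time of each
#' food entry into one of seven fixed meal slots rather than an exact clock
#' time. Each slot spans an inclusive range of minutes since midnight and
#' carries a single representative clock time used whenever a broad eating
#' occasion needs a numeric timestamp.
#'
#' The default scheme is the historical coding frame reproduced verbatim,
#' including its two quirks: the Mid-afternoon slot (14:30--16:59) is
#' represented by 17:00, which is the *start* of the next slot, and the
#' Evening slot (17:00--19:29) is represented by 20:00, which lies outside
#' the slot altogether. These representations are deliberate: they are what
#' the legacy coding documents printed, not interval midpoints, and the
#' arithmetic of broad timing variables depends on using them as-is.
#'
#' @return A tibble with columns `slot` (character), `start_min`, `end_min`
#'   (inclusive minute bounds) and `rep_min` (representative minute), one row
#'   per slot in clock order.
#' @examples
#' meal_slot_scheme()
#' @export
meal_slot_scheme <- function() {
  tibble::tibble(
    slot      = c("Overnight", "Breakfast", "Mid-morning", "Lunch",
                  "Mid-afternoon", "Evening", "Late-evening"),
    start_min = c(0L,   420L, 600L, 720L, 870L,  1020L, 1170L),
    end_min   = c(419L, 599L, 719L, 869L, 1019L, 1169L, 1439L),
    rep_min   = c(360L, 480L, 660L, 780L, 1020L, 1200L, 1320L)
  )
}

#' Validate a meal-slot scheme
#'
#' Checks that a candidate scheme is a complete, non-overlapping partition of
#' the day (minutes 0..1439) with inclusive bounds, unique slot names and
#' in-range representative times. Used on user-supplied schemes before they
#' replace the default; the default scheme passes by construction.
#'
#' @param scheme A data frame with columns `slot`, `start_min`, `end_min`,
#'   `rep_min`.
#' @return The scheme, invisibly, ordered by `start_min`; errors otherwise.
#' @export
validate_slot_scheme <- function(scheme) {
  required <- c("slot", "start_min", "end_min", "rep_min")
  missing_cols <- setdiff(required, names(scheme))
  if (length(missing_cols) > 0) {
    stop("slot scheme is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  scheme <- dplyr::arrange(tibble::as_tibble(scheme), .data$start_min)
  if (anyDuplicated(scheme$slot)) {
    stop("slot names must be unique", call. = FALSE)
  }
  if (scheme$start_min[1] != 0L || scheme$end_min[nrow(scheme)] != 1439L) {
    stop("slot scheme must cover minutes 0 through 1439", call. = FALSE)
  }
  if (any(scheme$end_min < scheme$start_min)) {
    stop("each slot must satisfy start_min <= end_min", call. = FALSE)
  }
  if (nrow(scheme) > 1) {
    gaps <- scheme$start_min[-1] - scheme$end_min[-nrow(scheme)]
    if (any(gaps != 1L)) {
      stop("slots must tile the day with no gaps or overlaps", call. = FALSE)
    }
  }
  if (any(scheme$rep_min < 0L | scheme$rep_min > 1439L)) {
    stop("representative times must lie in [0, 1439]", call. = FALSE)
  }
  invisible(scheme)
}

#' Assign clock times to meal slots
#'
#' Maps minutes since midnight to the slot whose inclusive range contains
#' them. Total on 0..1439; any other value is an error, since validated diary
#' records cannot carry one.
#'
#' @param time_min Integer vector of minutes since midnight (0..1439).
#' @param scheme A slot scheme as returned by [meal_slot_scheme()].
#' @return Character vector of slot names, same length as `time_min`.
#' @examples
#' assign_slot(c(0, 480, 810, 1439))
#' @export
assign_slot <- function(time_min, scheme = meal_slot_scheme()) {
  scheme <- validate_slot_scheme(scheme)
  if (length(time_min) == 0) return(character(0))
  bad <- !is.finite(time_min) | time_min < 0 | time_min > 1439
  if (any(bad)) {
    stop("time_min out of range [0, 1439]: ",
         paste(utils::head(time_min[bad], 5), collapse = ", "), call. = FALSE)
  }
  idx <- findInterval(time_min, scheme$start_min)
  scheme$slot[idx]
}

#' Representative clock time of a meal slot
#'
#' @param slot Character vector of slot names.
#' @param scheme A slot scheme as returned by [meal_slot_scheme()].
#' @return Integer vector of representative minutes since midnight.
#' @examples
#' slot_representation("Lunch")  # 780, i.e. 13:00
#' @export
slot_representation <- function(slot, scheme = meal_slot_scheme()) {
  scheme <- validate_slot_scheme(scheme)
  idx <- match(slot, scheme$slot)
  if (anyNA(idx)) {
    stop("unknown slot name(s): ",
         paste(unique(slot[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  scheme$rep_min[idx]
}

#' Read a meal-slot scheme from a plain-text config file
#'
#' Accepts a CSV with header `slot,start,end,representation`; the three time
#' columns may be given as `HH:MM` clock strings or integer minutes. The
#' scheme is validated for partition completeness before being returned, so a
#' malformed file fails loudly rather than silently miscoding times.
#'
#' @param path Path to the CSV file.
#' @return A validated scheme tibble.
#' @export
read_slot_scheme <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("slot", "start", "end", "representation")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("slot scheme file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  to_min <- function(x) {
    out <- parse_clock_time(x)
    if (anyNA(out$min) || any(out$invalid)) {
      stop("unparseable or out-of-range time in slot scheme file", call. = FALSE)
    }
    out$min
  }
  scheme <- tibble::tibble(
    slot      = as.character(raw$slot),
    start_min = to_min(raw$start),
    end_min   = to_min(raw$end),
    rep_min   = to_min(raw$representation)
  )
  validate_slot_scheme(scheme)
  dplyr::arrange(scheme, .data$start_min)
}

#' Format minutes since midnight as HH:MM
#'
#' @param x Numeric vector of minutes since midnight; values are rounded to
#'   the nearest minute. `NA` formats as `NA`.
#' @return Character vector like `"08:04"`.
#' @examples
#' format_clock(c(484, 1209.6))
#' @export
format_clock <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  m <- as.integer(round(x[ok]))
  out[ok] <- sprintf("%02d:%02d", m %/% 60L, m %% 60L)
  out
}
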