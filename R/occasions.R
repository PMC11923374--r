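#' Build eating occasions from validated diary records
#'
#' An eating occasion (EO) groups the food records of one participant-day
#' under one of two timing definitions:
#'
#' * **precise** -- one EO per distinct recorded clock time; the EO keeps
#'   that exact time and is labelled with the meal slot the time falls in;
#' * **broad** -- one EO per occupied meal slot; the EO's timestamp is the
#'   slot's representative clock time, and `n_precise_members` records how
#'   many distinct precise times it absorbed.
#'
#' Grams and kcal are summed over constituent records under both
#' definitions, so day totals are conserved exactly; the broad definition
#' can only merge occasions, never split them, hence per day the broad EO
#' count is at most the precise count and never exceeds the number of slots.
#'
#' @param records Validated record tibble (all times present and in range),
#'   as returned by [validate_cohort()].
#' @param method `"precise"` or `"broad"`.
#' @param scheme Slot scheme; see [meal_slot_scheme()].
#' @return A tibble with one row per EO: `participant_id`, `day`, `method`,
#'   `time_min`, `slot`, `grams`, `kcal`, `n_records`, `n_precise_members`,
#'   sorted by participant, day and time.
#' @examples
#' rec <- tibble::tibble(participant_id = "P1", day = 1L,
#'                       time_min = c(1030L, 1140L), grams = c(300, 50),
#'                       kcal = c(350, 90))
#' build_occasions(rec, "precise")
#' build_occasions(rec, "broad")   # one Evening EO at 20:00
#' @export
build_occasions <- function(records, method = c("precise", "broad"),
                            scheme = meal_slot_scheme()) {
  method <- match.arg(method)
  scheme <- validate_slot_scheme(scheme)
  if (nrow(records) == 0) {
    stop("cannot build eating occasions from zero records", call. = FALSE)
  }
  if (anyNA(records$time_min) ||
      any(records$time_min < 0L | records$time_min > 1439L)) {
    stop("records must be validated first: all times in [0, 1439]", call. = FALSE)
  }
  rec <- dplyr::mutate(records, slot = assign_slot(.data$time_min, scheme))
  if (method == "precise") {
    eos <- dplyr::summarise(
      dplyr::group_by(rec, .data$participant_id, .data$day, .data$time_min),
      slot = .data$slot[1],
      grams = sum(.data$grams),
      kcal = sum(.data$kcal),
      n_records = dplyr::n(),
      .groups = "drop"
    )
    eos$n_precise_members <- 1L
  } else {
    eos <- dplyr::summarise(
      dplyr::group_by(rec, .data$participant_id, .data$day, .data$slot),
      grams = sum(.data$grams),
      kcal = sum(.data$kcal),
      n_records = dplyr::n(),
      n_precise_members = dplyr::n_distinct(.data$time_min),
      .groups = "drop"
    )
    eos$time_min <- slot_representation(eos$slot, scheme)
  }
  eos$method <- method
  eos <- eos[, c("participant_id", "day", "method", "time_min", "slot",
                 "grams", "kcal", "n_records", "n_precise_members")]
  dplyr::arrange(eos, .data$participant_id, .data$day, .data$time_min)
}

#' Build precise and broad occasions together
#'
#' Convenience wrapper returning both EO tables stacked, which is the shape
#' the downstream architecture and composition summaries consume.
#'
#' @inheritParams build_occasions
#' @return A tibble as from [build_occasions()], with both methods present.
#' @export
build_all_occasions <- function(records, scheme = meal_slot_scheme()) {
  dplyr::bind_rows(
    build_occasions(records, "precise", scheme),
    build_occasions(records, "broad", scheme)
  )
}
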