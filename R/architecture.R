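arch_vars <- c("frequency", "size_g", "size_kcal", "first_min", "last_min",
               "window_min", "interval_min")

#' Per-day eating-architecture variables
#'
#' For each participant-day-method group of an EO table, computes the seven
#' architecture variables:
#'
#' * `frequency` -- number of EOs that day;
#' * `size_g`, `size_kcal` -- mean grams / kcal per EO;
#' * `first_min`, `last_min` -- clock time (minutes since midnight) of the
#'   first and last EO;
#' * `window_min` -- eating window, `last_min - first_min` (0 on a
#'   single-EO day);
#' * `interval_min` -- mean gap between consecutive EOs; `NA` when the day
#'   has a single EO, since no gap exists. For sorted times the consecutive
#'   gaps telescope, so this equals `window_min / (frequency - 1)`.
#'
#' @param eos EO tibble from [build_occasions()] or [build_all_occasions()].
#' @return A tibble, one row per participant x day x method.
#' @export
day_architecture <- function(eos) {
  if (nrow(eos) == 0) stop("no eating occasions supplied", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(eos, .data$participant_id, .data$method, .data$day),
    frequency = dplyr::n(),
    size_g = mean(.data$grams),
    size_kcal = mean(.data$kcal),
    first_min = min(.data$time_min),
    last_min = max(.data$time_min),
    window_min = max(.data$time_min) - min(.data$time_min),
    interval_min = dplyr::if_else(
      dplyr::n() >= 2L,
      (max(.data$time_min) - min(.data$time_min)) / (dplyr::n() - 1),
      NA_real_
    ),
    .groups = "drop"
  )
}

#' Per-participant eating architecture
#'
#' Averages the daily architecture variables over all recorded days with
#' equal weight. The intermeal interval is averaged over the days where it
#' is defined (at least two EOs); it is `NA` for a participant none of whose
#' days has two EOs.
#'
#' @param days Daily architecture tibble from [day_architecture()].
#' @param pooled_interval When `TRUE`, pool all consecutive gaps across a
#'   participant's days (total window over total gap count) instead of
#'   averaging the per-day mean gap; a sensitivity option, since both
#'   readings of "mean intermeal interval" occur in practice.
#' @return A tibble, one row per participant x method, with the seven
#'   variables plus `n_days`.
#' @export
participant_architecture <- function(days, pooled_interval = FALSE) {
  if (nrow(days) == 0) stop("no daily architecture rows supplied", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(days, .data$participant_id, .data$method),
    n_days = dplyr::n(),
    frequency = mean(.data$frequency),
    size_g = mean(.data$size_g),
    size_kcal = mean(.data$size_kcal),
    first_min = mean(.data$first_min),
    last_min = mean(.data$last_min),
    window_min = mean(.data$window_min),
    interval_min = if (all(is.na(.data$interval_min))) NA_real_
                   else if (pooled_interval)
                     sum(.data$window_min[.data$frequency >= 2]) /
                       sum(.data$frequency[.data$frequency >= 2] - 1)
                   else mean(.data$interval_min, na.rm = TRUE),
    .groups = "drop"
  )
}

#' Eating architecture for a validated cohort, both methods
#'
#' One-call pipeline from validated records to the per-participant
#' architecture table under both timing definitions.
#'
#' @inheritParams build_occasions
#' @return A tibble as from [participant_architecture()].
#' @export
eating_architecture <- function(records, scheme = meal_slot_scheme()) {
  participant_architecture(day_architecture(build_all_occasions(records, scheme)))
}

#' Cohort summary of eating architecture
#'
#' Mean and SD of each architecture variable over participants, by method,
#' with human-readable renderings: clock-time variables as `HH:MM` and
#' durations as hours and minutes. The interval mean is over participants
#' for whom it is defined.
#'
#' @param participants Per-participant tibble from
#'   [participant_architecture()] or [eating_architecture()].
#' @return A tibble with one row per variable x method: `variable`,
#'   `method`, `n`, `mean`, `sd`, `mean_fmt`, `sd_fmt`.
#' @export
cohort_summary <- function(participants) {
  if (nrow(participants) == 0) stop("empty cohort", call. = FALSE)
  long <- tidyr::pivot_longer(
    participants[, c("participant_id", "method", arch_vars)],
    dplyr::all_of(arch_vars),
    names_to = "variable", values_to = "value"
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$variable, .data$method),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    # a one-participant cohort has zero between-participant spread
    sd = dplyr::if_else(sum(!is.na(.data$value)) > 1,
                        sd(.data$value, na.rm = TRUE), 0),
    .groups = "drop"
  )
  fmt_duration <- function(x) {
    m <- as.integer(round(x))
    sprintf("%d, %d", m %/% 60L, m %% 60L)  # "h, min"
  }
  out$mean_fmt <- dplyr::case_when(
    out$variable %in% c("first_min", "last_min") ~ format_clock(out$mean),
    out$variable %in% c("window_min", "interval_min") ~ fmt_duration(out$mean),
    TRUE ~ sprintf("%.1f", out$mean)
  )
  out$sd_fmt <- dplyr::case_when(
    out$variable %in% c("first_min", "last_min", "window_min", "interval_min") ~
      fmt_duration(out$sd),
    TRUE ~ sprintf("%.1f", out$sd)
  )
  out$variable <- factor(out$variable, levels = arch_vars)
  dplyr::arrange(out, .data$variable, .data$method)
}
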