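#' Gaps between precise occasions merged into one broad occasion
#'
#' Whenever a broad (meal-slot) occasion absorbs two or more distinct
#' precise eating times, the times it merged are separated by real gaps
#' that the broad coding erases. This summarises those gaps: for every
#' broad EO with at least two precise members, the consecutive sorted
#' differences between member times are collected, the per-EO mean gap is
#' taken, and the distribution of mean gaps is summarised per slot.
#'
#' @param precise_eos Precise EO tibble from
#'   `build_occasions(records, "precise")`.
#' @return A list with:
#'   * `gaps` -- one row per consecutive within-slot gap: `participant_id`,
#'     `day`, `slot`, `gap_min`;
#'   * `eo_means` -- one row per multi-member broad EO with its mean gap
#'     and member count;
#'   * `by_slot` -- per-slot summaries of the mean gaps: `n_multi_eos`,
#'     `median`, `q25`, `q75`, `p10`, `p90`.
#' @export
within_slot_gaps <- function(precise_eos) {
  pe <- precise_eos[precise_eos$method == "precise", , drop = FALSE]
  grp <- dplyr::group_by(pe, .data$participant_id, .data$day, .data$slot)
  eo_means <- dplyr::summarise(
    grp,
    n_members = dplyr::n_distinct(.data$time_min),
    mean_gap = if (dplyr::n_distinct(.data$time_min) >= 2)
      mean(diff(sort(unique(.data$time_min)))) else NA_real_,
    .groups = "drop"
  )
  eo_means <- eo_means[eo_means$n_members >= 2, , drop = FALSE]
  gaps <- dplyr::reframe(
    grp,
    gap_min = if (dplyr::n_distinct(.data$time_min) >= 2)
      diff(sort(unique(.data$time_min))) else numeric(0)
  )
  by_slot <- dplyr::summarise(
    dplyr::group_by(eo_means, .data$slot),
    n_multi_eos = dplyr::n(),
    median = median(.data$mean_gap),
    q25 = quantile(.data$mean_gap, 0.25, names = FALSE),
    q75 = quantile(.data$mean_gap, 0.75, names = FALSE),
    p10 = quantile(.data$mean_gap, 0.10, names = FALSE),
    p90 = quantile(.data$mean_gap, 0.90, names = FALSE),
    .groups = "drop"
  )
  list(gaps = gaps, eo_means = eo_means, by_slot = by_slot)
}

#' Fractions of within-slot gaps around separation cutoffs
#'
#' The eating-occasion literature separates occasions with minimum-gap
#' rules, most commonly 15 or 60 minutes. For each slot this reports the
#' fraction of within-slot gaps at or above each cutoff and at or below it
#' (both inclusive, so a gap exactly at the cutoff counts on both sides),
#' together with the underlying counts.
#'
#' @param gaps Gap tibble (`slot`, `gap_min`), e.g. the `gaps` element of
#'   [within_slot_gaps()].
#' @param cutoffs Numeric vector of cutoffs in minutes (default 15 and 60).
#' @return A tibble: `slot`, `cutoff`, `n_gaps`, `n_ge`, `frac_ge`,
#'   `n_le`, `frac_le`.
#' @export
cutoff_fractions <- function(gaps, cutoffs = c(15, 60)) {
  grid <- tidyr::expand_grid(slot = unique(gaps$slot), cutoff = cutoffs)
  purrr::pmap_dfr(grid, function(slot, cutoff) {
    g <- gaps$gap_min[gaps$slot == slot]
    tibble::tibble(
      slot = slot, cutoff = cutoff, n_gaps = length(g),
      n_ge = sum(g >= cutoff), frac_ge = mean(g >= cutoff),
      n_le = sum(g <= cutoff), frac_le = mean(g <= cutoff)
    )
  })
}

#' Per-slot occasion size by method
#'
#' Mean grams per EO within each meal slot, separately for the precise and
#' broad definitions, with a normal-approximation 95% CI
#' (mean +/- 1.96 SE). Slots holding fewer than two EOs under a method get
#' an undefined (NA) CI. Because the broad definition pools every record in
#' a slot into one EO, its per-slot means sit at or above the precise ones
#' wherever merging occurs.
#'
#' @param eos EO tibble containing both methods ([build_all_occasions()]).
#' @return A tibble: `slot`, `method`, `n_eos`, `mean_g`, `ci_low`,
#'   `ci_high`.
#' @export
slot_size_summary <- function(eos) {
  out <- dplyr::summarise(
    dplyr::group_by(eos, .data$slot, .data$method),
    n_eos = dplyr::n(),
    mean_g = mean(.data$grams),
    se = if (dplyr::n() >= 2) sd(.data$grams) / sqrt(dplyr::n()) else NA_real_,
    .groups = "drop"
  )
  out$ci_low <- out$mean_g - 1.96 * out$se
  out$ci_high <- out$mean_g + 1.96 * out$se
  out$se <- NULL
  out
}

#' Per-slot precise-occasion frequency
#'
#' How many distinct precise occasions fall in each meal slot on the days
#' the slot is occupied: for each participant and slot, the mean precise EO
#' count per occupied day (or per recorded day when `per_day = TRUE`), then
#' the median and IQR of those per-participant means across the cohort.
#' The broad counterpart of this quantity is identically 1 per occupied
#' slot by construction.
#'
#' @param precise_eos Precise EO tibble.
#' @param per_day When `TRUE`, divide by all recorded days instead of only
#'   the days on which the slot was occupied.
#' @return A tibble: `slot`, `n_participants`, `median`, `q25`, `q75`.
#' @export
slot_frequency_summary <- function(precise_eos, per_day = FALSE) {
  pe <- precise_eos[precise_eos$method == "precise", , drop = FALSE]
  n_days_tbl <- dplyr::summarise(
    dplyr::group_by(pe, .data$participant_id),
    n_days_recorded = dplyr::n_distinct(.data$day), .groups = "drop"
  )
  per_part <- dplyr::summarise(
    dplyr::group_by(pe, .data$participant_id, .data$slot),
    n_eos = dplyr::n(),
    n_days_occupied = dplyr::n_distinct(.data$day),
    .groups = "drop"
  )
  per_part <- dplyr::left_join(per_part, n_days_tbl, by = "participant_id")
  per_part$mean_per_day <- if (per_day) {
    per_part$n_eos / per_part$n_days_recorded
  } else {
    per_part$n_eos / per_part$n_days_occupied
  }
  dplyr::summarise(
    dplyr::group_by(per_part, .data$slot),
    n_participants = dplyr::n(),
    median = median(.data$mean_per_day),
    q25 = quantile(.data$mean_per_day, 0.25, names = FALSE),
    q75 = quantile(.data$mean_per_day, 0.75, names = FALSE),
    .groups = "drop"
  )
}
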