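prec_eos <- function(times, id = "P1", day = 1L, grams = 100) {
  tibble::tibble(participant_id = id, day = day, method = "precise",
                 time_min = as.integer(times), slot = assign_slot(times),
                 grams = grams, kcal = grams * 1.5,
                 n_records = 1L, n_precise_members = 1L)
}

test_that("within-slot gaps are consecutive sorted differences of member times", {
  # 17:00, 17:30, 19:00 all sit in the Evening slot
  eos <- prec_eos(c(1020, 1050, 1140))
  res <- within_slot_gaps(eos)
  expect_equal(res$gaps$gap_min, c(30, 90))
  expect_equal(res$eo_means$mean_gap, 60)
  expect_equal(res$eo_means$n_members, 3L)

  # a single-member slot contributes nothing
  res2 <- within_slot_gaps(prec_eos(c(480, 780)))
  expect_equal(nrow(res2$gaps), 0)
  expect_equal(nrow(res2$by_slot), 0)
})

test_that("per-slot gap percentiles match a longhand quantile oracle", {
  set.seed(41)
  # 20 multi-member Evening occasions across participants
  eos <- dplyr::bind_rows(lapply(1:20, function(i) {
    times <- sort(sample(1020:1169, sample(2:4, 1)))
    prec_eos(times, id = sprintf("P%02d", i))
  }))
  res <- within_slot_gaps(eos)
  mg <- res$eo_means$mean_gap[res$eo_means$slot == "Evening"]
  row <- res$by_slot[res$by_slot$slot == "Evening", ]
  expect_equal(row$n_multi_eos, length(mg))
  expect_equal(row$median, oracle_quantile7(mg, 0.5))
  expect_equal(row$q25, oracle_quantile7(mg, 0.25))
  expect_equal(row$q75, oracle_quantile7(mg, 0.75))
  expect_equal(row$p10, oracle_quantile7(mg, 0.10))
  expect_equal(row$p90, oracle_quantile7(mg, 0.90))

  # every gap fits inside the width of its slot
  scheme <- meal_slot_scheme()
  width <- scheme$end_min - scheme$start_min
  expect_true(all(res$gaps$gap_min <=
                    width[match(res$gaps$slot, scheme$slot)]))
})

test_that("cutoff fractions are inclusive on both sides and count-exact", {
  g <- tibble::tibble(slot = "Evening", gap_min = c(10, 20, 30))
  cf <- cutoff_fractions(g, cutoffs = 15)
  expect_equal(cf$frac_ge, 2 / 3)
  expect_equal(cf$n_ge, 2L)

  g1 <- tibble::tibble(slot = "Lunch", gap_min = 15)
  cf1 <- cutoff_fractions(g1, cutoffs = c(15, 60))
  expect_equal(cf1$frac_ge[cf1$cutoff == 15], 1)  # ties count as separate
  expect_equal(cf1$frac_le[cf1$cutoff == 60], 1)

  set.seed(42)
  g2 <- tibble::tibble(slot = sample(c("Lunch", "Evening"), 50, replace = TRUE),
                       gap_min = sample(1:120, 50, replace = TRUE))
  cf2 <- cutoff_fractions(g2)
  for (i in seq_len(nrow(cf2))) {
    gg <- g2$gap_min[g2$slot == cf2$slot[i]]
    expect_equal(cf2$frac_ge[i], sum(gg >= cf2$cutoff[i]) / length(gg))
    expect_equal(cf2$frac_le[i], sum(gg <= cf2$cutoff[i]) / length(gg))
  }
})

test_that("the merge deficit balances: precise - broad count = sum(members - 1)", {
  set.seed(43)
  for (i in 1:40) {
    rec <- random_day()
    pe <- build_occasions(rec, "precise")
    be <- build_occasions(rec, "broad")
    expect_equal(nrow(pe) - nrow(be), sum(be$n_precise_members - 1))
  }
})

test_that("slot size summaries agree across methods iff no merging happens", {
  rec <- tibble::tibble(participant_id = "P1", day = 1L,
                        time_min = c(480L, 780L, 1075L),
                        grams = c(120, 250, 320), kcal = c(150, 300, 400))
  eos <- build_all_occasions(rec)
  ss <- slot_size_summary(eos)
  for (s in unique(ss$slot)) {
    expect_equal(ss$mean_g[ss$slot == s & ss$method == "precise"],
                 ss$mean_g[ss$slot == s & ss$method == "broad"])
  }
  # single-EO cells carry an undefined CI
  expect_true(all(is.na(ss$ci_low)))

  # post-dinner snacking pushes the broad Evening mean above the precise one
  rec2 <- dplyr::bind_rows(lapply(1:15, function(i) tibble::tibble(
    participant_id = sprintf("P%02d", i), day = 1L,
    time_min = c(1075L, 1110L), grams = c(350, 60), kcal = c(420, 120)
  )))
  ss2 <- slot_size_summary(build_all_occasions(rec2))
  ev <- ss2[ss2$slot == "Evening", ]
  expect_gt(ev$mean_g[ev$method == "broad"],
            ev$mean_g[ev$method == "precise"])
  expect_equal(ev$mean_g[ev$method == "broad"], 410)
  expect_equal(ev$mean_g[ev$method == "precise"], mean(c(350, 60)))
  expect_false(any(is.na(ev$ci_low)))
})

test_that("per-slot frequency is 1 with degenerate IQR when nothing merges", {
  eos <- dplyr::bind_rows(
    prec_eos(c(480, 780), id = "A", day = 1L),
    prec_eos(c(490, 790), id = "A", day = 2L),
    prec_eos(c(480, 780), id = "B", day = 1L)
  )
  sf <- slot_frequency_summary(eos)
  expect_equal(sf$median, rep(1, nrow(sf)))
  expect_equal(sf$q25, rep(1, nrow(sf)))
  expect_equal(sf$q75, rep(1, nrow(sf)))

  # hand-checked mixed case: A has 3, 1 Evening EOs on its two days
  eos2 <- dplyr::bind_rows(
    prec_eos(c(1030, 1060, 1100), id = "A", day = 1L),
    prec_eos(1040, id = "A", day = 2L),
    prec_eos(c(1030, 1090), id = "B", day = 1L)
  )
  sf2 <- slot_frequency_summary(eos2)
  # A: (3 + 1) / 2 occupied days = 2; B: 2 / 1 = 2
  expect_equal(sf2$median[sf2$slot == "Evening"], 2)
  # per recorded-day variant divides by all days with any record
  sf2b <- slot_frequency_summary(eos2, per_day = TRUE)
  expect_equal(sf2b$median[sf2b$slot == "Evening"], 2)  # A: 4/2, B: 2/1
})
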