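test_that("consistency ICC is 1 for identical series and under constant offset", {
  x <- c(1, 2, 3, 4, 7)
  expect_equal(icc_consistency(x, x)$icc, 1)
  r <- icc_consistency(x, x + 5)
  expect_equal(r$icc, 1)
  expect_equal(r$ci_low, 1)
})

test_that("ICC matches longhand ANOVA sums of squares to 1e-10", {
  set.seed(31)
  x <- c(10.2, 11.5, 9.8, 14.1, 12.3, 8.7)
  y <- c(10.9, 11.1, 10.5, 13.2, 12.9, 9.4)
  got <- icc_consistency(x, y)
  want <- oracle_icc31(x, y)
  expect_equal(got$icc, want$icc, tolerance = 1e-10)
  expect_equal(got$ci_low, want$ci_low, tolerance = 1e-10)
  expect_equal(got$ci_high, want$ci_high, tolerance = 1e-10)
  expect_true(got$ci_low <= got$icc && got$icc <= got$ci_high)

  # and against the mean squares of a fitted two-way ANOVA
  dat <- data.frame(value = c(x, y),
                    subj = factor(rep(seq_along(x), 2)),
                    meth = factor(rep(c("p", "b"), each = length(x))))
  ms <- summary(stats::aov(value ~ subj + meth, data = dat))[[1]][, "Mean Sq"]
  ms_subj <- ms[1]; ms_err <- ms[3]
  expect_equal(got$icc, (ms_subj - ms_err) / (ms_subj + ms_err),
               tolerance = 1e-10)
})

test_that("ICC ignores a shift of one method but not a rescale", {
  set.seed(32)
  for (i in 1:10) {
    x <- rnorm(8); y <- x + rnorm(8, sd = 0.3)
    base <- icc_consistency(x, y)$icc
    expect_equal(icc_consistency(x, y + 3.7)$icc, base, tolerance = 1e-12)
  }
  x <- rnorm(20); y <- x + rnorm(20, sd = 0.1)
  expect_false(isTRUE(all.equal(icc_consistency(x, y)$icc,
                                icc_consistency(x, 3 * y)$icc)))
})

test_that("ICC rejects degenerate input", {
  expect_error(icc_consistency(c(1, 2), c(1, 2)), "at least 3")
  expect_error(icc_consistency(rep(2, 5), rep(2, 5)), "degenerate")
})

test_that("Bland-Altman reproduces the textbook formulas", {
  got <- bland_altman(c(5, 7), c(4, 5))
  expect_equal(got$mean_diff, 1.5)
  expect_equal(got$sd_diff, sqrt(0.5))
  expect_equal(got$loa_low, 1.5 - 1.96 * sqrt(0.5))
  expect_equal(got$loa_high, 1.5 + 1.96 * sqrt(0.5))

  set.seed(33)
  x <- rnorm(10, 50, 5); y <- x + rnorm(10, 1, 2)
  want <- oracle_bland_altman(x, y)
  got <- bland_altman(x, y)
  expect_equal(got$mean_diff, want$mean_diff, tolerance = 1e-10)
  expect_equal(got$loa_low, want$loa_low, tolerance = 1e-10)
  expect_equal(got$loa_high, want$loa_high, tolerance = 1e-10)
  expect_equal(got$pct_outside, want$pct_outside)
  expect_equal(got$points$diff, x - y)
  expect_equal(got$points$mean, (x + y) / 2)

  ident <- bland_altman(x, x)
  expect_equal(ident$mean_diff, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))
  expect_equal(ident$pct_outside, 0)

  offs <- bland_altman(x + 2.5, x)
  expect_equal(offs$mean_diff, 2.5)
  expect_equal(offs$sd_diff, 0)
  expect_equal(c(offs$loa_low, offs$loa_high), c(2.5, 2.5))

  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("about 5% of normal differences fall outside the limits", {
  set.seed(34)
  n <- 10000
  x <- rnorm(n, 100, 10)
  y <- x + rnorm(n, 2, 5)  # bivariate normal pair with bias and noise
  got <- bland_altman(x, y)
  expect_gt(got$pct_outside, 0.03)
  expect_lt(got$pct_outside, 0.07)
})

test_that("Pearson r and Fisher-z CI match longhand formulas and cor.test", {
  x <- 1:10
  expect_equal(pearson_ci(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_ci(x, -x)$r, -1)

  set.seed(35)
  x <- rnorm(10); y <- 0.6 * x + rnorm(10, sd = 0.8)
  got <- pearson_ci(x, y)
  want <- oracle_pearson_ci(x, y)
  expect_equal(got$r, want$r, tolerance = 1e-10)
  expect_equal(got$ci_low, want$ci_low, tolerance = 1e-10)
  expect_equal(got$ci_high, want$ci_high, tolerance = 1e-10)
  ct <- stats::cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(c(got$ci_low, got$ci_high), as.numeric(ct$conf.int),
               tolerance = 1e-10)
  expect_true(got$ci_low <= got$r && got$r <= got$ci_high)

  expect_error(pearson_ci(1:3, 3:1), "at least 4")
  expect_error(pearson_ci(rep(1, 5), 1:5), "constant")
})

test_that("the Fisher-z interval narrows as n grows and covers the null 95%", {
  set.seed(36)
  width <- function(n) {
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    ci <- pearson_ci(x, y)
    ci$ci_high - ci$ci_low
  }
  expect_gt(width(20), width(2000))

  covered <- replicate(400, {
    x <- rnorm(20); y <- rnorm(20)  # independent: true r = 0
    ci <- pearson_ci(x, y)
    ci$ci_low <= 0 && 0 <= ci$ci_high
  })
  expect_gt(mean(covered), 0.90)
})

test_that("association tables give r = 1 when the outcome is the variable itself", {
  set.seed(37)
  g <- generate_cohort(synthetic_config(n_participants = 12, seed = 9))
  arch <- eating_architecture(g$records)
  fake <- tibble::tibble(
    participant_id = unique(arch$participant_id),
    mirror = arch$size_g[arch$method == "precise"][
      match(unique(arch$participant_id),
            arch$participant_id[arch$method == "precise"])]
  )
  tab <- association_table(arch, fake)
  diag_row <- tab[tab$variable == "size_g" & tab$outcome == "mirror" &
                    tab$method == "precise", ]
  expect_equal(diag_row$r, 1)
  expect_error(
    association_table(arch, tibble::tibble(participant_id = "nobody", x = 1)),
    "overlapping"
  )
})
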