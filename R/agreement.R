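#' Two-way mixed-effects consistency ICC, single measure
#'
#' The Shrout--Fleiss ICC(3,1): participants are random rows, the two timing
#' methods fixed columns, and agreement is judged on consistency, so a
#' constant shift of one method leaves the coefficient at 1. From the
#' two-way ANOVA decomposition with n subjects and k methods,
#'
#' \deqn{ICC = (MS_S - MS_E) / (MS_S + (k - 1) MS_E)}
#'
#' where `MS_S` is the between-subject and `MS_E` the residual
#' (subject x method interaction) mean square. The confidence interval is
#' the exact F-based one: with `F = MS_S / MS_E` on `(n - 1, (n - 1)(k - 1))`
#' degrees of freedom, the lower bound is
#' `(F / F_u - 1) / (F / F_u + k - 1)` at the upper critical value `F_u`,
#' and symmetrically for the upper bound.
#'
#' @param x,y Paired per-participant values for the two methods.
#' @param alpha Two-sided significance level for the CI (default 0.05).
#' @return A list: `icc`, `ci_low`, `ci_high`, `n`, `k`.
#' @examples
#' icc_consistency(c(1, 2, 3, 4), c(1.1, 2.3, 2.9, 4.2))
#' @export
icc_consistency <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), alpha > 0, alpha < 1)
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) stop("ICC needs at least 3 complete pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in ICC input", call. = FALSE)
  }
  k <- 2L
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  ss_total <- sum((dat - grand)^2)
  ss_subj <- k * sum((row_means - grand)^2)
  ss_meth <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_subj - ss_meth
  if (ss_total <= 0) stop("degenerate series: zero total variance", call. = FALSE)
  ms_subj <- ss_subj / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  icc <- (ms_subj - ms_err) / (ms_subj + (k - 1) * ms_err)
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  if (ms_err <= .Machine$double.eps * ms_subj) {
    # methods agree exactly up to a constant: ICC is 1 with a degenerate CI
    return(list(icc = 1, ci_low = 1, ci_high = 1, n = n, k = k))
  }
  fobs <- ms_subj / ms_err
  fu <- qf(1 - alpha / 2, df1, df2)
  fl <- qf(alpha / 2, df1, df2)
  ci_low <- (fobs / fu - 1) / (fobs / fu + k - 1)
  ci_high <- (fobs / fl - 1) / (fobs / fl + k - 1)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high, n = n, k = k)
}

#' Bland--Altman agreement analysis
#'
#' Differences are taken as `x - y` (precise minus broad in the pipeline);
#' a positive mean difference therefore means the broad method
#' underestimates the quantity. Limits of agreement are
#' `mean(d) +/- z * sd(d)` with the sample SD (denominator n - 1), and
#' `pct_outside` is the fraction of pairs strictly beyond either limit.
#'
#' @param x,y Paired values; differences are `x - y`.
#' @param z Normal quantile for the limits (default 1.96, i.e. 95%).
#' @return A list: `mean_diff`, `sd_diff`, `loa_low`, `loa_high`,
#'   `pct_outside` (a fraction in \[0, 1\]), `n`, and `points`, a tibble of
#'   `(mean, diff)` pairs for plotting.
#' @examples
#' bland_altman(c(5, 7), c(4, 5))
#' @export
bland_altman <- function(x, y, z = 1.96) {
  stopifnot(length(x) == length(y), z > 0)
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 2) stop("Bland-Altman needs at least 2 complete pairs", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  loa_low <- mean_diff - z * sd_diff
  loa_high <- mean_diff + z * sd_diff
  pct_outside <- mean(d < loa_low | d > loa_high)
  list(mean_diff = mean_diff, sd_diff = sd_diff,
       loa_low = loa_low, loa_high = loa_high,
       pct_outside = pct_outside, n = n,
       points = tibble::tibble(mean = m, diff = d))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y Paired values; pairs with a missing value on either side are
#'   dropped.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A list: `r`, `ci_low`, `ci_high`, `n`.
#' @examples
#' pearson_ci(1:10, (1:10) + rnorm(10))
#' @export
pearson_ci <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y), alpha > 0, alpha < 1)
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 4) stop("correlation CI needs at least 4 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    return(list(r = r, ci_low = r, ci_high = r, n = n))
  }
  zq <- qnorm(1 - alpha / 2)
  zr <- atanh(r)
  half <- zq / sqrt(n - 3)
  list(r = r, ci_low = tanh(zr - half), ci_high = tanh(zr + half), n = n)
}

#' Between-method agreement table for the architecture variables
#'
#' For each architecture variable, pairs each participant's precise value
#' with their broad value and reports the consistency ICC with its CI and
#' the Bland--Altman mean difference (precise - broad), limits of agreement
#' and percentage of points outside them. Participants missing the variable
#' under either method (e.g. the intermeal interval when no day has two
#' EOs) are dropped for that variable only.
#'
#' @param participants Per-participant architecture tibble containing both
#'   methods ([eating_architecture()]).
#' @param alpha Significance level for the ICC CI.
#' @param z Normal quantile for the limits of agreement.
#' @return A tibble, one row per variable: `variable`, `n`, `icc`,
#'   `icc_ci_low`, `icc_ci_high`, `mean_diff`, `loa_low`, `loa_high`,
#'   `pct_outside`.
#' @export
agreement_table <- function(participants, alpha = 0.05, z = 1.96) {
  wide <- method_wide(participants)
  purrr::map_dfr(arch_vars, function(v) {
    px <- wide[[paste0(v, "_precise")]]
    py <- wide[[paste0(v, "_broad")]]
    ok <- complete.cases(px, py)
    ic <- icc_consistency(px[ok], py[ok], alpha = alpha)
    ba <- bland_altman(px[ok], py[ok], z = z)
    tibble::tibble(
      variable = v, n = sum(ok),
      icc = ic$icc, icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
      mean_diff = ba$mean_diff, loa_low = ba$loa_low, loa_high = ba$loa_high,
      pct_outside = ba$pct_outside
    )
  })
}

# NA-valued result for cells where a correlation is undefined (constant or
# too-short input), so table builders report the cell instead of aborting
safe_pearson_ci <- function(x, y, alpha = 0.05) {
  tryCatch(pearson_ci(x, y, alpha = alpha),
           error = function(e) list(r = NA_real_, ci_low = NA_real_,
                                    ci_high = NA_real_,
                                    n = sum(complete.cases(x, y))))
}

# participant x method architecture reshaped to one row per participant with
# <var>_precise / <var>_broad columns
method_wide <- function(participants) {
  tidyr::pivot_wider(
    participants[, c("participant_id", "method", arch_vars)],
    names_from = "method",
    values_from = dplyr::all_of(arch_vars),
    names_glue = "{.value}_{method}"
  )
}

#' Intercorrelations among architecture variables within one method
#'
#' @param participants Per-participant architecture tibble.
#' @param method `"precise"` or `"broad"`.
#' @param alpha Significance level for the Fisher-z CIs.
#' @return A tibble of variable pairs with `r`, `ci_low`, `ci_high`, `n`.
#' @export
intercorrelation_table <- function(participants, method = c("precise", "broad"),
                                   alpha = 0.05) {
  method <- match.arg(method)
  sub <- participants[participants$method == method, , drop = FALSE]
  pairs <- utils::combn(arch_vars, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    res <- safe_pearson_ci(sub[[v1]], sub[[v2]], alpha = alpha)
    tibble::tibble(var1 = v1, var2 = v2, method = method,
                   r = res$r, ci_low = res$ci_low, ci_high = res$ci_high,
                   n = res$n)
  })
}

#' Associations between architecture variables and outcomes
#'
#' Pearson correlations (with Fisher-z CIs) of each architecture variable,
#' under each method, with each supplied outcome column (e.g. total energy
#' intake, BMI, waist circumference, a dietary-pattern z-score). Each cell
#' is complete-case: only participants observed for both members of the
#' pair contribute, and the per-cell n is reported.
#'
#' @param participants Per-participant architecture tibble (both methods).
#' @param outcomes A data frame with `participant_id` plus one column per
#'   outcome.
#' @param alpha Significance level.
#' @return A tibble: `variable`, `outcome`, `method`, `r`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
association_table <- function(participants, outcomes, alpha = 0.05) {
  stopifnot("participant_id" %in% names(outcomes))
  outcome_vars <- setdiff(names(outcomes), "participant_id")
  if (length(outcome_vars) == 0) stop("no outcome columns supplied", call. = FALSE)
  joined <- dplyr::inner_join(participants, outcomes, by = "participant_id")
  if (nrow(joined) == 0) {
    stop("no overlapping participants between architecture and outcomes",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(variable = arch_vars, outcome = outcome_vars,
                             method = c("precise", "broad"))
  purrr::pmap_dfr(grid, function(variable, outcome, method) {
    sub <- joined[joined$method == method, , drop = FALSE]
    res <- safe_pearson_ci(sub[[variable]], sub[[outcome]], alpha = alpha)
    tibble::tibble(variable = variable, outcome = outcome, method = method,
                   r = res$r, ci_low = res$ci_low, ci_high = res$ci_high,
                   n = res$n)
  })
}
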