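# Independent brute-force reference implementations used as oracles.
# These deliberately avoid the package's own code paths: plain loops and
# explicit textbook formulas only.

# group records into occasions by sorting then scanning, one day at a time
oracle_precise_eos <- function(times, grams, kcal) {
  ord <- order(times)
  times <- times[ord]; grams <- grams[ord]; kcal <- kcal[ord]
  out <- list()
  for (t in unique(times)) {
    idx <- which(times == t)
    out[[length(out) + 1]] <- c(time = t, grams = sum(grams[idx]),
                                kcal = sum(kcal[idx]), n = length(idx))
  }
  do.call(rbind, out)
}

oracle_broad_eos <- function(times, grams, kcal, scheme = eatarch::meal_slot_scheme()) {
  slot_of <- function(t) {
    for (i in seq_len(nrow(scheme))) {
      if (t >= scheme$start_min[i] && t <= scheme$end_min[i]) return(scheme$slot[i])
    }
    stop("time out of range")
  }
  slots <- vapply(times, slot_of, character(1))
  out <- list()
  for (s in unique(slots[order(times)])) {
    idx <- which(slots == s)
    out[[length(out) + 1]] <- list(
      slot = s,
      rep = scheme$rep_min[match(s, scheme$slot)],
      grams = sum(grams[idx]), kcal = sum(kcal[idx]),
      n_members = length(unique(times[idx]))
    )
  }
  out[order(vapply(out, function(e) e$rep, numeric(1)))]
}

# two-way ANOVA sums of squares written out longhand for an n x 2 layout
oracle_icc31 <- function(x, y, alpha = 0.05) {
  n <- length(x); k <- 2
  vals <- c(x, y)
  grand <- sum(vals) / (n * k)
  ss_total <- sum((vals - grand)^2)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * ((x[i] + y[i]) / 2 - grand)^2
  ss_cols <- n * ((mean(x) - grand)^2 + (mean(y) - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  icc <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  fobs <- ms_rows / ms_err
  fu <- qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fl <- qf(alpha / 2, n - 1, (n - 1) * (k - 1))
  list(icc = icc,
       ci_low = (fobs / fu - 1) / (fobs / fu + k - 1),
       ci_high = (fobs / fl - 1) / (fobs / fl + k - 1))
}

oracle_bland_altman <- function(x, y, z = 1.96) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  lo <- m - z * s; hi <- m + z * s
  list(mean_diff = m, loa_low = lo, loa_high = hi,
       pct_outside = sum(d < lo | d > hi) / n)
}

oracle_pearson_ci <- function(x, y, alpha = 0.05) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  zq <- qnorm(1 - alpha / 2)
  lo <- tanh(0.5 * log((1 + r) / (1 - r)) - zq / sqrt(n - 3))
  hi <- tanh(0.5 * log((1 + r) / (1 - r)) + zq / sqrt(n - 3))
  list(r = r, ci_low = lo, ci_high = hi)
}

# linear-interpolation quantile (R default type 7) written out longhand
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small random diary day for property tests
random_day <- function(n_records = sample(1:10, 1)) {
  times <- sample(0:1439, n_records, replace = TRUE)
  tibble::tibble(
    participant_id = "PX", day = 1L, time_min = as.integer(times),
    grams = round(runif(n_records, 1, 400), 1),
    kcal = round(runif(n_records, 1, 600), 1)
  )
}
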