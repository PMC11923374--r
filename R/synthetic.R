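#' Configuration for the synthetic diary generator
#'
#' Builds the parameter set for [generate_cohort()]. The defaults emulate
#' 3-day diet diaries of young children: three anchored meals (breakfast,
#' lunch, dinner) with day-to-day jitter, plus a Poisson number of snacks
#' placed mid-morning, mid-afternoon or shortly after dinner. Post-dinner
#' snacks sit a log-normal gap (median about 30 min, clipped to 15--120
#' min) after the dinner time, which is what makes the broad meal-slot
#' coding merge them into the dinner occasion with positive probability --
#' the mechanism by which timing coarseness biases eating-architecture
#' estimates. Occasion weights are log-normal, with snacks smaller but more
#' energy-dense than meals, and each occasion is split into 1--4 food
#' records so that record-level grouping is exercised.
#'
#' Outcome variables (TEI, BMI, WC, ODP by default) are generated from a
#' latent-factor model: each outcome is correlated with a chosen
#' architecture variable at a configurable target correlation `rho`, then
#' scaled to a realistic mean and SD.
#'
#' @param n_participants Number of participants.
#' @param n_days Diary days per participant (default 3).
#' @param seed Base seed; each participant uses a substream derived from it,
#'   so participant `i`'s diary is identical whatever `n_participants` is.
#' @param anchors Named list of `c(mean, sd)` minute pairs for
#'   breakfast/lunch/dinner.
#' @param snacks_per_day Poisson mean of the daily snack count.
#' @param snack_placement Probabilities over
#'   `c(mid_morning, mid_afternoon, post_dinner)`; must sum to 1.
#' @param snack_centers `c(mean, sd)` minutes for the mid-morning and
#'   mid-afternoon snack times.
#' @param post_dinner_gap List `meanlog`, `sdlog`, `min`, `max` for the
#'   log-normal minutes between dinner and a post-dinner snack.
#' @param meal_grams,snack_grams Lists `meanlog`, `sdlog` for occasion
#'   weight in grams.
#' @param meal_density,snack_density `c(mean, sd)` kcal-per-gram energy
#'   density, truncated below at 0.3.
#' @param max_records_per_eo Upper bound on food records per occasion.
#' @param outcomes Named list; each element is a list
#'   `list(var, rho, mean, sd)` tying the outcome to an architecture
#'   variable at target correlation `rho`.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_participants = 100,
    n_days = 3,
    seed = 1,
    anchors = list(breakfast = c(mean = 484, sd = 30),
                   lunch = c(mean = 765, sd = 25),
                   dinner = c(mean = 1075, sd = 35)),
    snacks_per_day = 4,
    snack_placement = c(mid_morning = 0.3, mid_afternoon = 0.3,
                        post_dinner = 0.4),
    snack_centers = list(mid_morning = c(mean = 630, sd = 45),
                         mid_afternoon = c(mean = 945, sd = 45)),
    post_dinner_gap = list(meanlog = log(30), sdlog = 0.55, min = 15, max = 120),
    meal_grams = list(meanlog = log(300), sdlog = 0.35),
    snack_grams = list(meanlog = log(100), sdlog = 0.5),
    meal_density = c(mean = 1.2, sd = 0.15),
    snack_density = c(mean = 2.0, sd = 0.25),
    max_records_per_eo = 4,
    outcomes = list(
      TEI = list(var = "size_g", rho = 0.3, mean = 1699, sd = 312),
      BMI = list(var = "size_g", rho = 0.1, mean = 16.3, sd = 2.1),
      WC  = list(var = "size_g", rho = 0.1, mean = 56.5, sd = 5.3),
      ODP = list(var = "size_g", rho = -0.1, mean = 0, sd = 1.1)
    )) {
  cfg <- list(
    n_participants = n_participants, n_days = n_days, seed = seed,
    anchors = anchors, snacks_per_day = snacks_per_day,
    snack_placement = snack_placement, snack_centers = snack_centers,
    post_dinner_gap = post_dinner_gap,
    meal_grams = meal_grams, snack_grams = snack_grams,
    meal_density = meal_density, snack_density = snack_density,
    max_records_per_eo = max_records_per_eo, outcomes = outcomes
  )
  check <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid config field '", field, "': ", msg, call. = FALSE)
  }
  check(is.numeric(n_participants) && n_participants >= 1, "n_participants", "must be >= 1")
  check(is.numeric(n_days) && n_days >= 1, "n_days", "must be >= 1")
  check(is.numeric(seed) && is.finite(seed), "seed", "must be a finite number")
  check(all(c("breakfast", "lunch", "dinner") %in% names(anchors)), "anchors",
        "needs breakfast, lunch, dinner")
  for (a in names(anchors)) {
    check(anchors[[a]][["sd"]] > 0, "anchors", paste0(a, " sd must be > 0"))
  }
  check(snacks_per_day >= 0, "snacks_per_day", "must be >= 0")
  check(abs(sum(snack_placement) - 1) < 1e-8 && all(snack_placement >= 0),
        "snack_placement", "probabilities must be non-negative and sum to 1")
  check(all(c("mid_morning", "mid_afternoon", "post_dinner") %in%
              names(snack_placement)), "snack_placement",
        "needs mid_morning, mid_afternoon, post_dinner")
  check(post_dinner_gap$min > 0 && post_dinner_gap$max > post_dinner_gap$min,
        "post_dinner_gap", "need 0 < min < max")
  check(max_records_per_eo >= 1, "max_records_per_eo", "must be >= 1")
  for (o in names(outcomes)) {
    spec <- outcomes[[o]]
    check(all(c("var", "rho", "mean", "sd") %in% names(spec)), "outcomes",
          paste0(o, " needs var, rho, mean, sd"))
    check(abs(spec$rho) <= 1, "outcomes", paste0(o, " rho must be in [-1, 1]"))
    check(spec$sd > 0, "outcomes", paste0(o, " sd must be > 0"))
  }
  structure(cfg, class = "synthetic_config")
}

participant_seed <- function(base_seed, i) {
  (as.integer(base_seed) %% 1000003L) * 1000L + (i %% 1000L) +
    (i %/% 1000L) * 7919L
}

clip_min <- function(x, lo = 0, hi = 1439) pmin(pmax(round(x), lo), hi)

# one participant's diary + ground-truth EO list, generated in its own
# RNG substream so regeneration is stable under cohort-size changes
generate_participant <- function(cfg, i) {
  set.seed(participant_seed(cfg$seed, i))
  pid <- sprintf("S%04d", i)
  eo_rows <- vector("list", cfg$n_days)
  for (d in seq_len(cfg$n_days)) {
    repeat {
      meals <- clip_min(c(
        rnorm(1, cfg$anchors$breakfast[["mean"]], cfg$anchors$breakfast[["sd"]]),
        rnorm(1, cfg$anchors$lunch[["mean"]], cfg$anchors$lunch[["sd"]]),
        rnorm(1, cfg$anchors$dinner[["mean"]], cfg$anchors$dinner[["sd"]])
      ))
      if (!anyDuplicated(meals)) break
    }
    dinner_time <- meals[3]
    n_snacks <- rpois(1, cfg$snacks_per_day)
    times <- meals
    types <- c("meal", "meal", "meal")
    if (n_snacks > 0) {
      kinds <- sample(names(cfg$snack_placement), n_snacks, replace = TRUE,
                      prob = cfg$snack_placement)
      for (kind in kinds) {
        for (attempt in 1:50) {
          t <- switch(kind,
            mid_morning = clip_min(rnorm(1, cfg$snack_centers$mid_morning[["mean"]],
                                         cfg$snack_centers$mid_morning[["sd"]])),
            mid_afternoon = clip_min(rnorm(1, cfg$snack_centers$mid_afternoon[["mean"]],
                                           cfg$snack_centers$mid_afternoon[["sd"]])),
            post_dinner = clip_min(dinner_time +
              pmin(pmax(rlnorm(1, cfg$post_dinner_gap$meanlog,
                               cfg$post_dinner_gap$sdlog),
                        cfg$post_dinner_gap$min), cfg$post_dinner_gap$max))
          )
          if (!(t %in% times)) break
        }
        if (!(t %in% times)) {
          times <- c(times, t)
          types <- c(types, "snack")
        }
      }
    }
    n_eo <- length(times)
    is_meal <- types == "meal"
    grams <- numeric(n_eo)
    grams[is_meal] <- rlnorm(sum(is_meal), cfg$meal_grams$meanlog,
                             cfg$meal_grams$sdlog)
    grams[!is_meal] <- rlnorm(sum(!is_meal), cfg$snack_grams$meanlog,
                              cfg$snack_grams$sdlog)
    density <- numeric(n_eo)
    density[is_meal] <- pmax(rnorm(sum(is_meal), cfg$meal_density[["mean"]],
                                   cfg$meal_density[["sd"]]), 0.3)
    density[!is_meal] <- pmax(rnorm(sum(!is_meal), cfg$snack_density[["mean"]],
                                    cfg$snack_density[["sd"]]), 0.3)
    ord <- order(times)
    eo_rows[[d]] <- tibble::tibble(
      participant_id = pid, day = d, time_min = as.integer(times[ord]),
      type = types[ord], grams = grams[ord], kcal = grams[ord] * density[ord]
    )
  }
  eos <- dplyr::bind_rows(eo_rows)

  # split each EO into 1..max_records_per_eo food records
  n_eo_total <- nrow(eos)
  m <- sample.int(cfg$max_records_per_eo, n_eo_total, replace = TRUE)
  rec_idx <- rep(seq_len(n_eo_total), m)
  w <- runif(length(rec_idx), 0.2, 1)
  w <- w / stats::ave(w, rec_idx, FUN = sum)
  records <- tibble::tibble(
    participant_id = eos$participant_id[rec_idx],
    day = eos$day[rec_idx],
    time_min = eos$time_min[rec_idx],
    grams = eos$grams[rec_idx] * w,
    kcal = eos$kcal[rec_idx] * w,
    label = paste0("food_", seq_along(rec_idx)),
    slot_recorded = NA_character_
  )
  # outcome noise drawn here so it lives in the participant's substream
  eps <- rnorm(length(cfg$outcomes))
  names(eps) <- names(cfg$outcomes)
  list(records = records, truth = eos, eps = eps)
}

#' Generate a synthetic diary cohort
#'
#' Deterministic in `cfg$seed`: the same configuration always produces the
#' same records, ground truth and outcomes, and each participant is drawn
#' from their own seed-derived substream.
#'
#' @param cfg A [synthetic_config()].
#' @return A list:
#'   * `records` -- food-record tibble in the shape [parse_diaries()]
#'     produces (1--4 records per occasion, grams/kcal summing to the
#'     occasion totals);
#'   * `outcomes` -- per-participant outcome tibble (`participant_id` plus
#'     one column per configured outcome);
#'   * `truth` -- ground-truth occasion table (`participant_id`, `day`,
#'     `time_min`, `type`, `grams`, `kcal`), one row per true EO;
#'   * `config` -- the configuration used.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  parts <- lapply(seq_len(cfg$n_participants), function(i) generate_participant(cfg, i))
  records <- dplyr::bind_rows(lapply(parts, `[[`, "records"))
  truth <- dplyr::bind_rows(lapply(parts, `[[`, "truth"))
  records <- dplyr::arrange(records, .data$participant_id, .data$day, .data$time_min)

  # latent-factor outcomes: rho * standardized architecture variable +
  # sqrt(1 - rho^2) * participant noise, rescaled to the target moments
  arch <- participant_architecture(day_architecture(
    dplyr::mutate(truth, method = "precise")
  ))
  ids <- sort(unique(records$participant_id))
  arch <- arch[match(ids, arch$participant_id), , drop = FALSE]
  eps_mat <- do.call(rbind, lapply(parts, `[[`, "eps"))
  outcomes <- tibble::tibble(participant_id = ids)
  for (j in seq_along(cfg$outcomes)) {
    oname <- names(cfg$outcomes)[j]
    spec <- cfg$outcomes[[j]]
    v <- arch[[spec$var]]
    if (is.null(v)) stop("outcome '", oname, "' references unknown variable '",
                         spec$var, "'", call. = FALSE)
    z <- as.numeric(scale(v))
    latent <- spec$rho * z + sqrt(1 - spec$rho^2) * eps_mat[, j]
    outcomes[[oname]] <- spec$mean + spec$sd * latent
  }
  list(records = records, outcomes = outcomes, truth = truth, config = cfg)
}

#' Inject missing and invalid times into diary records
#'
#' Marks a random subset of records as having a missing time (`NA`) or an
#' impossible one (beyond 23:59), returning the tampered records together
#' with a log of exactly which rows were touched -- so the cohort validator
#' can be checked against known corruption counts.
#'
#' @param records A food-record tibble.
#' @param missing_rate,invalid_rate Per-record corruption probabilities;
#'   each record suffers at most one corruption, missing taking precedence.
#' @param seed Seed for the corruption draw.
#' @return A list with `records` (tampered copy) and `tamper_log` (tibble:
#'   `row`, `participant_id`, `day`, `type` in `{"missing", "invalid"}`).
#' @export
corrupt_times <- function(records, missing_rate = 0, invalid_rate = 0, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate < 1,
            invalid_rate >= 0, invalid_rate < 1,
            missing_rate + invalid_rate < 1)
  set.seed(as.integer(seed))
  n <- nrow(records)
  u <- runif(n)
  make_missing <- u < missing_rate
  make_invalid <- !make_missing & u < missing_rate + invalid_rate
  out <- records
  out$time_min[make_missing] <- NA_integer_
  out$time_min[make_invalid] <- 1440L + sample.int(120L, sum(make_invalid),
                                                   replace = TRUE)
  tamper_log <- tibble::tibble(
    row = c(which(make_missing), which(make_invalid)),
    participant_id = records$participant_id[c(which(make_missing), which(make_invalid))],
    day = records$day[c(which(make_missing), which(make_invalid))],
    type = rep(c("missing", "invalid"),
               c(sum(make_missing), sum(make_invalid)))
  )
  list(records = out, tamper_log = tamper_log)
}
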