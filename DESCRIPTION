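Package: eatarch
Title: Eating Architecture from Timed Diet Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying eating architecture - the size, timing and
    frequency of eating occasions - from timestamped diet-diary records, and
    for quantifying the bias introduced when exact clock times are coarsened
    into broad meal slots. Builds eating occasions under a precise (unique
    clock time) and a broad (seven-slot meal-period) definition, derives
    per-participant architecture variables (occasion size in grams and kcal,
    first and last eating time, eating window, intermeal interval, daily
    frequency), and measures between-method agreement with two-way
    mixed-effects consistency intraclass correlations, Bland-Altman limits of
    agreement, and Pearson correlations with Fisher-z confidence intervals.
    Includes a synthetic three-day child-diary cohort generator with anchored
    meals, clustered post-dinner snacking and correlated outcome variables,
    and an end-to-end pipeline writing tidy CSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
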