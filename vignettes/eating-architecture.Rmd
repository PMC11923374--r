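---
title: "Eating architecture and the precision of recorded eating times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eating architecture and the precision of recorded eating times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatarch)
```

## The problem

*Eating architecture* is the joint structure of when, how often, and how much
a person eats, resolved at the level of individual eating occasions (EOs).
Diet diaries can record the exact clock time of every food entry, but many
large cohort databases historically coded entry times only into a handful of
broad meal slots ("breakfast", "mid-morning", ...), because their purpose was
nutrient estimation rather than timing. When two distinct eating events fall
into the same slot, the slot-coded data silently fuses them into one larger
occasion. That coarsening biases every architecture variable at once:
frequency is undercounted, mean occasion size is inflated, and the timing
variables inherit the slots' representative clock times instead of the real
ones.

`eatarch` quantifies this bias. It constructs EOs from the same records under
both timing definitions, derives the standard architecture variables under
each, and measures between-method agreement with the statistics used in
method-comparison work: two-way mixed-effects consistency intraclass
correlations (ICC), Bland–Altman limits of agreement, and Pearson
correlations with Fisher-z intervals. Because real slot-coded diary archives
are typically access-controlled, the package ships a synthetic diary
generator that reproduces the temporal structure the analysis cares about,
so the entire pipeline is testable end to end.

## Occasion definitions

Records are long-format: participant, diary day, clock time (minutes since
midnight, 0–1439), grams and kcal per food entry. Two EO definitions are
applied per participant-day:

* **precise** — one EO per distinct recorded clock time; grams and kcal are
  summed over records sharing that time;
* **broad** — one EO per occupied meal slot; everything in the slot is
  pooled, and the EO is timestamped with the slot's representative clock
  time.

The default slot scheme is the seven-slot historical coding frame:

```{r}
meal_slot_scheme()
```

Two representations deserve a remark because they look like errors and are
not: Mid-afternoon (14:30–16:59) is represented by 17:00, the *start of the
next slot*, and Evening (17:00–19:29) by 20:00, outside the slot entirely.
These are the values the legacy coding documents used, and the package keeps
them verbatim — recomputing them as interval midpoints would change the
broad timing variables and break comparability with archives coded this way.
Alternative schemes (slot periods are culturally specific) can be supplied
via `read_slot_scheme()` and are validated as gapless inclusive partitions
of the day.

Two invariants tie the definitions together and are enforced in the tests:
totals of grams and kcal are conserved exactly between raw records, precise
EOs and broad EOs; and per day the broad EO count never exceeds the precise
count, with the deficit equal to the number of extra precise members merged
into broad EOs.

## Architecture variables

Per day: EO `frequency`; mean `size_g` and `size_kcal` per EO; `first_min`
and `last_min` (clock time of the first/last EO); the eating window
`window_min = last_min - first_min`; and the mean intermeal interval.
Because consecutive gaps of sorted times telescope, the per-day mean gap is
identically `window_min / (frequency - 1)`; a single-EO day has a window of
0 and no defined interval. Participant values are unweighted means over
recorded days (the interval over days where it exists). Both "average the
per-day mean gap" and "pool all gaps across days" are defensible readings
of a mean intermeal interval; the former is the default and the latter is
available as `participant_architecture(..., pooled_interval = TRUE)`.

Clock times are averaged as plain minutes since midnight, not circularly:
diary days are day-local by construction, no eating time can wrap past
midnight, and child cohorts eat nowhere near the 00:00 discontinuity, so
linear averaging is exact for the question asked. Cross-midnight linkage
between consecutive diary days is deliberately out of scope.

## Agreement statistics

For each variable the per-participant precise and broad values form paired
series, and three statistics are computed by the package itself (they are
the point of the exercise; standard library fits are used only as oracles in
the test suite):

* **ICC(3,1)** — single-measure, two-way mixed-effects *consistency* ICC:
  participants random, the two methods fixed. From the two-way ANOVA mean
  squares, $ICC = (MS_S - MS_E)/(MS_S + (k-1)MS_E)$ with $k = 2$. The
  consistency form ignores a constant shift between methods, which is the
  right notion here: a slot representation offsets every participant
  equally. The CI is the exact F-based interval on
  $(n-1, (n-1)(k-1))$ degrees of freedom.
* **Bland–Altman** — differences are precise − broad, so a positive mean
  difference reads "the broad method underestimates". Limits are
  mean ± 1.96 SD (sample SD, $n-1$); the share of points outside the limits
  is counted *strictly* beyond either limit (a point on a limit is within
  tolerance, not outside it).
* **Pearson + Fisher z** — $\tanh(\operatorname{atanh} r \pm
  z_{1-\alpha/2}/\sqrt{n-3})$, used for variable intercorrelations within a
  method and for associations with outcomes (total energy intake, BMI,
  waist circumference, a dietary-pattern z-score). All cells are
  complete-case with per-cell n reported; a cell whose input is constant is
  reported as NA rather than failing the run.

Pairs with an undefined interval on either side are dropped listwise for
that variable only.

## Within-slot composition

To locate *where* merging happens, every broad EO carries the count of
distinct precise times it absorbed. For multi-member broad EOs the
consecutive sorted gaps between member times are collected; per-slot
summaries (median, IQR, 10th/90th percentiles of per-EO mean gaps) use R's
default linear-interpolation quantile convention, which the test oracle
re-implements longhand. Gap fractions around the 15- and 60-minute
separation cutoffs common in the EO-definition literature are inclusive on
the matched side: a gap of exactly 15 min counts as "≥ 15 min apart", and
exactly 60 as "≤ 60 min". Consecutive (not all-pairs) differences are used
throughout, matching how minimum-gap EO definitions operate.

## The synthetic cohort generator

`synthetic_config()` / `generate_cohort()` emulate 3-day child diet
diaries:

* three anchored meals per day, drawn around 08:04 (SD 30 min), 12:45
  (SD 25) and 17:55 (SD 35) — placed so the cohort's precise first eating
  time averages just after 08:00 and meals land in the expected slots;
* a Poisson(4) number of snacks per day placed mid-morning, mid-afternoon
  or after dinner (probabilities 0.3/0.3/0.4), giving about 7 precise EOs
  per day; post-dinner snacks follow dinner by a log-normal gap with median
  30 min clipped to 15–120 min, so they frequently share the dinner slot —
  the designated mechanism by which broad coding merges occasions, and the
  reason the largest per-slot size inflation appears in the evening;
* log-normal occasion weights (meals: median 300 g; snacks: median 100 g)
  with snacks roughly 2.0 kcal/g against meals' 1.2 kcal/g, each EO split
  into 1–4 food records so record-level grouping is exercised;
* outcomes from a latent-factor model: each outcome equals
  $\mu + \sigma(\rho z_v + \sqrt{1-\rho^2}\,\varepsilon)$ where $z_v$ is the
  cohort-standardised value of a chosen architecture variable. This was
  preferred over deriving TEI mechanically from simulated kcal because it
  makes the architecture–outcome correlation a *configurable* target the
  pipeline's recovery can be checked against; the default ties TEI to EO
  size at ρ = 0.3 with TEI scaled to a realistic child mean (1699 kcal/d,
  SD 312).

Each participant is generated in an RNG substream derived from the base
seed, so participant *i*'s diary is byte-identical whatever the cohort
size. `corrupt_times()` injects missing and impossible (> 23:59) times with
an exact tamper log, against which the validator's exclusion counts are
checked; dropped participants are classified once each, in the order
missing → invalid → partial.

What the generator does **not** emulate: dietary underreporting, weekday vs
weekend structure (days are exchangeable, matching the unweighted
averaging), foods and nutrients beyond grams/kcal/energy density,
correlation between snack size and time of day, and seasonal or secular
trends. A pipeline that passes on this cohort is therefore validated for
its *arithmetic and its bias mechanism*, not certified against every
feature of real diary data.

## Validity rules

Participants are excluded wholesale (never day-wise) if any time is
missing, any time is invalid (> 23:59), or — when records carry an
independent legacy slot code — some day's distinct valid times cannot
account for its occupied slots, which makes a precise/broad comparison
impossible for that participant. The per-day check with whole-participant
exclusion mirrors how such archives were cleaned. Duplicate identical rows
are kept: two portions of the same food at the same time are legitimate and
merge at EO construction.

## Problem sizes and numerical choices

The package's own verification runs use cohorts of 300–500 participants
(about 1,000–1,500 participant-days) for the distributional checks, 1,000
participants for correlation-recovery, and 10,000 simulated pairs for the
limits-of-agreement coverage check — sizes at which sampling error is well
inside the asserted tolerances while a full test run stays comfortably
fast. Algebraic identities (conservation, merge accounting) are asserted at
1e-9 or tighter; statistic implementations match their brute-force oracles
at 1e-10 relative tolerance.

Degenerate inputs are defined, not patched around: a single-EO day has
window 0 and no interval; an ICC on series the two methods agree on up to a
constant returns exactly 1 with a degenerate CI; Bland–Altman on identical
series gives limits (0, 0) with nothing outside.

## Limitations

The slot scheme's historical anomalies mean broad timing variables are not
monotone transforms of precise ones (a 20:00 representation can sit later
than a real 19:00 dinner but earlier than a real 23:50 snack), so no
monotone relation between methods' first/last times is asserted anywhere.
ICC and Bland–Altman quantify agreement, not correctness: on real data
neither method is ground truth, whereas in simulation the precise method is
correct by construction. Associations produced by `association_table()` are
unadjusted cross-sectional correlations and are meant for method
comparison, not aetiological inference.
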