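---
title: "Modeling an egg substitution in exemplary menus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling an egg substitution in exemplary menus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnimenu)
library(dplyr)
```

## The problem

Adolescents (14–18 y) underconsume several micronutrients — most severely
vitamin D and choline. Eggs are inexpensive, widely accepted, and dense in
both. This package models a practical intervention: in a multi-day menu
plan, replace 44 g (one medium boiled egg) of the day's main protein-source
food with an egg, and quantify what that does to (a) micronutrient quality,
scored with the Food Nutrient Index (FNI), and (b) daily menu cost.

The package ships transcriptions of the daily nutrient totals and daily
prices of four seven-day exemplary menus — the Healthy U.S.-Style pattern
(HUSS), the DASH diet menu, the Harvard Healthy Eating Guide menu (all
2000 kcal/d) and the Healthy Vegetarian pattern (HVEG, 2400 kcal/d) — in
both conditions (as given, and with the daily egg substitution), so the
entire scoring and comparison pipeline can be exercised and checked against
the published summaries. The food-level composition of those menus is not
public; food-level work therefore runs on the packaged synthetic generator.

## The Food Nutrient Index

Eight shortfall nutrients are scored: choline, potassium, calcium, folate
(as dietary folate equivalents), magnesium, zinc, vitamin D, and vitamin C.
For a daily amount $a$ of a nutrient with sex-specific reference intakes
(RDA or AI) $r_F$ and $r_M$, the component score is

$$s(a) = \tfrac{1}{2}\left[\min\!\left(100,\ 100\,\frac{a}{r_F}\right) +
\min\!\left(100,\ 100\,\frac{a}{r_M}\right)\right],$$

and the total FNI is the equal-weight mean of the eight components. Two
choices here were genuinely open, and both are pinned down by the published
component scores:

* **Cap before averaging.** When a menu exceeds the female reference but
  not the male one (e.g. the Harvard menu's zinc: 9.67 mg against 9/11 mg),
  capping each sex first then averaging gives 93.96, matching the published
  94; capping the averaged ratio does not.
* **Sex handling.** Components are computed per sex and averaged, rather
  than scored against a single midpoint reference. The published HUSS
  choline score (83.4) equals the per-sex average against 400/550 mg, not
  the capped ratio against the narrative 475 mg midpoint.

The per-sex score matrix is retained in every result (`tidy(x, by_sex =
TRUE)`) so single-sex scoring is available.

Default reference values are the adolescent (14–18 y) DRIs, with the lower
bound of each printed range assigned to females and the upper to males, as
in the standard DRI tables. Other life stages can be supplied as a CSV in
the same layout (`read_dri_table()`); no other defaults are shipped.

### Aggregation modes

`fni_score()` offers two aggregations over days:

* `mean_of_days` — average each nutrient across the seven days, then score
  the means. This is the index's defining construction and the mode used
  for all published-value comparisons.
* `per_day` — score each day and summarise the daily totals (mean and
  sample SD). Because the cap is concave, the per-day mean is generally
  *larger* than the mean-of-days score when some days exceed the reference
  and others fall short; both are reported, neither is forced to agree.

The published total-score SDs (e.g. 94.0 ± 2.3) and the four total-FNI
p-values could not be reconstructed from any per-day scheme derivable from
the printed dailies, so SDs from `per_day` mode are reported as this
package's construction and are not compared against the printed ones.

## The substitution engine

Per day, candidates are protein-group foods (meats/poultry, seafood,
legumes, nuts/seeds/soy — never eggs themselves) served in at least 44 g,
ranked by absolute protein in the served portion (grams × density / 100),
not by protein density: the selection compares protein content across
served foods. Two menu-design rules modify the ranking:

* **Seafood retention.** A seafood candidate is passed over if removing
  44 g would drop the plan's weekly seafood below eight ounce-equivalents
  (226.8 g) per 2000 kcal; the target scales linearly with the plan's
  energy level. The running total accounts for seafood already removed on
  earlier days.
* **Variety.** A (subgroup, name) pair already substituted on an earlier
  day is deprioritized below unused alternatives — a soft penalty, not a
  prohibition, so a repeated protein is still substituted when it is the
  only option.

The swap itself is gram-for-gram: the target loses 44 g, a 44 g egg item is
added, total grams per day are conserved exactly, and the daily nutrient
change is `0.44 × (egg density − target density)` per nutrient. Requiring
candidates to carry at least 44 g keeps the swap well defined; "holding
energy constant" is realized as the gram-for-gram exchange, with any
residual energy difference reported rather than forced to zero. Mixed
dishes are treated as atomic foods: their densities embed the recipe, so
the swap applies to the dish as served. Days with no eligible candidate
pass through untouched — exactly the pattern of the one DASH day whose
printed rows are identical in both conditions; a `skip_days` argument
reproduces such days without guessing their reason.

The shipped egg profile (`default_egg_profile()`) uses standard
food-composition reference values for a boiled egg per 100 g (they are
reference data, not values transcribed from the study); tests exercise the
engine with synthetic profiles, and any one-row profile in the same layout
can be substituted.

## Pricing

Daily cost is `sum(grams / 100 × price)` with as-consumed USD per 100 g
prices. Unpriced foods follow an explicit policy: `skip_and_log` (omit and
report — the treatment small spice amounts received), `map_then_skip`
(consult a user-supplied most-similar-food mapping first; similarity is a
curated table, not an algorithm), or `error`. Summaries use the sample
(n−1) SD, which reproduces all eight printed "Daily mean (SD)" cells from
the printed dailies within 0.05 USD. Prices are carried at full precision
and rounded only for display. The substituted plan is priced as-is, egg
included, which matches the small printed decreases. Annualized-cost
extrapolations are out of scope: the printed annual figures are not
consistent with any mean × 365 or weekly × 52 arithmetic on the printed
dailies.

## Condition comparisons

`compare_conditions()` reproduces the published testing scheme: per-nutrient
t tests at a Bonferroni threshold of 0.05/256, and total-FNI and price
tests at 0.05/4. The 256 follows the published counting (8 nutrients × 8
"days", counting the daily-mean row as an eighth observation, × 4 menus);
it is reproduced as configuration because its combinatorial rationale is
not explained. Thresholds are computed exactly (0.0125, 0.000195…); a
`printed_thresholds` switch substitutes the truncated printed values (0.01,
0.0001). Conclusions are identical either way on the packaged data.

Whether the published "pairwise" tests were day-paired or unpaired is not
stated. Both are offered (`paired`, `welch`, `pooled`), with **Welch as the
default**: the unpaired modes reproduce the published verdict of no
significant differences in every family, whereas day-pairing makes the
nutrient and FNI comparisons strongly significant (the substitution shifts
choline in the same direction every single day, and pairing removes the
between-day variance) — strong evidence the published analysis was not
day-paired. Prices are non-significant in every mode. Degenerate inputs
follow fixed conventions: an all-zero paired difference returns p = 1, a
constant nonzero difference p = 0.

## The synthetic generator

`generate_plan()` emits food-level plans with the structure the engine
assumes: 7 days, 6–12 foods/day, two non-egg protein items of ≥ 44 g per
day, seafood on the first two days, a quarter of protein items flagged as
mixed dishes, and per-100 g densities drawn from per-group log-normals
(positivity and right skew; medians are order-of-magnitude plausible per
food group — configuration, not claims about real foods). Portion grams
are rescaled uniformly so each day lands within ±15% of the 2000 kcal
target, preserving group composition; protein portions are then floored at
45 g so substitution eligibility is never destroyed by rescaling. A single
seeded stream with a documented draw order (group, name, densities, grams —
day by day, food by food) makes plans fully reproducible;
`generate_price_table()` draws on a stream derived from the same seed so
pricing does not perturb plan generation. `generate_calibrated_plan()`
rescales densities so each nutrient's across-day mean sits at a chosen
multiple of the sex-averaged reference, pinning every component to a closed
form for end-to-end checks.

What the generator does **not** emulate: real NDSR food distributions,
recipe structure, nutrient correlations within foods, or realistic price
structure. Passing tests on synthetic plans demonstrate the engine's
selection logic, conservation laws and scoring arithmetic — not that the
packaged menus' unpublished food lists would be selected identically.

## Numerical choices and known data issues

* Published-score comparisons use ±0.2 for FNI scores, ±0.05 USD for
  prices, ±0.1 for daily-mean nutrient rows — the slack the printed
  one-decimal inputs require (the Harvard vitamin D component, for
  instance, recomputes to 65.24 from printed dailies against a printed
  65.1).
* Two printed daily-mean cells are inconsistent with their own printed
  dailies beyond that tolerance: the DASH as-given zinc mean (prints 12.9;
  the seven printed dailies average 13.01, while the substituted-condition
  zinc mean *is* consistent) and the HVEG substituted choline mean (prints
  562.7 vs 562.93 recomputed). Both look like misprints — the published
  means were evidently computed from unrounded source data. The package
  reports these two cells as failures of the daily-mean cross-check, by
  design; `reproduce_menus()`'s overall verdict covers the score and price
  surfaces it reproduces, with the daily-mean comparison reported
  alongside.
* Displayed scores are rounded to one decimal; all computation is at full
  precision. Ties in candidate protein content are broken by menu order.
* All published-value checks run on the 4 × 2 × 7-day fixtures
  (deterministic, < 1 s); engine properties run on 100 seeded synthetic
  plans against a brute-force enumeration oracle; gram-conservation,
  monotonicity and calibration properties use 3–50 seeds each.

## Limitations

Scores are intake-based: bioavailability differences between protein
sources are not modeled. The FNI covers micronutrient adequacy only — no
macronutrient balance, no nutrients to limit. The DRI defaults cover one
life-stage group; supplements (which would distinguish the Total Nutrient
Index from the FNI) are excluded. Food-level conclusions about the four
published menus are limited by the unavailability of their food lists.
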