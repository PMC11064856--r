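---
title: "From feeding visits to home ranges: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From feeding visits to home ranges: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vermivory)
```

This vignette documents the scientific models behind `vermivory`, the
assumptions they rest on, and the numerical and design decisions made
where the underlying field methodology left the choice open.

## The data model

The unit of observation is a **prey item** delivered during a **feeding
visit** of a parent to its nest. Visits are grouped into **sessions**
(one nest on one observation day); each session day carries its recorded
observation hours, cumulative rainfall (mm) and nestling age (days).
Visit tables are interchanged as one-row-per-item CSV
(`visit_csv_columns()` documents the schema) and validated into
coordinated item / visit / day views by `as_visit_data()`.

Prey lengths are estimated in units of beak length to the nearest
quarter unit and converted at 2 cm per beak length, so lengths are
quantised to 0.5 cm. Beak units are the primary stored quantity and
centimetres are derived: the quantisation is part of the measurement
model and survives write/read round trips. Earthworms cut into pieces
before transport ("sundered") are represented as a single item with the
reconstructed pre-sundering length and a piece count.

Categorical derivations, and the conventions chosen where interval
endpoints touch:

* **Visit type.** `NoE` (no earthworm in the load), `OnlyE` (nothing
  but earthworms), `MIX` (both); `YesE = OnlyE + MIX` is derived.
* **Time of day.** Morning [8, 10), noon [10, 14), afternoon [14, 18].
  The half-open-on-the-left convention is ours: the field definition
  gives touching endpoints without assigning them, so 10:00 is "noon"
  and the final instant of the window is "afternoon".
* **Rainfall.** "Heavy" requires the daily total to *exceed* 4 mm, so
  exactly 4.0 mm is "light".
* **Age class.** "Young" broods are 1–7 days, "old" 8–13 days.

Interval-based analyses drop exactly the first visit of every session
(`exclude_first_visits()`), because no preceding inter-visit interval
exists for it.

## Diet statistics

Diet composition uses identified items only: items whose taxon could not
be determined at all ("unknown") stay in the table but leave the
denominator. Length summaries use measured items only and report the
exclusion count; the sample (n−1) SD is used throughout, matching the
"mean ± SD" convention of field studies.

Age effects on earthworm use are tested per nest with a two-sided Fisher
exact test on the young/old × earthworm/other table (item level) or
young/old × OnlyE/other table (visit level), then combined across nests
with Fisher's method: X = −2 Σ ln p ~ χ² with 2k df. Two design points:

* The two-sided p-value uses the dominant *probability-ordering* rule —
  the sum of hypergeometric probabilities no greater than the observed
  table's. The implementation sums `dhyper()` terms with a 1 + 1e−7
  relative tie tolerance; tests verify exact agreement with brute-force
  enumeration over binomial coefficients and with `stats::fisher.test()`.
* Nests in which one age class was never observed carry no information
  about the age contrast; they are excluded with a warning and the
  combined df adjusted. Per-nest p-values are always reported, because a
  combined result driven by a single nest should be visible as such —
  no leave-one-out procedure is applied, only exposure.

## The bioenergetic chain

All constants live in `energetics_params()` and can be overridden.

| parameter | default | units | role |
|---|---|---|---|
| allometry slope / intercept | 3.19 / −15.85 | — | AFDM(g) = exp(3.19 ln L(mm) − 15.85), Megascolecidae |
| fresh : AFDM | 5.7904 | g/g | fresh mass conversion |
| DEE coefficient / exponent | 1092 / 0.729 | kJ/day, kg | DEE = 1092 · BM^0.729 |
| male / female mass | 0.109 / 0.0715 | kg | adult body masses |
| printed pair DEE | 377 | kJ/day | rounded pair total used downstream |
| worm energy density | 16.72 | kJ/g AFDM | energy per gram of worm |
| mean worm AFDM | 0.12258 | g | average single worm |
| provisioning hours | 15 | h/day | daily provisioning window |
| nestling / incubation / nest-building | 12.05 / 14 / 10 | days | stage durations (36.05 total) |
| standard brood | 5 | nestlings | standardized brood size |
| standardized brood consumption | 855 | worms | default brood total |

Two units/rounding decisions matter numerically:

* **Body mass enters the DEE power law in kilograms.** Only this choice
  makes the pair total (217.0 + 159.6 = 376.6 kJ/day) round to the
  published 377; a regression test guards the unrounded value into
  [376, 377.5].
* **Downstream consumption uses the printed integer 377**, not the
  unrounded 376.6: the published consumption equation fixes the pair DEE
  at 377 kJ/day, and only that constant reproduces the family totals
  2,844 and 5,497 worms exactly. Worm counts are rounded half-up to
  integers at the reporting step only; all intermediates keep full
  precision.

The chain: per nest-day, worms delivered (including worms inside mixed
loads) and their summed AFDM are divided by that day's recorded hours;
days with hours but no visits are valid zero-rate days; unmeasured worms
count for numbers but not biomass. Nest-day rates are averaged per nest,
scaled by 15 h/day × 12.05 days to a brood total, divided by brood size,
averaged across the selected nests and scaled to a brood of five
("standardized brood"). The default nest selection drops the nest with
the fewest recorded days (ties: fewest hours), mirroring the use of the
more reliably sampled nests; `nests = "all"` keeps everything. Parent
consumption at earthworm diet share *p* is
p · 377 · 36.05 / (0.12258 · 16.72) worms, linear in *p*; family
consumption adds the standardized brood. Stage-specific energy needs
(egg production, incubation metabolism) are deliberately not modelled —
the single DEE constant is applied across all 36.05 days, an
acknowledged approximation.

## The home-range model

A consumption total N converts to the area containing that many
*available* surfacing worms: A = N / (D · a), with epigeic density D
between 0.53 and 8.7 worms/m² (the range reported for breeding habitats)
and availability fraction a — the share of worms a foraging bird can
actually detect and capture — assumed in [0.005, 0.05]. For each a this
yields a predicted band [N/(8.7a), N/(0.53a)] m²; its intersection
length with the observed home-range band (default 10–30 ha, alternatives
10–20 and 5–20 ha) is integrated over the availability domain.

Numerical choices:

* Integration is a **left-endpoint Riemann sum at step 1e−5** (0.001
  percentage points of availability, 4,500 nodes) on the **linear** area
  scale — log scaling is for plots only. The stated resolution comes
  from the original analysis; the quadrature rule was unspecified, so
  the simplest rule is used and guarded: tests require agreement with a
  piecewise closed-form integral (the integrand is C + D/a between
  band-edge crossings) to 0.2% and < 0.1% change under step halving.
* The **relative overlap index** normalises each scenario's integral by
  the maximum across the evaluated scenario set (brood-only plus family
  at p = 0.3…0.7), per observed-band option. "Theoretical maximum
  overlap" is interpreted as this within-set maximum — it is defined as
  the condition yielding the highest overlap among those compared — and
  whether to take it per band option or globally was unspecified;
  per-band-option is implemented so each band's indices are
  self-contained. Indices are invariant to any global rescaling of the
  integrand, so the choice of measuring intersection length in m² is
  immaterial to the reported percentages.

Assumptions worth keeping in mind: worm density is treated as stationary
(predation by the birds does not deplete it), availability is uniform
across the home range, and the observed band is itself a literature
estimate, not a tracking result.

## The synthetic generator

`generate_visits()` exists so that every stage — validation, summaries,
contingency tests, rates, consumption — runs against data with known
ground truth. It emulates a four-nest study with roughly 230 visits and
650 prey items, with one dataset-level seed and per-nest substreams
derived from it.

What it reproduces, by construction:

* sessions as nest-days with 3–5 h of recording; session bounds defined
  by the first and last visit, as in the field protocol;
* gamma-distributed inter-visit intervals (CV 0.743) whose base mean is
  calibrated **analytically** so the visit-weighted marginal mean is
  35 min (SD ≈ 26) under the configured morning (×0.8) and old-brood
  (×0.85) reductions — shorter intervals when nestlings are hungriest;
* age-conditional visit-type mixtures whose visit-weighted overall
  shares equal 0.648/0.305/0.047 (OnlyE/MIX/NoE), with NoE and MIX
  enriched for old broods;
* 1 + Binom(5, q) worms per OnlyE load with q = 0.35 (light rain) and
  0.25 (heavy), marginal mean 2.6 — fewer worms under heavy rain;
  2 + Binom(5, 0.28) items per MIX load (mean 3.4); single-item NoE
  loads;
* lognormal worm lengths (sdlog 0.38) quantised to 0.5 cm and capped at
  15.5 cm, with a heavy-rain meanlog shift of +0.12 (heavier worms when
  rain brings large worms to the surface) and a count exponent of 0.31 ≈
  1/3.19: because AFDM scales as L^3.19, lengths scaling as k^−1/3.19
  make the expected load biomass flat in worm count, reproducing the
  "constant beak-load biomass" pattern. The base meanlog is solved in
  closed form from the discrete (rain × count) distribution so the
  worm-level marginal mean is 6.34 cm;
* non-earthworm lengths lognormal with mean 3.59 cm; a small fraction of
  unmeasured worm lengths (2%) and unknown-taxon non-worm items (4.5%).

`recovery_report()` compares a generated dataset against these targets
with tolerances of three standard errors plus a small allowance for the
analytic approximations, and checks the two rain-effect directions by
stratified means.

What it does **not** emulate: parental movement and foraging search,
weather autocorrelation across days, between-year effects beyond the
nest level, prey-taxon seasonality, and any mixed-model error structure.
Recovering the configured effect directions by stratified means is
therefore a stand-in for — not a replication of — mixed-model inference
on real data; passing tests show the pipeline computes its statistics
correctly, not that the field system behaves like the generator.

One representational simplification: items of unknown taxon are recorded
with `is_earthworm = 0`, so visit-type classification treats them as
non-worms (earthworms are visually distinctive enough that this is the
plausible field situation); they are excluded from composition
denominators as in the field convention.

## Test problem sizes

The deterministic stages are tested on hand-built fixtures (13 items,
8 visits) and on exact arithmetic cases. Stochastic properties use a
220-session, ~1,600-visit synthetic dataset (20 nests, 11 observation
days each) for parameter recovery, 40 random 2×2 tables with margins
≤ 30 against the enumeration oracle, and 10 random band geometries
against the closed-form overlap integral. The full suite runs in well
under a minute on one CPU.

## Known limitations

* Consumption estimates are scenario grids, not intervals: no
  uncertainty propagation through the allometry, DEE scaling or density
  constants.
* The standardized-brood default (855 worms) and the per-nest brood
  range depend on per-nest field data; with synthetic data the brood
  stage reproduces arithmetic, not those published values.
* The published cross-check of ~70–80 worms/day per brood implies a
  13-day multiplier, slightly inconsistent with the 12.05-day nestling
  stage used in the chain; the discrepancy is inherited, not resolved.
* The home-range model is spatially implicit: no habitat fragmentation,
  patch structure or foraging cost enters the area calculation.
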