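# vermivory

Quantitative tools for studying earthworm-specialist (vermivorous) birds
during breeding: from parental feeding-visit records, through diet
composition and earthworm bioenergetics, to the habitat area a breeding
family needs to find its worms.

The package is written for field ornithologists and conservation
ecologists working with nest-observation data — tables of prey items
delivered to nestlings, one row per item, with visit timing, rainfall,
nestling age and observation effort. It is organised as a pipeline whose
stages are all usable on their own:

1. **Data** — validated readers/writers for prey-item level visit tables
   (`read_visits()`, `write_visits()`, `as_visit_data()`), plus a seeded
   synthetic generator (`generate_visits()`) that emulates the structure
   of a four-nest field study so every downstream stage can be exercised
   and tested without field data.
2. **Diet** — composition and prey-length summaries, visit-type shares
   (`NoE` / `OnlyE` / `MIX` food-loads), and per-nest Fisher exact tests
   of age effects combined by Fisher's method (`composition()`,
   `visit_type_proportions()`, `length_summary()`, `age_contingency()`).
3. **Bioenergetics** — the consumption chain (`brood_consumption()`,
   `parent_consumption()`, `family_consumption()`) built on:
   - earthworm biomass from length (Megascolecidae allometry):
     AFDM (g) = exp(3.19 · ln L(mm) − 15.85), fresh mass = 5.7904 × AFDM;
   - adult daily energy expenditure: DEE (kJ/day) = 1092 · BM^0.729
     with body mass BM in kg;
   - worm currency: 0.12258 g AFDM and 16.72 kJ/g AFDM per average worm.
4. **Home range** — predicted home-range area
   A(a) = N / (D · a) for consumption N, epigeic worm density
   D ∈ [0.53, 8.7] /m² and availability fraction a ∈ [0.005, 0.05]; the
   overlap between this predicted band and the observed home-range band
   is integrated over a (`overlap_integral()`) and normalised across
   consumption scenarios into a relative overlap index
   (`scenario_grid()`).

## Worked example

```r
library(vermivory)

vd <- generate_visits(synthetic_config(), seed = 42)
vd
#> Feeding-visit dataset: 588 prey items in 209 visits,
#>    28 observation sessions across 4 nests
#>   visit types: NoE=9, OnlyE=133, MIX=67
#>   unknown-taxon items: 4 | unmeasured lengths: 8

visit_type_proportions(vd)
#>   visit_type count percent
#> 1        NoE     9     4.3
#> 2      OnlyE   133    63.6
#> 3        MIX    67    32.1
#> 4       YesE   200    95.7
```

About 96% of simulated visits deliver at least one earthworm, matching
the heavily earthworm-dominated provisioning the generator targets. The
consumption chain for a standardized brood of five plus both parents,
across assumed earthworm shares `p` of the adult DEE:

```r
ct <- consumption_table()
ct[ct$scope == "family", ]
#>     scope   p worms   afdm_g  fresh_g
#> 7  family 0.3  2844 348.6609 2018.886
#> 8  family 0.4  3507 429.9459 2489.558
#> 9  family 0.5  4171 511.2308 2960.231
#> 10 family 0.6  4834 592.5158 3430.904
#> 11 family 0.7  5497 673.8008 3901.576
```

A family consumes an estimated 2,844–5,497 earthworms (about 2–3.9 kg
fresh mass) over a full breeding event, depending on how much of the
adult diet is earthworms. Which assumption best matches observed
home-range sizes (here the narrow 10–20 ha option):

```r
scenario_grid(observed_bands = list("10-20 ha" = c(1e5, 2e5)))
#>       scenario   p worms overlap  index
#> 1        brood  NA   855   618.7  13.80
#> 2 family p=0.3 0.3  2844  3207.2  71.53
#> 3 family p=0.4 0.4  3507  3850.1  85.87
#> 4 family p=0.5 0.5  4171  4255.1  94.90
#> 5 family p=0.6 0.6  4834  4457.2  99.40
#> 6 family p=0.7 0.7  5497  4483.8 100.00
```

The predicted area band overlaps the observed home-range band most when
earthworms are assumed to cover 70% of the adult energy budget (index
100, with 60% close behind at 99.4) — indirect evidence that breeding
adults, like their nestlings, are largely vermivorous.

A full run (data → diet → consumption → home range, with all stage CSVs,
a resolved-config snapshot and a plain-text report) is one call:

```r
run_pipeline(pipeline_config(outdir = "pipeline-out", seed = 1))
```

or, from a shell, `Rscript inst/scripts/run_pipeline.R --outdir out --seed 1`.

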