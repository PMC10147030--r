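# nupeval

Multi-criteria evaluation of wild fruit-tree and shrub germplasm for
agronomic exploitation. Traditionally used but commercially neglected and
underutilized plant species (NUPs) — dog rose, cornelian cherry, elderberry,
serviceberry and their kin — are candidate new crops and natural antioxidant
sources; deciding which of a regional collection deserve domestication
effort means turning heterogeneous evidence (molecular authentication of
genotypes, fruit phytochemistry, rooting trials, pilot orchard cultivation)
into comparable species-level summaries. `nupeval` implements that
evaluation chain for breeders, genebank curators and agronomists.

## What it computes

**Multifaceted-potential rubric.** Seven attributes scored 0–5 per species
— molecular authentication (boolean), rooting % of cuttings, antioxidant
activity (%RSA), total phenolic content (mg GAE/100 g), juvenile tree
height at 18 months, % height increase from 6–18 months, and onset of fruit
production — from banded ordinal scales. The species score is

> P = 100 · Σᵢ sᵢ / 35,  sᵢ ∈ {0,…,5},

reported to one decimal (half away from zero). Raw measurements are
averaged across genotypes before scoring; missing data score 0.

**Feasibility and readiness.** Twelve attributes scored against
attribute-specific admissible sets with maximum 6 each (total out of 72),
expressed as a percentage and classified on a readiness timescale:
"already achieved" (> 70 %), "achievable in short-term" (> 55–70 %), or
unclassified below that.

**Trial statistics.** Per-date one-way ANOVA of height across fertilization
treatments with Tukey HSD (Tukey–Kramer for unequal replicates), a
mixed-design repeated-measures decomposition (treatment between subjects,
time within, replicate plant as subject), juvenile growth rates, and
extraction of the rubric's cultivation inputs from long-format trial data.

**Synthetic trials.** A seeded two-level Gaussian generator of replicate
height trajectories and fruiting onsets (presets `rosa-like`,
`cornus-like`, `sambucus-like`), with per-genotype stream splitting, so the
full pipeline is testable without field data.

## Worked example

```r
library(nupeval)

p <- species_profile("Rosa canina", list(
  genotype_measurements("GR-1-BBGK-19,191", rooting_pct = 55, aa_rsa_pct = 90,
    tpc = 160, height_18m = 2.35, growth_rate_6_18 = 21.8,
    fruit_onset_season = 2, genetically_distinct = TRUE),
  genotype_measurements("GR-1-BBGK-19,635", rooting_pct = 80, aa_rsa_pct = 88,
    tpc = 140, height_18m = 2.5, growth_rate_6_18 = 31,
    fruit_onset_season = 2, genetically_distinct = TRUE)))
score_species(p)
#> <multifaceted_scorecard> Rosa canina: total 33/35 (94.3%)
#>     molecular_auth        rooting_pct antioxidant_aa_pct     tpc_mgGAE_100g
#>                  5                  4                  5                  4
#>  tree_height_18m_m    growth_rate_pct        fruit_onset
#>                  5                  5                  5
```

Both genotypes are genetically distinct (5); mean rooting 67.5 % falls in
the (50, 70] band (4); mean %RSA 89 exceeds 85 (5); mean TPC 150 sits at
the top of the (100, 150] band (4); mean height 2.4 m, growth 26.4 % and
fruiting from season 2 all take the top band — a total of 33/35, i.e.
94.3 % of the attainable maximum.

The bundled reference feasibility vectors run through the whole
feasibility/readiness stage:

```r
run_full_evaluation(feasibility_scores = reference_fixtures()$feasibility_scores)
#> <nupeval_report> schema nupeval-report/1 (rubric default)
#> Feasibility / readiness:
#>              species total percentage                         band_label
#> 1        rosa_canina    52       72.2            Already achieved (>70%)
#> 2     sambucus_nigra    51       70.8            Already achieved (>70%)
#> 3         cornus_mas    45       62.5 Achievable in short-term (>55-70%)
#> 4 amelanchier_ovalis    40       55.6 Achievable in short-term (>55-70%)
```

Trial analysis on synthetic data:

```r
d <- simulate_trial(sim_preset("rosa-like", seed = 42))
oneway_anova(d, "SYN-01", 18)          # treatment F at 18 months
tukey_hsd(d, "SYN-01", 18)             # which regimes differ
repeated_measures_anova(d, "SYN-01", 2)  # season-2 treatment/time split
rubric_inputs_from_trial(d)            # heights, growth rates, onsets
```

A thin command-line wrapper ships in `inst/cli/nupeval.R`
(`evaluate`, `simulate`, `trial-analyze` subcommands).

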