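# elnm — eco-linguistic niche modelling

`elnm` asks a biogeographic question about language: *to what degree does
environment predict where a language group lives?* It does so by treating
language territories the way species distribution modelling treats species
ranges. Village localities inside a group's territory become presence
records; a stack of bioclimatic and terrain rasters becomes the covariate
space; presence-only suitability models estimate the group's
**eco-linguistic niche (ELN)** — a [0, 1] suitability grid. Niches are then
compared in environmental space, grouped into **eco-linguistic patterns
(ELPs)**, and summarised into diversity counts, family-level suitability
differentials, and growing-season / ecological-risk grids.

The package is aimed at researchers in biogeography, linguistics and
cultural evolution who want a fully scripted, testable version of this
workflow — including a seeded synthetic-world generator with planted ground
truth, so the entire pipeline can be validated without any data downloads.

## The method in brief

For each group *g* with occurrence environmental vectors `X_g`:

1. **Ensemble** — fit several deterministic presence-only algorithms
   (climate envelopes, envelope fraction scores, environmental-distance
   models) on a training half of `X_g` and predict suitability over the
   study area **M**.
2. **Evaluation** — score each prediction on the held-out half against a
   random background sample: accuracy (ACC), rank-based AUC, and the
   bootstrap partial-ROC ratio restricted to sensitivity ≥ 0.9.
3. **Weighted elitist consensus** — keep the top half of models by AUC and
   add them cellwise with AUC-proportional weights:
   `ELN_g = Σ_m w_m · S_m` with `Σ w_m = 1`.
4. **Omission threshold** — zero all cells below τ, the (⌊s·n⌋+1)-th
   smallest suitability at the held-out occurrences (sensitivity
   s = 0.10).
5. **Niche space** — PCA of the standardised study-area environment;
   niches are projected as clouds of cells with suitability > 0.9 and
   summarised by 61%-coverage inertia ellipses.
6. **Overlap and patterns** — Schoener's `D = 1 − ½Σ|p₁ − p₂|` and
   Hellinger's `I = 1 − ½Σ(√p₁ − √p₂)²` on normalised maps;
   complete-linkage clustering of `1 − D`; ELPs are connected components
   of the graph linking groups with Jaccard range overlap ≥ 0.4 **and**
   D ≥ 0.6, after accessibility filtering (maritime families keep
   sea-connected patches).
7. **Potentials and risk** — family potential = mean suitability over the
   family's groups; `ΔELN = mean(TNG) − mean(Austronesian)` ∈ [−1, 1];
   growing season = number of months with `t > 6 °C` and `prec > 2·t`;
   ecological risk = `1 / MGS`.

## Worked example

```r
library(elnm)

# a 200 x 200 synthetic island world: sea, coastal plain, highland ridge,
# 8 language groups planted in elevation strata, villages with ground truth
world <- generate_synthetic_world(synthetic_world_config(seed = 7))

res <- run_elnm_pipeline(world, seed = 7)

res$elns[["00"]]
#> <suitability_map> group 00, 200 x 200, max 1.000, omission threshold 0.822

res$diversity
#>   elp_label member_ids     families n_groups n_languages
#> 1     ELP 1 00, 01, 02          TNG        3          NA
#> 2     ELP 2     03, 04          TNG        2          NA
#> 3     ELP 3     06, 07 Austronesian        2          NA
#> 4     ELP 4         05          TNG        1          NA

round(res$overlap$d[1:4, 1:4], 3)
#>       00    01    02 03
#> 00 1.000 0.947 0.907  0
#> 01 0.947 1.000 0.910  0
#> 02 0.907 0.910 1.000  0
#> 03 0.000 0.000 0.000  1
```

The three highland groups (00–02) share near-identical niches (D ≥ 0.9) and
form one pattern of diversity 3; the lowland group (05) overlaps nobody and
is a singleton pattern — exactly the planted structure. Against the planted
ground-truth niches this run recovers a mean Schoener's D of 0.83, and the
regional growing season is 11.96 months (ecological risk 1/MGS ≈ 0.084),
the expected near-year-round growing season of a wet equatorial world.

Language counts are `NA` here because the synthetic world plants no
per-group language inventory; with real metadata (see
`load_table1_fixture()` for the packaged 29-group, 17-pattern table) the
same function sums languages per pattern.

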