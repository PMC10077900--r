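# nullcomm

Rank-abundance-matched null models for testing whether a focal plant guild
— root hemiparasites — is associated with more even or more species-rich
plant communities than equally uncommon plants are.

## The problem

Root hemiparasites photosynthesise but also parasitise the roots of
neighbouring plants, preferentially belowground dominants. By suppressing
dominants they can release subordinate species and raise community
evenness. Manipulative evidence for this comes from a handful of taxa and
grassland systems; the observational question at survey scale is whether
natural communities carry the same fingerprint. The confound is rarity
itself: uncommon species of *any* kind tend to co-occur with even,
species-rich communities, so the focal guild must be compared against
random sets of non-parasitic species drawn from the same region of the
global rank-abundance curve.

For a plot-by-species percentage-cover survey, `nullcomm` implements:

* **Community metrics** per plot and growth form (all / herbaceous /
  woody): richness `S`, summed cover, and Shannon evenness
  `E = H / ln S` with `H = -Σ p_i ln p_i` (undefined for `S < 2`).
  Richness is log-transformed and evenness logit-transformed for modelling.
* **A rank-abundance null framework**: global ranks from summed cover;
  null focal sets drawn uniformly from the non-focal species inside the
  guild's rank window; the whole analysis re-run per set.
* **Presence models** on mutual-nearest-neighbour plot pairs within Level
  IV ecoregions (haversine distances; non-mutual and identical-coordinate
  pairs discarded): `response ~ presence + (1|pair) + (1|year)`.
* **Abundance models** on plots containing the (focal or null) set:
  `response ~ ln(summed cover) + (1|year) + (1|park) + (1|ecoregion)`,
  with marginal/conditional R² and an AIC screen — ΔAIC = AIC(without) −
  AIC(with) from ML refits, ΔAIC ≥ 2 counting as support.
* **Empirical significance**: p = proportion of null-set coefficients ≥
  the observed coefficient.
* **A synthetic-community generator** with a known, tunable focal effect
  (`gamma`, acting on a geometric dominance series), used to demonstrate
  type-I calibration and effect recovery end to end.

Models are Gaussian mixed models fitted with lme4 (REML for coefficients,
ML refits for AIC comparisons).

## Worked example

Generate a synthetic survey at the calibrated effect preset (~12,500 plots,
6,987 species, 78 focal taxa occupying ~13% of plots, true effect ~0.19)
and run the abundance analysis with 50 rank-matched null sets:

```r
library(nullcomm)

out <- run_pipeline(pipeline_config(
  generator = list(effect_evenness = 1.05),   # the config_effect() preset
  analyses = "abundance", n_replicates = 50L, seed = 42L,
  responses = data.frame(response = c("evenness", "evenness", "richness"),
                         growth_form = c("herbaceous", "woody", "herbaceous"))))
out$results[, .(response, growth_form, n, beta1 = round(beta1, 3),
                delta_aic = round(delta_aic, 1), empirical_p, p_report)]
```

```
   response growth_form     n  beta1 delta_aic empirical_p                                          p_report
1: evenness  herbaceous  1556  0.173      58.2        0.00 p < 0.02 (0 of 50 null coefficients >= observed)
2: evenness       woody  1553  0.040      -1.1        0.18 p = 0.18 (9 of 50 null coefficients >= observed)
3: richness  herbaceous  1556 -0.021       2.6        1.00   p = 1 (50 of 50 null coefficients >= observed)
```

Reading the rows: on the 1,556 plots containing a focal taxon, logit
herbaceous evenness rises by 0.173 per unit log focal cover; no null set
reached that coefficient (p < 0.02) and dropping the focal term costs 58
AIC units — strong, abundance-dependent support. The woody stratum, which
the generator builds with no focal effect, shows neither AIC support nor
an unusual coefficient. The herbaceous richness row is the instructive
one: its AIC screen nominally crosses the support threshold (2.6), but the
coefficient is negative and *every* null set matched or exceeded it
(p = 1.0) — rank-matched nulls are exactly what separates a structural
association of rarity from a guild-specific signal.

The same pipeline runs on real data from three CSVs (`cover.csv`:
plot_id, species_id, stratum, cover; `species.csv`: species_id, genus,
growth_habit, is_hemiparasite, life_history; `plots.csv`: plot_id,
latitude, longitude, area_m2, year, park_id, ecoregion_l4) via
`pipeline_config(mode = "files", paths = list(...))`.

The numbered scripts under `analysis/` run the full study workflow on a
generated survey: `01_simulate.R` (build the dataset), `02_presence_analysis.R`
(mutual-NN pairing and presence contrasts), `03_abundance_analysis.R`
(abundance models plus top-10 / ranks-11-20 / genus subset reruns),
`04_calibration.R` (type-I error and effect recovery). Each writes its
tables under `results/`.

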