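# maculadev

Colocalised structural change across macular retinal layers in glaucoma,
from en-face OCT thickness maps.

Glaucoma primarily damages retinal ganglion cells, thinning the ganglion
cell–inner plexiform layer (GCIPL). Whether that damage propagates upstream
— a measurable thinning of the inner nuclear layer (INL), or any consistent
change in the outer retinal complex (ORC) — is hard to see in conventional
subfield averages, because normal between-eye variability swamps the small
effects and coarse grids pool damaged and spared locations. `maculadev`
implements a high-resolution deviation-mapping pipeline that addresses both
problems:

1. **Standardisation** — raw 512×128 macular cube thickness maps
   (6.00 × 6.00 mm) are resized to 512×512 (bicubic), converted to
   right-eye format, rotated about the fovea to zero disc-to-fovea tilt,
   and (ORC only) re-aligned to their inner-retinal partners with an
   eccentricity-dependent radial displacement profile.
2. **Normative modelling** — per-layer multiple linear regression of mean
   thickness on age, spherical equivalent (SE) and sex in a healthy cohort,
   with one round of backward stepwise elimination (a removed effect is
   reinstated if any retained coefficient shifts by ≥ 10%). The final
   covariate set decides which variables are *matched* downstream.
3. **Deviation maps** — each glaucoma eye is compared against the mean map
   of its demographics-matched healthy subgroup (±7.5 y, ±2.00 D, same sex
   where required); raw µm differences are averaged over 8×8-pixel blocks
   into a 64×64 grid of 93.75 µm cells.
4. **Topographic clustering** — per (visual-field defect type × MD bin)
   stratum and layer, grid cells are clustered by agglomerative
   *within-groups* linkage on squared Euclidean distance; a
   likelihood-based BIC picks the starting count and cluster pairs are
   merged while their separability

   d′ = |x₁ − x₂| / √(0.5 (σ₁² + σ₂²))

   is below 1, so every final cluster pair is at least one pooled SD apart.
5. **Agreement and severity** — clusters are *defective* when their mean
   deviation is negative and below the macula-wide average; binary
   defective maps are compared between layers with percentage agreement and
   Cohen's κ, and per-participant within/outside-defect differences and
   cross-layer Spearman correlations are correlated globally with 10-2
   visual field MD and PSD.

Visual fields are classified with the Hodapp–Parrish–Anderson cluster
criterion (≥3 contiguous points at p<5%, ≥1 at p<1%) into clear / inferior /
superior / ring types, stratified by MD in 3 dB bins.

Because no clinical data ship with the package, a first-class synthetic
cohort generator (`simulate_cohort()`, `synth_thickness_map()`,
`synth_vf()`) produces healthy and glaucomatous eyes with known ground
truth — eccentricity-dependent layer profiles, linear age/SE/sex effects,
spatially correlated noise, arcuate GCIPL defects with attenuated INL
involvement, and matching visual fields — so every stage is testable end to
end.

## Worked example

```r
library(maculadev)

res <- run_pipeline(default_pipeline_config(seed = 1), out_dir = "demo_run")
print(res$agreement, digits = 3)
```

```
  stratum layer_pair percent_agreement kappa p_value    n
1  I.bin1  GCIPL-INL              95.4 0.858       0 3624
2  I.bin1  GCIPL-ORC              77.8    NA      NA 3644
3  I.bin1    INL-ORC              81.8    NA      NA 3600
4  S.bin1  GCIPL-INL              78.7    NA      NA 3824
5  S.bin1  GCIPL-ORC              78.8    NA      NA 3840
6  S.bin1    INL-ORC             100.0    NA      NA 3804
```

Read: in the inferior-defect stratum (8 eyes) the defective-GCIPL and
defective-INL cell maps agree on 95% of the grid cells (κ = 0.86): the
planted, attenuated INL defect colocalises with the GCIPL defect. The ORC
map contains no defective cluster at all, so κ against the ORC is
undefined and reported `NA` — the generator planted no ORC change and the
pipeline found none. In the superior-defect stratum the INL deficit stays
below the d′ separability criterion at this cohort size, so its map is
single-category too: with eight eyes per stratum an attenuated ~3 µm
deficit sits at the detection edge, which is exactly the behaviour the
replicated recovery experiments quantify at n = 20. The run directory
contains every table (strata, normative models, cluster stats, agreement,
severity correlations), the 64×64 label maps, a log, and a JSON provenance
record; rerunning with the same configuration reproduces every number
exactly.

Individual stages are exported too — `standardise_map()`, `classify_vf()`,
`fit_normative_model()` + `backward_stepwise_elimination()`,
`cohort_deviation_grids()`, `cluster_deviation_grids()`,
`layer_agreement_table()`, `participant_severity_table()` — see the methods
vignette (`vignettes/macular-deviation-mapping.Rmd`) for the model details
and design choices.

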