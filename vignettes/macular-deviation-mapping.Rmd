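---
title: "Macular deviation mapping and layer-cluster agreement: models and design choices"
author: "maculadev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macular deviation mapping and layer-cluster agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maculadev)
```

This vignette documents the models behind `maculadev`, the tunable
parameters and their defaults, what the synthetic cohort generator does and
does not emulate, and the numerical and design decisions that were
genuinely open. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The scientific question and the pipeline

Glaucomatous damage begins at the retinal ganglion cells, so the ganglion
cell–inner plexiform layer (GCIPL) thins first. If degeneration propagates
trans-synaptically, the inner nuclear layer (INL) — bipolar, amacrine,
horizontal and Müller cell bodies — should thin in *the same macular
locations*, while the outer retinal complex (ORC, outer nuclear layer
through retinal pigment epithelium) should not change consistently. Testing
colocalisation needs (i) per-location comparisons at high sampling
resolution rather than subfield averages, and (ii) suppression of normal
between-eye variability, which is larger than the effect of interest in the
INL.

The pipeline therefore expresses each glaucomatous eye as a *deviation map*
— its thickness minus the mean of demographics-matched healthy eyes, in raw
micrometres — pools deviation grids within strata of similar visual-field
damage, partitions the macula into statistically separable clusters, and
quantifies between-layer agreement of the defective regions.

## Map standardisation

Raw macular cubes sample a 6.00 × 6.00 mm field at 512 × 128 pixels.
Standardisation is a fixed sequence, each step recorded in the map's
provenance:

1. *Thickness extraction*: `(lower − upper) × axial scale`; the axial scale
   defaults to 2000/1024 ≈ 1.953 µm/pixel (2.0 mm imaging depth over 1024
   axial pixels) and is configurable. A-scans with flagged segmentation
   errors become invalid pixels and never re-enter any statistic.
2. *Resize* to 512 × 512 by cubic-convolution (Keys, a = −0.5)
   interpolation along the slow axis. The kernel reproduces constants and
   linear ramps exactly, which the test suite asserts. Validity is eroded
   conservatively: an output pixel is invalid if any source pixel in its
   interpolation support is invalid.
3. *Right-eye conversion*: left eyes are mirrored about the vertical axis
   (fovea x and tilt sign updated), so column 0 is temporal retina and row
   0 superior retina for every eye. Coordinates are 0-based and the fovea
   is a continuous (column, row) position.
4. *Tilt-zero rotation* by minus the disc-to-fovea tilt about the foveal
   centre, bicubic resampling. A pixel at polar angle θ before rotation
   appears at θ − tilt afterwards.
5. *Displacement correction* (ORC only): each pixel is resampled from
   eccentricity `e + d(e)` along its own meridian — an outward
   (centrifugal) remap that brings outer-retina content into register with
   its displaced inner-retinal partners. The profile `d(e)` is a
   meridian-averaged table shipped as an editable CSV
   (`inst/extdata/displacement_profile_synthetic.csv`, a representative
   synthetic curve peaking near 2.2° at ~1.5–2° eccentricity and decaying
   to zero by ~12°); per-meridian tables can be supplied by calling the
   correction once per sector. Degrees convert to retinal millimetres at
   0.288 mm/° (configurable).

Numerical rules: no extrapolation — a resampled pixel is invalid if any
interpolation tap falls outside the field or on an invalid pixel; the
valid-pixel count therefore never increases through the pipeline (asserted
in tests). Whether the original study displaced the ORC inward or pulled
the partner layers outward is not decidable from its description; the
outward convention is fixed here and exposed through the profile.

## Visual field classification

The 10-2 lattice is the 68 points with odd-degree coordinates within 10°
of fixation. Defects follow the Hodapp–Parrish–Anderson reading: a
qualifying cluster needs ≥ 3 *contiguous* flagged points (p < 5% or worse)
with ≥ 1 at p < 1% or worse. Decisions that the criterion leaves open:

- **Contiguity** is 8-connectivity on the 2° lattice (diagonal neighbours
  count) — the common clinical reading.
- **Encroaching points count** toward the 3-point minimum: the defining
  feature of a superior/inferior defect is that at most one point crosses
  the horizontal midline, not that the crossing point is discarded.
- **Arcuate** ("greater loss nasally than temporally") is operationalised
  as: the hemifield cluster contains nasal points and its mean pattern
  deviation over nasal points is at least as negative as over temporal
  points. A visibility judgement cannot be coded verbatim.
- **Ties** for "larger cluster" go to the cluster with the more negative
  mean pattern deviation.
- **MD bins** are 3 dB wide with boundaries closed on the worse side
  (MD = −3.00 falls in the −3 to −6 bin).

## Normative demographic model

Per layer, ordinary least squares of scan-mean thickness on age (years),
SE (dioptres) and sex (female = 0, male = 1), followed by **one** round of
backward elimination: drop the least significant effect, refit, and compute
`|Δβ|/|β_pre|` for every retained coefficient. If any change reaches 10%,
the dropped effect was masking shared variance and is reinstated. The final
covariate set is exactly the set matched when building normative subgroups.
Percent changes use the pre-removal coefficient magnitude as denominator;
only a single elimination round is performed because the decision feeding
the matching step is which covariates *must* be controlled, not a minimal
model.

## Deviation maps

For each glaucoma eye and layer: healthy participants within ±7.5 years and
±2.00 D (and of the same sex when the normative model retained sex) form
the matched subgroup; their standardised maps are averaged per pixel (a
pixel's mean uses only the maps where it is valid); the difference
glaucoma − normative mean is taken in raw µm — deliberately *not* percent
of normal, which would exaggerate differences near the foveal pit and
peripheral macula where absolute thickness approaches the measurement
floor. The 512 × 512 deviation map is block-averaged over 8 × 8 pixels into
a 64 × 64 grid of exactly 93.75 µm cells (asserted in code), anchored at
pixel (0, 0). A cell is valid when ≥ 50% of its 64 pixels are valid — the
source exclusions are pixel-wise and no block-level rule is canonical, so
the majority rule is the package's choice. Subgroups smaller than 3 are
flagged with a warning; a participant present in its own healthy pool is
excluded from its subgroup. The cohort-level driver additionally requires
each normative pixel to be supported by at least `min_subgroup`
contributing maps: after tilt rotation the field corners of different
healthy eyes do not coincide, and a corner pixel resting on one or two
maps carries that eye's subject-level variability (several µm) into every
deviation map of the stratum as a shared artefact, which the clustering
stage would faithfully pick up as a spurious cluster.

## Clustering: within-groups linkage, BIC start, d′ refinement

The feature clustered is, by default, the *subcohort mean deviation per
grid cell* (a scalar per location), because the quantities reported per
cluster — mean ± SD in µm — are statistics over locations. A per-location
*vector* mode (one entry per participant) is available behind the
`feature = "vector"` flag for users who prefer clustering the raw
participant profiles; the scalar mode is the default.

**Linkage.** Agglomerative *within-groups average linkage* on squared
Euclidean distance: the next merge minimises the mean pairwise squared
distance over all pairs inside the merged cluster. For a candidate union
with m members, sufficient statistics give the pair sum as
`m·Σ||x||² − ||Σx||²`, so each candidate cost is O(1) and nearest-neighbour
costs can be cached exactly (a pair's cost depends only on the two
clusters' statistics). Ties break in cluster-index order. The test suite
checks the full merge sequence against a brute-force oracle that rescans
the complete distance matrix at every step.

**Starting count.** For each k up to `k_max` (default 10) the tree cut is
scored by the BIC of a Gaussian classification model with cluster-specific
means, a pooled variance, and multinomial mixing proportions:
`logL = Σ_k n_k log(n_k/n) − n/2 (log 2πσ² + 1)`, `BIC = −2 logL + 2k log n`.
The mixing-proportion term matters: without it, every split of a
one-dimensional cut that shaves a few percent off the pooled variance pays
back its penalty, the criterion runs to `k_max` on clean two-component
data, and the d′ refinement — which can only merge — inherits a
systematically inflated start. With proportions included, two well
separated components yield k₀ = 2.

**Refinement.** From the k₀ cut, the pair with the smallest
`d′ = |x₁ − x₂|/√(0.5(σ₁² + σ₂²))` is merged while that d′ < 1 (smallest
first; the criterion itself does not prescribe an order), recomputing all
statistics after each merge. Every finalised solution therefore satisfies
min pairwise d′ ≥ 1, i.e. cluster means at least one pooled SD apart —
asserted on every solution the pipeline produces. Degenerate cases: two
zero-SD clusters with equal means have d′ = 0, with unequal means d′ = ∞.
Labels are ordinal, 1 = most positive mean deviation. Cells excluded by the
validity rule carry label 0 and never enter statistics.

## Agreement and severity

A cluster is **defective** iff its mean deviation is negative *and* below
the macula-wide mean deviation of the subcohort grid; both conditions are
required, so a mildly-below-average but thickened region never counts.
Binary defective maps are compared per layer pair over the cells valid in
both layers: percentage agreement, Cohen's κ with chance agreement from the
marginals, and a p-value from the large-sample normal approximation (the κ
variance under the null of chance agreement). κ is reported `NA` whenever
either map is single-category — in particular when a layer has *no*
defective cluster, which is the expected outcome for an unchanged layer and
must not be conflated with κ = 0.

Per participant: the mean deviation inside minus outside the
defective-GCIPL mask of the participant's (defect type × MD bin) stratum,
for each layer; and Spearman correlations between layer pairs across the
whole 64 × 64 grid (not pooled over clusters). Participants whose stratum
has no defective GCIPL cluster contribute no difference values and are
counted in logs. Globally, each of the six per-participant quantities is
rank-correlated (mid-rank ties, t-approximation p-values) against 10-2 MD
and PSD. Spearman rather than Pearson because MD and PSD are far from
normal across a glaucoma cohort.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults define the
conditions under which the validation experiments run.

**Demographics.** Healthy cohorts: age from a truncated normal
(50.4 ± 16.9 y on 20–86), 45.3% male; glaucoma cohorts 64.4 ± 11.5 y on
27–88, 59.8% male. SE is generated with structure, not independently:
`SE = −0.55 + 0.0458·(age − mean age) − 0.55·(male) + N(0, 1.77)` D,
truncated to ±6 D — an age-related hyperopic drift and a modest male
myopia offset whose magnitudes are chosen so that the age–SE–sex
collinearity is strong enough for backward elimination to behave as it
does in real cohorts (dropping a genuinely contributing covariate visibly
shifts its partners), while the total SE spread stays ≈ 1.9 D. Disc-to-
fovea tilt is Gaussian (≈ 6.9 ± 3.4°), laterality Bernoulli(½).

**Layers.** Expected thickness at a pixel of eccentricity e (mm) is
`baseline(e)·(1 + γ) + β_age (age − 50) + β_SE·SE + β_sex·[male] + b`,
with piecewise-linear radial templates per layer (foveal pit, perifoveal
peak, peripheral decline — editable via `baseline_profiles()`), slopes
β set per layer at GCIPL (−0.112 µm/y, 0.513 µm/D, 0), INL (−0.039, 0.258,
0) and ORC (−0.078, 0.437, −1.953 µm male–female) — magnitudes
representative of adult normative cohorts. Between-subject variability has
two components: a profile-shape scaling γ ~ N(0, 0.03), giving healthy
deviation fields a smooth eccentricity-dependent structure (real normal
eyes differ in profile shape, not just offset), and a flat intercept
b ~ N(0, σ_layer) with σ chosen per layer (3.83, 0.94, 2.57 µm) so the
*total* SD of scan-mean thickness is ≈ 4.3, 1.4 and 5.9 µm — the spread
that makes an n = 548 regression recover its coefficients with realistic
standard errors. Map noise is smoothed white noise with a stated Gaussian
correlation length (default 0.25 mm, SD 2 µm): per-pixel independent noise
would make 8 × 8 block averaging unrealistically powerful.

**Defects.** An arcuate mask (inner/outer eccentricity, angular extent
about the vertical meridian of the chosen retinal hemifield) subtracts
`gcipl_depth` from the GCIPL, `inl_ratio × gcipl_depth` from the INL
(attenuated colocalised involvement), and adds `orc_delta` (0 or small
positive) to the ORC. The mask is evaluated analytically in the eye's
*native* orientation — pre-rotated by the recorded tilt and mirrored for
left eyes — so the preprocessing stage genuinely inverts the generator
(round-trip asserted within interpolation tolerance). The matching visual
field puts pattern deviation −`vf_depth` on the points whose retinal
projection (vertical flip) falls inside the mask. MD is the mean total
deviation and PSD the SD of the pattern deviations — simplified,
unweighted analogues of the perimeter's indices, used because the
proprietary per-point weights are unavailable; consequently the synthetic
PSD does not reproduce the saturation of the clinical index in advanced
loss (its magnitude stops growing once defects become deep and uniform),
and no conclusions about that regime are drawn from it. Probability flags
come from fixed dB thresholds (defaults −3/−5/−6.5/−8 for p5/p2/p1/p05).

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: OCT speckle and signal-strength-dependent
segmentation bias, microcystic macular oedema, vessel shadowing (dropout
is available but random), the temporal raphe's individual position,
non-linear ageing, measurement floors, and clinically realistic MD ranges
in advanced disease.

## Validation experiments and problem sizes

Three replicated experiments back the acceptance checks; their sizes are
the package's chosen defaults and are stated here so results can be read in
context.

- **Regression/elimination recovery** (`run_normative_recovery_experiment`):
  replicate healthy cohorts of n = 548 at the scan-mean level; reports the
  fraction of fitted coefficients within 2 SE of truth and the rate at
  which elimination lands on {age, SE} for GCIPL/INL and {age, SE, sex}
  for the ORC. The ORC pattern is intrinsically stochastic: whether SE or
  sex is the least significant term is a near coin-flip at these effect
  sizes, and both removal paths must then trigger the 10% reinstatement
  rule, so the expected pattern rate is ≈ 0.9, not 1.
- **Planted-defect recovery** (`run_defect_recovery_experiment`): 50
  replicates of a 20-eye glaucoma subcohort (10 µm inferior-retina GCIPL
  arc, INL ratio 0.3, ORC untouched, map noise 2 µm) against a 15-eye
  matched healthy pool, with eyes generated at zero tilt: the experiment
  probes the deviation/clustering/agreement stages, the radial baseline
  makes rotation a no-op in expectation, and the rotation/mirroring
  operators carry their own round-trip tests. Reported: visual-field
  typing, Dice overlap of the most-negative GCIPL cluster with the planted
  mask, κ for GCIPL–INL, and the ORC outcome. With a truly unchanged ORC
  the usual outcome is that *no* ORC cluster is defective (the cohort-mean
  ORC deviation field is featureless), so the GCIPL–ORC κ is undefined
  rather than small — the experiment counts that as the strongest possible
  evidence of no colocalised ORC change.
- **Severity gradient** (`run_severity_experiment`): 60 glaucoma eyes with
  GCIPL depth growing 2→16 µm and VF depth 6.6 + 0.25·depth dB. The VF
  mapping deliberately keeps the whole cohort inside a single defect-type/
  MD stratum: with one shared defective-GCIPL mask, a severity-independent
  layer's within/outside difference is exchangeable across participants
  and its global correlation with MD has the textbook null distribution;
  letting the cohort straddle strata superimposes mask-specific offsets
  that masquerade as severity trends. Expected directions: within/outside
  differences for GCIPL and INL correlate positively with MD and
  negatively with PSD; the ORC stays inside the two-sided 95% null band.

`run_pipeline()` chains every stage from one configuration (R list or YAML
file), writes all tables, label maps, a log and a JSON provenance record,
and is bit-reproducible for a fixed configuration.

## Known limitations

Single elimination round (by design); scalar clustering features by
default; the simplified PSD; the synthetic displacement profile is
representative rather than measured; agreement is computed only on cells
valid in both layers; no spatial-contiguity constraint on clusters (the
method's clusters may be spatially disjoint, which is intended); and the
cross-sectional framing — nothing here speaks to the time course of
trans-synaptic change.
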