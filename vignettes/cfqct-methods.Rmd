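---
title: "Quantitative CT of airway disease and air trapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT of airway disease and air trapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfqct)
```

cfqct implements a lobe-resolved quantitative-CT (QCT) analysis of early
cystic fibrosis lung disease and exercises it end to end on synthetic
phantoms with exact ground truth. This vignette explains the measurement
models, the generative models behind the phantoms and the simulated
cohorts, the numerical choices, and what the passing test suite does and
does not establish about real clinical data.

## Airway cross-section measurement

Airway geometry is measured on planes orthogonal to the branch centerline.
On each plane the measurement casts `n_rays` (default 64) rays outward from
the lumen point and locates, per ray, the inner and outer wall borders by
the full-width-half-maximum (FWHM) convention: the inner border is the
half-rise position between the lumen attenuation and the wall peak, the
outer border the half-fall position between the peak and the parenchymal
plateau, both refined by linear interpolation between radial samples
(default 0.1 mm). The lumen area LA and the outer area are polygon areas
through the retained border points, WA is their difference, and

* WP = 100·WA/(LA + WA),
* TD = 2·√((LA + WA)/π),
* WT = (TD − 2·√(LA/π))/2

hold exactly, by construction, on every emitted section — the
equivalent-circle convention, chosen over per-ray chord averaging for its
robustness to single-ray noise.

Two numerical choices matter at clinical voxel sizes (0.5–0.6 mm) and are
worth stating openly. First, the section plane is resampled with Keys
cubic-convolution interpolation rather than trilinear interpolation:
trilinear blur is comparable to the voxel size, and for walls at or below
one voxel it attenuates the wall peak, which drags both half-maximum
crossings toward the wall centre (lumen underestimated, wall thickness
overestimated by 0.1–0.2 mm in phantom experiments). Second, the wall
attenuation entering the half levels is a section-level reference — the
90th percentile of the per-ray peak values — rather than each ray's own
peak. Peak attenuation varies with the sub-voxel phase of the wall
relative to the lattice; rays whose peak sample lands near the true wall
centre recover it almost fully, so a high quantile across 64 rays is a
nearly unbiased estimate of the wall material attenuation, while each
ray's own (possibly attenuated) peak still gates the minimum contrast
(default 100 HU) and anchors the outer-border search. With both choices,
noise-free cylinder phantoms with lumen 2–8 mm and wall 0.5–1.5 mm at
0.5–0.6 mm spacing are recovered with lumen-diameter and wall-thickness
errors below 0.3 mm — the conventional resolvability bound for airway
measurements around 2 mm lumen diameter.

Rays that find no sufficiently contrasted peak or no plateau crossing
within `max_radius_mm` are discarded; a section is invalid when more than
25% of rays fail. Sections are sampled every 1 mm along the centerline,
excluding 2 mm at either end of a branch so bifurcation geometry does not
contaminate the medians; per-branch geometry is the median over valid
sections, and regional aggregates (generations 5–10 by default, per lobe
or total lung) are medians over all pooled valid sections, so branches
contribute proportionally to their measured length. Medians were chosen as
the aggregation statistic because the descriptive layer of the analysis is
median/IQR throughout; an empty selection is reported as missing, never as
zero.

## Bronchiectasis index

Bronchiectasis is irreversible airway dilatation, visible in QCT as a
failure of tapering. For every measured parent–child pair with child
generation ≥ 3 the tapering error is
e = max(0, (LD_child − κ·LD_parent)/LD_parent) with lumen diameters from
the equivalent circle, and the regional BEI is the **sum** of errors over
pairs whose child lies in the region. Summation (not averaging) makes
lobar indices additive and the total-lung value the sum of its parts. The
reserve factor κ defaults to 1 (any child wider than its parent counts)
and is configurable. The exact error formula used by clinical software is
not published in a reproducible form; this definition is a declared
stand-in that preserves the properties the analysis relies on: exactly
zero on a strictly tapering tree, one violation of size r − 1 for a child
dilated to r times its parent, additivity over independent dilations, and
monotonicity in any single lumen.

## Air trapping on paired scans

All trapping metrics are pure histogram statistics over masked voxels, so
no inspiratory–expiratory registration is needed (or performed; lobe masks
are taken as given). With inclusive band edges for bit-exact counts:

* RVC<sub>856–950</sub> = RV_E − RV_I, where RV is the fraction of
  non-emphysematous voxels (> −950 HU) lying in [−950, −856] HU; range
  −1 to 0, values nearer 0 mean more trapping.
* E/I MLA = mean expiratory HU / mean inspiratory HU; range 0–1, larger
  means more trapping.
* A1–A3: percentages of analysed expiratory parenchyma at or below three
  patient-specific thresholds T_k = MLA_I + f_k (MLA_E − MLA_I), with
  f = (0.75, 0.50, 0.25) by default and the total-lung MLAs shared by all
  lobes of one patient, so A1 (liberal, mild) ⊇ A2 ⊇ A3 (stringent,
  severe) by construction. The published threshold scheme behind the
  original A-parameters is not reproducible from the literature available
  here; this interpolated scheme is a configurable stand-in that preserves
  the contract: patient-specific, three nested severities, defect size as
  a percentage of analysed parenchyma.

## Synthetic data: what it emulates and what it does not

**Airway phantoms.** Branches are straight cylindrical tubes (air lumen,
soft-tissue wall annulus, parenchymal background; defaults −1000/0/−850
HU). Rasterization splits every voxel into 3×3×3 subsamples and averages
the material attenuations, producing the graded partial-volume edges on
which half-maximum detection is meaningful — FWHM would be ill-defined on
binary-edged tubes. Optional Gaussian noise models quantum mottle. The
six-lobe tree (trachea G1, two mains G2, six lobar entries G3, tapering
chains to G6) spreads its lobar chains widely in 3-D so sibling tubes
clear each other within the entry branch; entry branches are longer
(12 mm) than deeper ones (8 mm) for the same reason. Dilations with known
ratio can be planted per lobe and generation.

**Paired lung phantoms.** Inspiratory parenchyma is N(−850, 50) HU,
expiratory normal tissue N(−650, 50) (the lung densifies on expiration),
planted defects N(−900, 30) — air that stays trapped. These means sit at
the middle of the attenuation ranges seen in school-age CF cohorts, and
the no-defect expectation E/I MLA = 650/850 ≈ 0.765 brackets the clinical
medians (≈ 0.64–0.68). Defects are spheres (default radius 3 mm) placed by
rejection sampling strictly inside one lobe — mimicking the contiguous
regional defects the A-parameters quantify — with the last sphere trimmed
from the outside in so the planted voxel count matches the target fraction
exactly; the realized fraction is recorded as ground truth. Lobe geometry
is six disjoint boxes: histogram metrics need labelled disjoint regions,
not anatomical shape.

**Cohort simulator.** The generative model mirrors the mixed model the
statistics fit: for each endpoint,
y = β₀ + β_age·age + β_A3·A3 + β_t + u_patient + u_region(patient) + ε,
on the response scale for linear endpoints (BEI, LA) and on the logit of
the proportion for the beta endpoint (WP), whose response is drawn from a
beta distribution with precision φ. The balanced design is 36 subjects ×
4 visits (0, 3, 12, 24 months) × 6 regions = 864 rows; baseline age is
Uniform(8, 16) years so the coefficient scale matches a school-age cohort
with median age near 12, and age advances 0/0.25/1/2 years with the visit
schedule. Default coefficients take the magnitudes of the fitted
cross-sectional models (age→BEI 0.046, A3→WP 0.004 on the logit, and so
on). A3 is drawn from a gamma distribution (shape 1.5, scale 3; median
≈ 3.5%, right-skewed) — lobar A3 distributions are only summarized as
medians and IQRs in the clinical literature, so this choice is
configurable and not claimed to match any cohort. Latent random effects
and linear predictors are recorded in `.`-prefixed columns for test
introspection.

What passing tests show: the estimators recover known truth under the
stated generative families, exactly where exactness is claimed and within
stated tolerances elsewhere. What they do not show: performance under real
scanner physics (reconstruction kernels, beam hardening, motion), real
airway geometry (curved, elliptic, mucus-obstructed airways), real lobe
shapes, or misspecified cohort models.

## Statistical layer

Descriptives are median/IQR (type-7 linear-interpolation quantiles) for
continuous variables and absolute/relative frequencies for binary ones.
Friedman tests use average-rank ties; for designs with at most 10⁵
within-subject orderings the P-value comes from the exact permutation
distribution (computed by convolving per-subject rank distributions),
otherwise from the chi-square reference — the exact branch exists because
at the cohort's size (36 × 4) the chi-square reference is used, but the
package's own validation demands exact agreement with enumeration on
small designs. McNemar uses the classical Edwards continuity correction
(|b − c| − 1)²/(b + c); Wilcoxon–Mann–Whitney enumerates exactly for
groups of at most 8 without ties and otherwise uses the tie-corrected
normal approximation. Pearson correlation maps pool all time points and
lobes, attach Fisher-z 95% intervals, adjust all off-diagonal cells by
Benjamini–Hochberg, and attach verbal ratings (|r| < 0.2 very weak,
0.2–0.4 weak, 0.4–0.6 moderate, 0.6–0.8 strong, ≥ 0.8 very strong).

**Mixed models.** The cross-sectional model is
`endpoint ~ age + A3 + timepoint + (1 | patient) + (1 | patient:region)`.
"Patient and lung regions" as random effects is realized as
region-within-patient (not crossed) intercepts, because regions are
repeated measurements nested in a patient. Linear endpoints are fit by
REML (lme4); the wall percentage is fit as a logit-link beta mixed model
(glmmTMB, Laplace approximation) on the shrunk proportion
(y·(n − 1) + 0.5)/n, and its coefficients are reported on the logit scale,
which every report header states. "Robust" (the default) means Huber
weights (c = 1.345) on scaled Pearson residuals, iterated to fixed-effect
convergence (relative tolerance 10⁻⁴, at most 12 refits) — the estimator
is a documented choice, switchable to plain REML, since robust mixed
estimation has no single canonical definition. Confidence intervals and
P-values for the linear family use Satterthwaite denominator degrees of
freedom (lmerTest): Wald-normal intervals are anti-conservative for
between-patient effects at 36 clusters. All P-values are descriptive; no
multiplicity correction is applied inside model reports.

The longitudinal model regresses the endpoint at the later visit of an
interval on age, A3 and the endpoint itself at the earlier visit, with the
same random-intercept structure. With one pair per patient-region cell the
cell variance is confounded with the residual and is estimated at the
boundary; such fits are flagged `singular` rather than silently
restructured, keeping the declared random-effects specification. A
baseline coefficient near 1 means the regional pattern tracks unchanged;
simulation harnesses verify both pure tracking and the recovery of a
carry-over effect present only over a short interval.

Parameter-recovery simulations at the design size (36 × 4 × 6) show 95%
interval coverage of ≈ 94–95% across replicate blocks for the age effect
on BEI, and coverage of zero at the nominal rate under a null A3 effect;
the test suite asserts ≥ 90/100 at fixed seeds.

## Pipeline

`run_pipeline()` chains phantom generation → airway measurement → air
trapping → cohort statistics from a single YAML config whose defaults
equal the package-wide parameter defaults, with validation before any
compute (e.g. threshold fractions must decrease strictly, longitudinal
intervals must lie on the visit schedule). Per-subject disease is planted
by the config: dilation probability and ratio range for bronchiectasis,
subject-level defect fractions for trapping; airway calibre grows 4% per
year so lumen areas rise with age while the ratio-based BEI stays
unaffected — the growth-independence that motivates a tapering index.
Airway phantoms add 15 HU noise so repeated visits differ realistically.
The QC stage applies the breath-hold consistency rule — consecutive total
lung volumes within 5% relative change (10% as a laxer published bound) —
to every subject's series. Every run writes a manifest (config, seed,
package version, MD5 of each output); reruns with the same config and seed
are bit-identical, which the tests verify at a reduced size (3 subjects ×
2 visits) and the bundled demo config exercises at 8 subjects × 4 visits.
All randomness flows from explicit per-call seeds derived from the run
seed; the session RNG is never touched.

Problem sizes used by the validation suite — a 30-tube accuracy grid,
100-phantom nesting checks on 20×20×27 grids, 100-replicate recovery
simulations at the 864-row design, and the reduced determinism run — were
chosen so the full suite exercises every contract at desk scale.

## Known limitations

* Airway segmentation of raw volumes is a phantom-grade HU-threshold
  region grower with a wavefront leak guard; clinical-grade segmentation
  is explicitly out of scope, as are DICOM reading, deformable
  registration and spirometry reference equations (predicted percentages
  are consumed as given covariates).
* The BEI error term and the A1–A3 threshold construction are declared
  stand-ins for unpublished clinical-software internals (see above).
* FWHM wall measurement retains a small residual bias for walls thinner
  than the voxel (up to ≈ 0.2 mm at 0.5 mm walls on 0.6 mm voxels).
* Beta-family robust weighting reuses the Huber scheme on Pearson
  residuals; alternative robust beta estimators exist and none is
  canonical.
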