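---
title: "Quantifying choriocapillaris flow deficits and the influence of large choroidal vessels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choriocapillaris flow deficits and the influence of large choroidal vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfdq)
```

## The measurement problem

The choriocapillaris (CC) is the capillary bed directly beneath the Bruch's
membrane / RPE complex. Its capillaries (intercapillary distance ~24 um at
the posterior pole) are below the ~14 um lateral resolution of current
OCT angiography devices, so CC perfusion is quantified indirectly: an
en-face slab of the OCTA volume is binarized and the *flow deficits* (FD) —
regions without detectable flow signal — are measured as a percentage of
the analysable area (FD%).

Large choroidal vessels (LCV) of the Sattler/Haller layers can protrude
into the CC slab projection, where they appear as smooth dark tubes. They
*replace* the granular CC texture, hiding the flow deficits beneath them;
since a homogeneous region is largely classified as flow by an adaptive
local threshold, sectors containing LCV appear *healthier* (lower FD%)
than they are. `ccfdq` implements the full quantification chain, the
statistical layer that measures this masking effect and models LCV
visibility as a function of choroidal thickness (CT), and a synthetic
scene generator that provides ground truth for all of it.

## The imaging chain

`quantifyEye()` runs four stages on a co-registered angio/structural
en-face pair (1024x1024 px for a 6x6 mm scan; pixel pitch 5.859 um):

1. **Signal compensation** (`compensateSignal`). The angiographic slab is
   divided by its Gaussian-smoothed, max-normalised, floored structural
   counterpart. This removes shared attenuation (RPE shadowing, drusen).
   Under a flat structural field the operation is exactly the identity, so
   compensation cannot change FD% where there is nothing to compensate.
2. **Phansalkar binarization** (`phansalkarThreshold`, `binarizeFD`). The
   local threshold over a digital-disk window (mirror-padded) is
   `t = mu * (1 + p*exp(-q*mu) + k*(sigma/r - 1))` with the ImageJ-variant
   constants k = 0.25, r = 0.5, p = 2, q = 10, and the *population*
   standard deviation. Pixels with intensity <= t are flow deficits (ties
   go to deficit, so a completely dark image is all-FD rather than an
   error). Two radii are supported: the literature-standard 15 px and the
   size-adjusted radius `round(ICD / pitch)` (4 px for 6 mm/1024 px
   scans), which aims the window at the intercapillary scale.
3. **Particle analysis** (`labelFDComponents`, `filterSmallFD`). FD
   components use 8-connectivity (diagonally touching pixels are one
   particle). Components smaller than the area of a 24 um circle,
   `ceiling(pi * 12^2 / pitch^2)` = 14 px at native pitch, are discarded:
   they are indistinguishable from normal intercapillary spacing and
   noise. The inequality is strict, matching the "smaller than" rule.
4. **Corner sectors** (`cornerSectors`, `sectorFDPercent`). Four 1x1 mm
   squares (`round(1000/pitch)` = 171 px) flush to the image corners,
   numbered clockwise from top-left. Orientation follows the fundus
   display convention — nasal is the right image half in right eyes and
   the left half in left eyes — and is configurable for devices with
   other display conventions. FD% is computed over *valid* pixels only:
   pixels under the dilated superficial-plexus projection mask never
   enter numerator or denominator. Sectors containing drusen of any size
   are excluded from FD% modelling (but kept in the LCV-visibility
   models, which do not depend on FD%).

### Numerical choices

* The Phansalkar window is a digital disk (centre distance <= radius),
  matching ImageJ; borders are mirror-padded (edge-inclusive reflection).
  Whether the original tool used N or N-1 in the window variance is not
  documentable; the population (divide-by-N) choice is pinned by a
  regression test.
* Intensities are normalised by the image dtype's full range (16-bit),
  never by the per-image maximum, so thresholds are portable across scans.
* The compensation smoothing default is sigma = 10 um. The kernel must
  stay below the calibre of the narrowest structure whose attenuation the
  division should track; with 50-150 um vessels, a kernel comparable to
  the vessel half-width leaves dark rims of under-compensated signal
  along every vessel edge, which register as spurious elongated FD
  components. 10 um (about twice the device's axial sampling, half its
  lateral resolution) tracks all structures the generator renders while
  still suppressing pixel noise in the denominator.
* CT is measured as the axial distance between the Bruch's-membrane outer
  border and the scleral inner border; an optional cosine correction for
  local surface tilt (plane fit over a 5 px radius) approximates the
  perpendicular-to-tangent measurement. It is off by default: below ~15
  degrees of tilt the correction is under 3.5% and desk-scale synthetic
  surfaces are flat.

## The synthetic scene generator

No imaging cohort of this kind is publicly deposited, so the package
ships a seeded generator (`simulateEye`, `simulateCohort`) whose defaults
encode the study conditions the statistical layer is meant to detect:

* **CT** per sector is drawn from normal laws with anatomical means
  (194, 148, 121, 157) um for the supero-temporal, supero-nasal,
  infero-nasal and infero-temporal corners, SD 63 um, truncated at 30 um;
  sub-foveal CT is N(197, 82) um. The nasal sectors are systematically
  thinner, which reproduces the nasal CT decline of real choroids. A
  quadratic surface through the five drawn values gives per-pixel depth
  maps, so `measureCT` at a sector centre returns the drawn value.
* **LCV visibility** per sector is Bernoulli with
  `logit P = 5.7 + log(0.94)*CT + log(6.23)*nasal + b_eye`,
  `b_eye ~ N(0, 1)`. The slope corresponds to an odds ratio of 0.94 per
  um of CT and the nasal shift to 6.23-fold odds; the intercept 5.7 was
  calibrated once, by numerical integration over the default CT mixture,
  to give ~26% marginal sector prevalence. Visible LCV are rendered as
  2-4 quadratic Bezier tubes per affected sector (widths 50-150 um),
  with a feathered profile (~15 um, the lateral optical resolution)
  shared by the angio and structural channels. Tubes carry 18% of the
  local angio signal but only 14% of the structural signal: a vessel
  lumen loses more reflectivity than decorrelation signal (blood still
  flows), and this per-channel asymmetry is what makes compensation
  restore the lumen to a homogeneous flow-level brightness — the
  mechanism behind the masking effect. Tubes *replace* the underlying
  texture; outside the tube
  footprint the image is bit-identical with and without LCV rendering.
  The same tubes are drawn in both slab settings, reflecting the
  observation that LCV visibility is conserved across slab definitions.
* **Flow texture**: smoothed white noise (correlation length 12 um),
  thresholded per sector at the quantile matching that sector's true FD
  fraction, drawn as N(group mean, 0.02) — 0.09 for iAMD eyes, 0.06 for
  controls. Only the ordering (iAMD above control) is empirically
  anchored; the levels are calibration constants exposed in the config.
  Dark pixels take the deficit level (0.08), others a granular bright
  level around 0.65.
* **Drusen** (iAMD eyes only, Poisson rate 0.7/eye, matching ~47 affected
  squares per 276) are disk blotches attenuating both channels; they are
  recorded in the drusen mask and their sectors excluded from FD models.
  Attenuation-only modelling is sufficient because those sectors never
  enter FD% analyses.
* **Superficial-plexus projections** are rendered as dark streaks across
  the angio channel and recorded in the vessel mask, which the pipeline
  dilates and excludes.

`simulateSectorData()` generates the *sector-level* measurement table
directly from the statistical laws (CT, LCV flags, FD% from a linear
mixed model with configurable effects) without rendering images. Effects
such as an FD% contrast of exactly -1.3 cannot be imposed through a
renderer, so parameter-recovery studies of the statistical layer use this
generator; the imaging chain is validated separately (below).

What the generator does *not* emulate: speckle statistics, motion and
projection artifacts beyond simple streaks, realistic drusen morphology,
3-D attenuation. Passing recovery tests therefore show that the
*algorithms* are correct and calibrated, not that the pipeline is robust
to every artifact of device data.

## The statistical layer

All models operate on the sector table (one row per eye and corner):

* `fitFDMixedModel`: REML linear mixed model
  `fd_percent ~ lcv * group + orientation + (1 | eye_id)` — the final
  model after dropping the LCV-by-orientation and group-by-orientation
  interactions, which is the reduction the underlying analysis arrived
  at. Four planned comparisons (LCV effect within each group, group
  effect within each LCV level) are derived with `emmeans`; p values are
  Bonferroni-adjusted (x4) and CIs widened to the 98.75% level.
* `fitLCVGlmm`: mixed logistic models of the LCV flag (random intercept
  per patient), univariate per predictor or multivariable (univariate
  p < 0.05 predictors plus the CT-by-orientation interaction, with CT
  odds ratios reported within each orientation). CT is mean-centred
  internally; odds ratios are per um. Drusen sectors are retained here.
* `fitEyeLevelLogistic`: ordinary logistic regression of "LCV in at
  least one sector" on sub-foveal CT, eye colour, or spherical
  equivalent.
* `youdenCutoff`: candidate thresholds are the midpoints between adjacent
  distinct CT values; a sector is called LCV-positive iff CT <= t; the
  maximal Youden index J = sens + spec - 1 wins, ties going to the
  smallest threshold. Sensitivity/specificity CIs use the closed-form
  cluster ratio estimator (`clusterRatioCI`),
  `var = m / ((m-1) (sum n_i)^2) * sum (x_i - p n_i)^2`,
  which accounts for the four repeated sectors per patient and reduces to
  the binomial Wald interval as within-patient correlation vanishes.

A note on the Youden recovery study: the empirical Youden threshold
converges to the CT value where the posterior LCV probability equals the
marginal prevalence (the density-crossing point), *not* automatically to
the logistic law's P = 0.5 crossing. The two coincide when the CT
distribution is symmetric about the crossing, which is how the recovery
world is constructed (CT ~ N(118, 63), intercept `-log(0.94) * 118`).

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
brute-force per-pixel evaluation for the Phansalkar map (bit-for-bit, 50
seeded images up to 32x32), flood-fill enumeration for particle analysis
(20 seeded 16x16 masks), exhaustive candidate scans for the Youden
cutoff, and hand-computed values for the ratio-estimator CI.

Statistical recovery runs 200 replicated cohorts of 118 eyes (69 iAMD,
49 control; 472 sectors) at the sector level: the CT odds ratio is
recovered with geometric mean within [0.93, 0.95] of the generating 0.94,
the LCV-within-iAMD FD% contrast within 0.15 of the generating -1.3, and
the median Youden threshold within 10 um of the constructed 118 um
crossing.

The imaging chain is validated end-to-end on rendered cohorts: measured
FD% correlates with the drawn true FD fraction (r >= 0.8 over 60 eyes at
256 px without LCV/drusen — at that size the pipeline runs in seconds per
eye while the sectors still hold ~1,850 pixels), and rendering LCV into
high-deficit sectors strictly lowers measured FD% in nearly all paired
sectors at the native 1024 px geometry. The masking check must run at
native pitch: the ICD size filter is 14 px there and removes the
salt-and-pepper noise specks inside compensated vessel lumina, whereas at
coarse pitch the same filter degenerates to a few pixels and noise
survives. The check uses the size-adjusted radius, whose window sits
inside the vessel lumen; the effect is present at the 15 px radius as
well (and slightly weaker, since that window straddles the lumen
boundary).

## Known limitations

* The compensation arithmetic is a floored division by the normalised
  structural signal; published compensation methods are not specified to
  the arithmetic level, and this implementation does not claim to
  reproduce any of them exactly. All three constants are configuration
  keys.
* In this synthetic world the masking effect requires compensation: an
  uncompensated tube at <= 20% of the flow signal lies below the
  Phansalkar dark-classification crossover (`2*exp(-10*c) < 0.25`, i.e.
  intensity ~0.21) and would be classified deficit. Real LCV span a wider
  brightness range, where masking is observed with and without
  compensation.
* The generator draws one eye per patient, so patient and eye coincide —
  as in the study design the defaults encode.
* Automatic LCV or drusen detection is out of scope: flags come from
  ground truth (synthetic mode) or expert annotation masks (real data).
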