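---
title: "Loci preselection for microperimetric progression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loci preselection for microperimetric progression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringmetrics)
```

## The measurement and its geometry

Fundus-tracked microperimetry projects Goldmann III stimuli onto fixed
retinal positions and reports, per locus, the attenuation (in dB relative
to the instrument's 317.04 cd/m² maximum) of the dimmest stimulus seen.
The 10-2 grid is a square array: the lattice of points whose horizontal
and vertical offsets from fixation are 1°, 3°, 5°, 7° or 9°, restricted
to the 68 points within a radial cut. `build_grid()` exposes that cut
(default 9.2°); any value in (9.06°, 9.49°) — between the eccentricities
of the (9, 1) and (9, 3) lattice points — yields the same 68-locus
membership, so the bound is a validity check rather than a tuning knob.
Each locus owns the axis-aligned square `[x−1, x+1] × [y−1, y+1]`,
giving a gap-free tessellation of the tested area; the squares are the
geometric substrate for the ring-transection test.

Coordinates are field coordinates (origin at fixation, y up, degrees).
No left/right mirroring is applied in the geometry layer; a mirror flag
exists at file I/O for right eyes, keeping the analysis code
orientation-agnostic.

A locus where the brightest stimulus is not seen is exported as −1 dB.
That code is an integer like any other in the export, and two of the
selection rules below deliberately treat it arithmetically; but it is not
a luminance, and `db_to_luminance()` refuses it.

### Adjacency

Two built-in neighbourhood schemes are provided: `orthogonal4` (loci at
Euclidean distance exactly 2°) and `chebyshev8` (Chebyshev distance
≤ 2°, i.e. orthogonal plus diagonal). The default for ESS and the mFTP
ranking is `chebyshev8`, the densest defensible reading of "adjacent" on
a square lattice. Published transition-point protocols on other grids
describe schemes with 2–5 neighbours per locus; neither built-in scheme
reproduces that range exactly (exhaustive enumeration gives degrees 2–4
for `orthogonal4` and 4–8 for `chebyshev8`), so a `custom` scheme takes
an explicit edge table — symmetrised and validated, with
`validate_adjacency_counts()` as a transcription check — letting such a
scheme be plugged in without code changes. A `peripheral_only` option in
`rank_ftp()` restricts the ranking to neighbours at strictly higher
eccentricity, for protocols that count only outward neighbours; it
defaults off.

## Ring coregistration

The ring boundary is traced on a short-wavelength autofluorescence image
(30° over 768 px here) and must be expressed in grid degrees on the MAIA
image (36° over 1024 px). Registration is a least-squares similarity
transform — isotropic scale, rotation, translation — fitted to manually
selected landmark pairs. The family is deliberately minimal: both images
are fundus photographs of the same eye taken by confocal scanning-laser
ophthalmoscopes, so scale and rotation are the real degrees of freedom,
and a handful of manual landmarks cannot support shear or projective
terms without overfitting. Writing points as complex numbers reduces the
fit to a closed-form complex regression `y = a·x + b` with
`a = s·e^{iθ}`; the reported `rmse` is the root mean squared residual
over all `2n` coordinates, so with isotropic landmark noise σ its
expectation is `σ·sqrt((2n−4)/(2n))` (four fitted parameters). At least
two non-coincident landmarks are required — the minimum that determines
a similarity.

Mapped vertices are converted to degrees by subtracting the grid centre
(default: the MAIA image centre, overridable because fixation offsets
exist) and scaling by 36/1024 °/px, with y negated because image rows
grow downward. Incomplete rings are rejected at construction rather than
silently analysed, mirroring the exclusion of eyes whose ring cannot be
fully traced.

**Transection.** A square is transected when at least one polygon edge
meets the *closed* square — touching counts, the inclusive reading of
"transects into". The implementation uses Liang–Barsky segment clipping;
tests cross-check it against an orientation-test oracle and, for circles,
against the exact corner-distance criterion. Analytic rings are
polygonized at ≤ 0.25° chord length, bounding the discretization error
of the transection test well below 0.05°.

## The four baseline selections

All selections are frozen at the baseline visit and reused for every
subsequent visit.

- **MMS** keeps all 68 loci; −1 dB enters the mean arithmetically, so a
  fully scotomatous field averages −1, not 0.
- **ESS** keeps non-scotomatous loci with ≥ 1 scotomatous neighbour.
  The scotomatous loci themselves are excluded: the quantity of interest
  is the sensitivity of the *seeing* edge, and including floor-coded
  loci would only dilute it. An eye without any −1 locus gets an empty
  selection with an explicit flag — never a silent zero.
- **mFTP** ranks loci with baseline ≥ 8 dB by the proportion of
  neighbours at least 7 dB lower (a −1 neighbour of an 8 dB locus counts:
  8 − (−1) = 9). All proportion-1 loci are selected; if fewer than 5,
  whole tied tiers at the next-highest positive proportion are added
  until the selection reaches 5. Tiers are indivisible — "until ≥ 5"
  permits overshoot, and splitting a tie would require an arbitrary
  secondary order. Proportion-0 loci are never selectable (they carry no
  transition-zone signal); an eye that cannot reach 5 positive-proportion
  loci is flagged ineligible for the event analysis rather than padded.
- **HRS** keeps loci whose square the registered ring transects. Loci
  already at −1 dB at baseline stay in the selection but are excluded
  from trend computation (no measurable range remains); a ring wholly
  outside the grid yields an empty, flagged selection.

The 8 dB baseline, 7 dB drop, 5-locus minimum and −7 dB event thresholds
are all data in `study_config()`, not constants in code.

## Per-eye progression

Eligibility requires ≥ 2.0 years of follow-up and ≥ 3 follow-up-mode
tests. **Trend** analysis regresses the per-visit selection mean on
elapsed years by OLS and reports the slope in dB/year. Subwindow
analyses at 0.5/1/1.5/2 years include every visit up to the window plus
a 0.1-year tolerance, reflecting the scheduling jitter of real 6-monthly
protocols. An optional scotoma-termination rule (`censor_scotoma`) drops
a locus from the visit of its second consecutive −1 dB reading onward
and recomputes the per-visit mean over survivors; it defaults off, so
reported rates match the uncensored convention, and exists to quantify
how much of a slow slope is floor artefact.

**Event** analysis uses the selection's event-eligible loci (baseline
≥ 8 dB, ≥ 5 of them required). The target visit is the final visit
("all") or the visit nearest 2.0 years within ±0.5 years ("2y") — a
nearest-visit rule consistent with 2-year follow-ups averaging ~2.1
years. The outcome is `mean_change = mean(target − baseline)` over those
loci, an event iff `mean_change ≤ −7` (boundary inclusive, no tolerance
fuzz), and `mean_rate = mean_change / elapsed years of the target visit`
— dividing the eye-level change by the eye's elapsed time, rather than
averaging per-locus rates, because the event criterion itself is defined
on the eye-level mean change. The floor diagnostic reports the fraction
of a selection's loci with two consecutive −1 dB readings in the window.

## Cohort statistics

Slopes (or baseline means) form an eyes × 4 matrix. The omnibus test is
a one-way within-subjects ANOVA, `F = MS_metric / MS_error` on
`(k−1, (k−1)(n−1))` degrees of freedom, computed on complete cases (an
eye lacking, say, an ESS selection is dropped and counted). No
sphericity correction is applied by default — the design's four highly
correlated metrics showed no need in practice — but a Greenhouse–Geisser
option exists. When the omnibus p < 0.05, all six pairwise comparisons
run as paired t-tests (the natural post hoc for a within-subject design)
with Bonferroni correction `p' = min(1, 6p)`; a pair whose difference
vector has zero variance returns a degenerate sentinel instead of a
p value. Baseline-versus-age associations are plain OLS fits reported as
`y = ax + b` with R².

## The synthetic cohort

Patient-level data for this design are not publicly deposited, so the
package generates cohorts whose ground truth is known exactly:

- sensitivity surface `s(r, t) = floor + (S_max − floor)·σ((R(t) − r)/w)`
  with logistic σ — the simplest monotone profile for a transition zone
  between healthy and degenerate retina;
- `R(t) = R0 − c·t` with `R0 ~ U[3°, 8°]` per eye and `c = 0.25`°/year,
  a ring radius range and constriction rate typical of reported HAR
  natural history;
- plateau `S_max = 24` dB (a normal-range macular sensitivity on this
  instrument), model floor −5 dB so that censoring at the export floor
  actually bites, transition width `w = 1.5°`;
- noise SD `σ0 + σ1·|∂s/∂r|` with `σ0 = 1` dB, `σ1 = 0.5` dB per
  (dB/°): test-retest variability is higher at the scotoma border than
  on normal retina, and the local spatial gradient is the natural
  covariate for that;
- thresholds are the rounded noisy surface, censored to −1 below 0 and
  36 above — the ±2 dB quantization of the instrument's 4-2 staircase is
  subsumed in σ0, since analysis only ever sees exported integers;
- visits every 0.5 years, 9 visits (4 years), 30 eyes by default,
  matching a realistic natural-history protocol; ages `U[18, 60]`;
- the baseline ring is emitted in degrees *and* as an AF-pixel trace
  with landmark pairs under a per-eye random similarity (scale jitter
  0.9–1.1 on top of the 30/768 : 36/1024 pixel-scale ratio, rotation
  ±0.1 rad), so selections inside `generate_cohort()` are produced by
  running the actual registration stage, not by bypassing it.

The model's closed-form time-averaged rate `(s(t_end) − s(0))/t_end`
(`truth_rates()`) is the oracle for parameter recovery: at the ring
midpoint the instantaneous rate is `−(S_max − floor)·c/(4w)` ≈ −1.21
dB/year at defaults, and over 20 replicate cohorts of 30 eyes the
pipeline's mean HRS slope agrees with the oracle within two Monte-Carlo
standard errors, with the qualitative ordering |mFTP|, |HRS| > |MMS|
reproduced.

What the generator does *not* emulate: fixation instability and
false-positive responses, asymmetric or fragmented rings, cystoid
macular edema and other media confounders, learning effects, and
longitudinal changes in ring shape other than isotropic contraction.
Passing recovery tests therefore show the pipeline is faithful to its
own disease model, not that the model exhausts real data.

## Numerical choices and degenerate inputs

- OLS slopes come from exact linear-algebra fits; a window with < 2
  usable time points yields an `NA` slope sentinel, and an empty
  effective locus set yields an `NA` mean — never 0.
- The ANOVA guards the 0/0 case (identical columns up to a subject
  shift) by reporting F = 0, p = 1 instead of a ratio of rounding
  errors.
- Selections are deterministic: re-running on the same baseline is
  bit-identical; the generator is bit-reproducible under its seed.
- Problem sizes in the shipped checks — 500 random fields for selection
  oracles, 1,000 random rings × 68 squares for transection, 10⁴ null
  replicates for the family-wise error, 20 × 30 eyes for recovery — were
  chosen to make Monte-Carlo error small relative to the tolerances
  being asserted.

## Limitations

Trend analysis is per-eye OLS, not a mixed model; censored-regression
alternatives to the floor-effect rule are out of scope, as are
point-wise (per-locus) progression maps, non-square grids, and automated
ring segmentation. The mean-rate convention (eye-level change over
eye-level time) is isolated in one function should a per-locus
convention be preferred.
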