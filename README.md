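# ringmetrics

Anatomy- and sensitivity-based loci preselection for microperimetric
progression analysis in retinal degeneration.

## The problem

In rod–cone degenerations such as *USH2A*-retinopathy, visual function is
lost outward-in: a hyperautofluorescent ring (HAR) on fundus
autofluorescence imaging marks the transition zone between preserved and
degenerate retina and contracts over time. Clinical trials need
microperimetry endpoints that detect change quickly, but the obvious
whole-grid average dilutes the fast-changing transition zone with a stable
plateau and an unrecordable scotoma. `ringmetrics` implements and compares
four ways of preselecting loci on the MAIA 10-2 grid (68 loci, 2° spacing,
thresholds 0–36 dB with −1 dB coding "not seen") at baseline, for
ophthalmic reading centres and trial statisticians:

- **MMS** — mean macular sensitivity: the average over all 68 loci,
  −1 dB values included.
- **ESS** — edge-of-scotoma sensitivity: the average over non-scotomatous
  loci adjacent to a scotomatous (−1 dB) locus.
- **mFTP** — modified functional transition point: loci with baseline
  ≥ 8 dB, ranked by the proportion *p* of adjacent loci whose baseline is
  ≥ 7 dB lower; all loci with *p* = 1 are taken, then whole tied tiers of
  the next-highest *p* > 0 until at least 5 loci are selected.
- **HRS** — hyperautofluorescent-ring sensitivity: loci whose 2°×2°
  tessellation square is transected by the HAR boundary after the
  autofluorescence image is registered to the MAIA image by a
  landmark-fitted similarity transform.

Selections are frozen at baseline. Per eye, progression is measured two
ways: **trend-based** — the OLS slope of the selection mean *m(t)* over
elapsed years, in dB/year — and **event-based** — whether the mean change
across ≥ 5 prespecified loci (each ≥ 8 dB at baseline) reaches
Δ ≤ −7 dB, the FDA's clinically-meaningful-change criterion. Cohort-level
comparison uses one-way repeated-measures ANOVA across the four metrics
with Bonferroni-corrected pairwise paired t-tests, plus a floor-effect
diagnostic (proportion of loci with two consecutive −1 dB readings).

Because no patient-level data are deposited for this design, the package
ships a synthetic-cohort generator with known ground truth: a
hill-of-vision `s(r,t) = floor + (S_max − floor)·σ((R(t) − r)/w)` whose
ring radius `R(t) = R0 − c·t` contracts linearly, sampled with
heteroscedastic test-retest noise and floor censoring. Closed-form decline
rates from the model serve as oracles for parameter-recovery tests.

## Worked example

```r
library(ringmetrics)

cohort <- generate_cohort(sim_config(n_eyes = 30, seed = 42))
bundle <- run_pipeline(cohort)
print(bundle$anova[["all"]])
```

```
repeated-measures ANOVA: F(3, 78) = 61.73, p = 1.51e-20 (n = 27 eyes, 3 dropped)
pairwise (Bonferroni-corrected):
    a    b  mean_diff         t        p_raw       p_bonf significant degenerate
  MMS  ESS  0.2146576  6.584448 5.547063e-07 3.328238e-06        TRUE      FALSE
  MMS mFTP  0.7789817  9.565787 5.299460e-10 3.179676e-09        TRUE      FALSE
  MMS  HRS  0.4204330 10.429364 8.771144e-11 5.262686e-10        TRUE      FALSE
  ESS mFTP  0.5643242  7.145822 1.373193e-07 8.239160e-07        TRUE      FALSE
  ESS  HRS  0.2057754  5.093069 2.629157e-05 1.577494e-04        TRUE      FALSE
 mFTP  HRS -0.3585487 -5.546805 7.987090e-06 4.792254e-05        TRUE      FALSE
```

Per-eye slopes sit in `bundle$results` (one row per eye × metric ×
window). On this cohort the full-follow-up means are MMS −0.66, ESS
−0.86, HRS −1.07 and mFTP −1.40 dB/year: the transition-zone metrics
decline roughly twice as fast as the whole-grid mean, with the
`mean_diff` column above giving each pairwise slope difference in
dB/year. Three eyes lack an ESS selection (no baseline scotoma) and are
dropped from the complete-case ANOVA.

The same analysis as a step-by-step workflow, each step printing what it
found and writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # cohort -> scratch/cohort/, baseline table
Rscript analysis/02_register.R   # landmark fits, rings in degrees
Rscript analysis/03_select.R     # the four baseline selections per eye
Rscript analysis/04_progress.R   # trend + event + floor, per eye
Rscript analysis/05_compare.R    # RM-ANOVA, pairwise, age regressions
```

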