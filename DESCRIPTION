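Package: ringmetrics
Title: Anatomy- and Sensitivity-Based Loci Preselection for Microperimetric Progression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing longitudinal MAIA 10-2 microperimetry in
    retinal degeneration with a hyperautofluorescent ring. Constructs the
    68-locus test grid with its 2x2-degree square tessellation and locus
    adjacency, registers ring boundaries traced in autofluorescence-image
    pixels into grid degrees via landmark-based similarity transforms, and
    computes four baseline-frozen loci preselections: mean macular
    sensitivity (MMS), edge-of-scotoma sensitivity (ESS), the modified
    functional transition point (mFTP), and hyperautofluorescent ring
    sensitivity (HRS). Provides per-eye trend-based (linear-regression
    slope) and event-based (mean change over prespecified loci) progression
    analyses, floor-effect diagnostics, cohort-level repeated-measures
    ANOVA with Bonferroni-corrected pairwise comparisons, and a synthetic
    longitudinal cohort generator with closed-form ground-truth decline
    rates for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
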