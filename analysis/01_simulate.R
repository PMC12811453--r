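#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates the default synthetic cohort: 30 eyes followed 6-monthly for 4
# years on the 68-locus 10-2 grid, each with a contracting
# hyperautofluorescent ring, logistic transition-zone decline,
# edge-weighted test-retest noise and -1 dB floor censoring. Writes the
# raw per-visit exports (plus rings and registration landmarks) under
# scratch/cohort/ and a per-eye baseline summary under results/.

suppressPackageStartupMessages(library(ringmetrics))

seed <- 42
cfg <- sim_config(n_eyes = 30, seed = seed)
cohort <- generate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "scratch/cohort")

baseline <- do.call(rbind, lapply(cohort$eyes, function(es) {
  b <- es$visits[[1]]
  data.frame(eye_id = es$eye_id, age = round(es$age, 1),
             ring_radius_deg = round(es$r0, 2),
             mms_baseline_db = round(evaluate_selection(es$selections$MMS, b), 2),
             n_scotomatous = sum(b$values == -1))
}))
write.csv(baseline, "results/baseline_cohort.csv", row.names = FALSE)

cat(sprintf("simulated %d eyes x %d visits (seed %d) -> scratch/cohort/\n",
            cfg$n_eyes, cfg$n_visits, seed))
cat(sprintf("baseline MMS %.1f +/- %.1f dB; ring radius %.1f-%.1f deg; %d/%d eyes with baseline scotoma\n",
            mean(baseline$mms_baseline_db), sd(baseline$mms_baseline_db),
            min(baseline$ring_radius_deg), max(baseline$ring_radius_deg),
            sum(baseline$n_scotomatous > 0), cfg$n_eyes))
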