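#!/usr/bin/env Rscript
# Step 5 — cohort-level comparison.
#
# Repeated-measures ANOVA of the per-eye progression slopes across the
# four metrics (complete cases), with Bonferroni-corrected pairwise paired
# t-tests when the omnibus test is significant, for each window; and the
# baseline metric-versus-age regressions. Machine-readable output in
# results/comparison.json.

suppressPackageStartupMessages(library(ringmetrics))

if (!file.exists("results/progression.csv")) {
  stop("run analysis/04_progress.R first (results/progression.csv missing)")
}
res <- read.csv("results/progression.csv")
eyes <- load_cohort("scratch/cohort")

out <- list()
for (w in c("2y", "all")) {
  sub <- res[res$window == w, c("eye_id", "metric", "slope")]
  wide <- reshape(sub, idvar = "eye_id", timevar = "metric",
                  direction = "wide")
  m <- as.matrix(wide[, -1])
  colnames(m) <- sub("^slope\\.", "", colnames(m))
  a <- rm_anova(m)
  cat(sprintf("window %s: ", w)); print(a)
  out[[w]] <- list(F = a$F, df = a$df, p = a$p, n = a$n,
                   n_dropped = a$n_dropped,
                   pairwise = a$pairwise)
}

ages <- sapply(eyes, `[[`, "age")
base <- sapply(eyes, function(es)
  evaluate_selection(es$selections$MMS, es$visits[[1]]))
fit <- baseline_age_fit(base, ages)
cat("baseline MMS vs age: ", fit$label, "\n", sep = "")
out$baseline_age <- list(slope = fit$slope, intercept = fit$intercept,
                         r_squared = fit$r_squared, n = fit$n)

jsonlite::write_json(out, "results/comparison.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat("wrote results/comparison.json\n")
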