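#!/usr/bin/env Rscript
# Inference over the pooled step-metrics table produced by 02_pipeline.R:
# mixed-design repeated-measures ANOVA per perturbed side and metric,
# Bonferroni post-hoc comparisons per recovery step, the Welch contrast on
# first-recovery-step asymmetry, and the handrail tally.  Writes a compact
# human-readable report to results/stats_report.txt.

library(stumblr)

metrics <- read.csv("results/pipeline/step_metrics.csv")
screening <- read.csv("results/pipeline/screening.csv")

sink("results/stats_report.txt", split = TRUE)
metric_cols <- c(sway = "trunk_sway", vel = "peak_flexion_velocity",
                 grf = "peak_grf")
for (side in c("intact", "prosthetic")) {
  for (mname in names(metric_cols)) {
    fam <- if (mname == "grf") "include_kinetic" else "include_kinematic"
    sub <- metrics[metrics$side_label == side & metrics[[fam]], ]
    cols <- c(unit = "unit", group = "snp", step = "label",
              value = metric_cols[[mname]])
    cat(sprintf("\n== %s-side perturbations, %s ==\n", side, mname))
    a <- mixed_anova(sub, cols = cols)
    print(a)
    ph <- bonferroni_posthoc(sub, cols = cols)
    cat("post-hoc (inactive - active), Bonferroni-adjusted:\n")
    print(ph, digits = 3)
  }
}
cat("\n== Welch contrast on first-recovery-step asymmetry ==\n")
for (mname in names(metric_cols)) {
  rec1 <- metrics[metrics$label == "rec1" &
                    metrics[[if (mname == "grf") "include_kinetic"
                             else "include_kinematic"]], ]
  w <- welch_asymmetry_test(rec1, cols = c(side = "side_label", group = "snp",
                                           value = metric_cols[[mname]]))
  cat(sprintf("%-5s contrast = %.3f +- %.3f, T(%.1f) = %.2f, p = %.3g\n",
              mname, w$estimate, w$se, w$df, w$t, w$p))
}
cat("\n== Handrail grabs by side and SNP condition ==\n")
print(handrail_count_table(screening))
sink()
message("report written to results/stats_report.txt")
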