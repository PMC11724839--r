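#!/usr/bin/env Rscript
# Summary figures of the cohort analysis: per-step metric means by SNP
# condition and a belt-speed profile illustration.  PNG output under
# results/figures/.

library(stumblr)
library(ggplot2)

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
metrics <- read.csv("results/pipeline/step_metrics.csv")
metrics$label <- factor(metrics$label, c("pert", "rec1", "rec2", "rec3"))

long <- do.call(rbind, lapply(
  c(trunk_sway = "trunk sway (deg)",
    peak_flexion_velocity = "peak flexion velocity (deg/s)",
    peak_grf = "first peak ||GRF|| (%BW)") |> names(), function(col) {
      fam <- if (col == "peak_grf") "include_kinetic" else "include_kinematic"
      sub <- metrics[metrics[[fam]], ]
      data.frame(metric = col, label = sub$label, snp = sub$snp,
                 side = sub$side_label, value = sub[[col]])
    }))

summ <- aggregate(value ~ metric + label + snp + side, long,
                  function(x) c(mean = mean(x), sd = sd(x)))
summ <- cbind(summ[1:4], as.data.frame(summ$value))

p1 <- ggplot(summ, aes(label, mean, fill = snp)) +
  geom_col(position = position_dodge(0.8), width = 0.7) +
  geom_errorbar(aes(ymin = mean - sd, ymax = mean + sd),
                position = position_dodge(0.8), width = 0.25) +
  facet_grid(metric ~ side, scales = "free_y") +
  scale_fill_manual(values = c(inactive = "#c0392b", active = "#2066ac")) +
  labs(x = "recovery step", y = NULL,
       title = "Step metrics by SNP condition (synthetic cohort)") +
  theme_bw()
ggsave("results/figures/step_metrics.png", p1, width = 8, height = 7, dpi = 150)

sp <- make_belt_profile(1.0, 3, 0.8, 1, 1000, 3)
p2 <- ggplot(data.frame(t = (seq_along(sp) - 1) / 1000, speed = sp),
             aes(t, speed)) +
  geom_line(linewidth = 0.8) +
  labs(x = "time (s)", y = "belt speed (m/s)",
       title = "Triangular belt perturbation: 3 m/s^2, 800 ms") +
  theme_bw()
ggsave("results/figures/belt_profile.png", p2, width = 6, height = 3, dpi = 150)
message("figures written to results/figures/")
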