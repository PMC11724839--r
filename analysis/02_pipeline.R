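#!/usr/bin/env Rscript
# Run the full analysis pipeline over the simulated cohort: preprocessing,
# gait events, perturbation detection, step metrics and screening, then the
# inference layer.  All interface files land in results/pipeline/.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE))), "00_cohort.R"))

seed <- 1
cfgs <- cohort_configs(seed)

message("simulating ", length(cfgs), " walking blocks ...")
trials <- lapply(cfgs, function(cfg) simulate_trial(cfg)$trial)
static <- generate_static_trial(simulation_config(participant_mass = 71.7,
                                                  seed = seed))

message("analysing ...")
res <- run_analysis(trials, static, out_dir = "results/pipeline")

kin <- sum(res$screening$include_kinematic)
message(sprintf("%d / %d perturbations enter the kinematic analysis",
                kin, nrow(res$screening)))
message(sprintf("body weight: %.1f N", res$body_weight$value))
message("interface files written to results/pipeline/")
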