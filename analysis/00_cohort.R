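# Shared cohort definition for the analysis drivers: one synthetic
# participant (71.7 kg, 800 ms perturbations) walking blocks under both SNP
# conditions.  The active condition carries the first-recovery-step effects
# reported for the strongest responder: -1.3 deg trunk sway, -10.5 deg/s
# peak flexion velocity, +5.8 %BW first-peak ||GRF|| after intact-side
# perturbations.  Deterministic given `seed`.

library(stumblr)

cohort_effect <- function() {
  effect_profile(intact = matrix(c(-1.3, -10.5, 5.8), 1, 3,
                                 dimnames = list("rec1",
                                                 c("sway", "vel", "grf"))))
}

cohort_configs <- function(seed = 1, n_blocks = 6) {
  cfgs <- list()
  for (b in seq_len(n_blocks)) {
    cfgs[[length(cfgs) + 1]] <- simulation_config(
      participant_mass = 71.7, seed = seed * 10 + b)
    cfgs[[length(cfgs) + 1]] <- simulation_config(
      participant_mass = 71.7, seed = seed * 10 + 50 + b,
      snp_condition = "active", effect_profile = cohort_effect())
  }
  cfgs
}
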