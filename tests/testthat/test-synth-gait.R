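test_that("static trial reproduces body weight and splits load evenly", {
  cfg <- simulation_config(participant_mass = 71.7, force_noise_sd = 0)
  st <- generate_static_trial(cfg)
  total <- st$forces$left + st$forces$right
  expect_equal(mean(sqrt(rowSums(total^2))), 71.7 * 9.81, tolerance = 1e-12)
  expect_equal(mean(st$forces$left[, "fz"]) / mean(total[, "fz"]), 0.5,
               tolerance = 1e-12)

  # noiseless 100 kg: every sample's total magnitude exactly 981 N
  cfg2 <- simulation_config(participant_mass = 100, force_noise_sd = 0)
  st2 <- generate_static_trial(cfg2)
  mag <- sqrt(rowSums((st2$forces$left + st2$forces$right)^2))
  expect_true(all(abs(mag - 981) < 1e-9))

  # with sensor noise the participant still reads as stationary (CV < 2%)
  cfg3 <- simulation_config(participant_mass = 85.1, force_noise_sd = 2)
  st3 <- generate_static_trial(cfg3)
  mag3 <- sqrt(rowSums((st3$forces$left + st3$forces$right)^2))
  expect_lt(sd(mag3) / mean(mag3), 0.02)

  expect_error(generate_static_trial(simulation_config(participant_mass = 1),
                                     duration = 0), class = "invalid_config")
  expect_error(simulation_config(participant_mass = 0),
               class = "invalid_config")
})

test_that("steady gait has the configured cadence and double-hump GRFs", {
  cfg <- noiseless_config(n_per_side = 0, cadence = 100)
  sg <- generate_steady_gait(cfg, duration = 60)
  n_strikes <- length(sg$truth$heel_strikes$left) +
    length(sg$truth$heel_strikes$right)
  # cadence 100 steps/min over 60 s, minus the lead-in before the first strike
  expect_true(abs(n_strikes - 100) <= 3)

  # swing GRF exactly zero without noise; stance peaks near 100-120 %BW
  fz <- sg$trial$forces$left[, "fz"]
  tf <- (seq_along(fz) - 1) / sg$trial$force_rate
  strikes <- sg$truth$heel_strikes$left
  offs <- sg$truth$toe_offs$left
  swing <- tf > offs[1] + 0.01 & tf < strikes[strikes > offs[1]][1] - 0.01
  expect_true(all(fz[swing] == 0))
  bw_n <- cfg$participant_mass * 9.81
  expect_gt(max(fz) / bw_n * 100, 100)
  expect_lt(max(fz) / bw_n * 100, 120)
})

test_that("heel/toe relative-AP extrema coincide with ground-truth events", {
  cfg <- noiseless_config(n_per_side = 0)
  sg <- generate_steady_gait(cfg, duration = 30)
  tr <- sg$trial
  pelvis_x <- (tr$markers$SACR[, 1] + tr$markers$LASI[, 1] +
                 tr$markers$RASI[, 1]) / 3
  tm <- (seq_len(nrow(tr$markers$LHEE)) - 1) / tr$marker_rate
  rel <- tr$markers$LHEE[, 1] - pelvis_x
  for (hs in sg$truth$heel_strikes$left) {
    win <- which(abs(tm - hs) <= 0.3)
    t_max <- tm[win[which.max(rel[win])]]
    expect_lte(abs(t_max - hs), 1 / tr$marker_rate + 1e-9)
  }
  rel_t <- tr$markers$LTOE[, 1] - pelvis_x
  for (to in sg$truth$toe_offs$left[1:5]) {
    win <- which(abs(tm - to) <= 0.3)
    t_min <- tm[win[which.min(rel_t[win])]]
    expect_lte(abs(t_min - to), 1 / tr$marker_rate + 1e-9)
  }
})

test_that("belt profile follows the closed-form triangle", {
  # 3 m/s^2 for 800 ms: peak +1.2 m/s at mid-perturbation, back to v0 at end
  sp <- make_belt_profile(v0 = 1, accel = 3, duration = 0.8, onset = 2,
                          rate = 1000, total_duration = 4)
  t <- (seq_along(sp) - 1) / 1000
  expect_equal(max(sp), 1 + 3 * 0.8 / 2, tolerance = 1e-12)
  expect_equal(sp[t == 2.4], 2.2, tolerance = 1e-12)
  expect_equal(sp[t == 2.8], 1.0, tolerance = 1e-12)
  expect_true(all(sp[t < 2 | t > 2.8] == 1))
  # 600 ms: peak increment a*T/2 = 0.9
  sp6 <- make_belt_profile(1, 3, 0.6, 2, 1000)
  expect_equal(max(sp6) - 1, 0.9, tolerance = 1e-12)
  # continuity: no jump exceeds one sample's acceleration quantum
  expect_lt(max(abs(diff(sp))), 3 / 1000 + 1e-12)
  # vanishing acceleration limit: constant series
  sp0 <- make_belt_profile(1, 1e-12, 0.8, 2, 1000)
  expect_true(all(abs(sp0 - 1) < 1e-9))
})

test_that("scheduling honours counts, spacing and the 100 N trigger rule", {
  cc <- cached_trial()
  perts <- cc$truth$perturbations
  expect_equal(nrow(perts), 4)   # 2 per side
  expect_equal(as.vector(table(perts$side)), c(2, 2))
  # spacing: at least min_spacing strides between onsets
  T_stride <- 120 / cc$cfg$cadence
  expect_true(all(diff(sort(perts$onset)) >= cc$cfg$min_spacing * T_stride))
  # trigger rule: vertical GRF exceeds 100 N at the onset sample, not before
  for (i in seq_len(nrow(perts))) {
    fz <- cc$trial$forces[[perts$side[i]]][, "fz"]
    j <- round(perts$onset[i] * cc$trial$force_rate) + 1L
    expect_gt(fz[j], 100)
    expect_lte(fz[j - 1], 100)
  }
  # early stance: all onset fractions inside the first 20% of the cycle
  expect_true(all(perts$cycle_fraction < 0.20))

  # zero perturbations: trial unchanged
  cfg0 <- noiseless_config(n_per_side = 0)
  sg <- generate_steady_gait(cfg0, duration = 30)
  out <- schedule_perturbations(sg$trial, sg$truth, cfg0)
  expect_identical(out$trial, sg$trial)

  # too-short trial: scheduling error naming the shortfall
  cfgN <- noiseless_config(n_per_side = 12)
  sgN <- generate_steady_gait(cfgN, duration = 40)
  expect_error(schedule_perturbations(sgN$trial, sgN$truth, cfgN),
               class = "scheduling_error")
})

test_that("belt speed is conserved around each perturbation", {
  cc <- cached_trial()
  sp <- cc$trial$belt_speed
  v0 <- cc$cfg$preferred_speed
  expect_equal(max(sp) - v0,
               cc$cfg$perturbation_accel * cc$cfg$perturbation_duration / 2,
               tolerance = cc$cfg$perturbation_accel / cc$trial$force_rate)
  for (i in seq_len(nrow(cc$truth$perturbations))) {
    j_end <- round((cc$truth$perturbations$onset[i] +
                      cc$truth$perturbations$duration[i]) *
                     cc$trial$force_rate) + 1L
    expect_equal(sp[j_end], v0, tolerance = 1e-9)
  }
})

test_that("injected recovery responses are exact at zero noise", {
  cc <- cached_trial()
  m <- merge(cc$res$step_metrics, cc$truth$injected,
             by = c("pert_id", "label"))
  expect_equal(nrow(m), 16)
  expect_lt(max(abs(m$trunk_sway - m$sway) / m$sway), 0.01)
  expect_lt(max(abs(m$peak_flexion_velocity - m$vel) / m$vel), 0.01)
  expect_lt(max(abs(m$peak_grf - m$grf) / m$grf), 0.01)
})

test_that("effect-profile offsets shift ground-truth metrics exactly", {
  eff <- effect_profile(intact = matrix(c(-1.3, 0, 0), 1, 3,
                                        dimnames = list("rec1",
                                                        c("sway", "vel", "grf"))))
  base <- noiseless_config(seed = 5, n_per_side = 2)
  act <- noiseless_config(seed = 5, n_per_side = 2, effect_profile = eff,
                          snp_condition = "active")
  st0 <- simulate_trial(base)
  st1 <- simulate_trial(act)
  g0 <- st0$truth$injected
  g1 <- st1$truth$injected
  sel0 <- g0$label == "rec1" &
    st0$truth$perturbations$side_label[g0$pert_id] == "intact"
  sel1 <- g1$label == "rec1" &
    st1$truth$perturbations$side_label[g1$pert_id] == "intact"
  expect_equal(unique(g0$sway[sel0] - g1$sway[sel1]), 1.3, tolerance = 1e-12)
  # null case: zero offsets and zero noise give metric-identical trials
  st2 <- simulate_trial(noiseless_config(seed = 5, n_per_side = 2,
                                         snp_condition = "active"))
  expect_equal(st2$truth$injected, st0$truth$injected)
  # negative GRF peaks are rejected
  bad <- effect_profile(intact = matrix(c(0, 0, -500), 1, 3,
                                        dimnames = list("rec1",
                                                        c("sway", "vel", "grf"))))
  cfgb <- noiseless_config(seed = 5, n_per_side = 1, effect_profile = bad)
  sg <- generate_steady_gait(cfgb, duration = 80)
  sg <- schedule_perturbations(sg$trial, sg$truth, cfgb)
  expect_error(inject_recovery_response(sg$trial, sg$truth, cfgb),
               class = "invalid_config")
})

test_that("with metric noise, injected values scatter around the target", {
  cfg <- simulation_config(n_perturbations_per_side = 6, seed = 17,
                           noise_sd = c(sway = 0.3, vel = 0, grf = 0),
                           marker_noise_sd = 0, force_noise_sd = 0)
  st <- simulate_trial(cfg)
  rec1 <- st$truth$injected[st$truth$injected$label == "rec1", ]
  base <- cfg$baseline_profile$sway[["rec1"]]
  # sample mean within 3 standard errors of the injected baseline
  expect_lt(abs(mean(rec1$sway) - base), 3 * 0.3 / sqrt(nrow(rec1)))
  expect_gt(sd(rec1$sway), 0)
})

test_that("identical configurations render bit-identical trials", {
  cfg <- simulation_config(n_perturbations_per_side = 1, seed = 9)
  a <- simulate_trial(cfg)
  b <- simulate_trial(simulation_config(n_perturbations_per_side = 1, seed = 9))
  expect_identical(a$trial$markers, b$trial$markers)
  expect_identical(a$trial$forces, b$trial$forces)
  expect_identical(a$trial$belt_speed, b$trial$belt_speed)
  expect_identical(a$truth, b$truth)
})

test_that("corruption is identity at zero probabilities and logged otherwise", {
  cfg <- noiseless_config(seed = 2, n_per_side = 2)
  st <- simulate_trial(cfg)
  out <- corrupt_trial(st$trial, st$truth, cfg)
  expect_identical(out$trial, st$trial)

  cfg2 <- noiseless_config(seed = 2, n_per_side = 2,
                           handrail_grab_probability = 1)
  st2 <- simulate_trial(cfg2)
  expect_equal(nrow(st2$truth$grabs), nrow(st2$truth$perturbations))
  # finger speed below 5 cm/s throughout each inserted grab interval
  tr <- st2$trial
  tm <- (seq_len(nrow(tr$markers$LFIN)) - 1) / tr$marker_rate
  for (i in seq_len(nrow(st2$truth$grabs))) {
    g <- st2$truth$grabs[i, ]
    idx <- which(tm >= g$start + 0.02 & tm <= g$end - 0.02)
    v <- (tr$markers$LFIN[idx + 1, ] - tr$markers$LFIN[idx - 1, ]) *
      tr$marker_rate / 2
    expect_lt(max(sqrt(rowSums(v^2))), 0.05)
  }

  # dropout marks a contiguous invalid run that fails the 5% rule downstream
  cfg3 <- noiseless_config(seed = 2, n_per_side = 2,
                           dropout_probability = 1, dropout_fraction = 0.06)
  st3 <- simulate_trial(cfg3)
  expect_equal(nrow(st3$truth$dropouts), nrow(st3$truth$perturbations))
  gti <- ground_truth_inclusion(st3$truth)
  expect_true(all(!gti$kinematic_complete))
  expect_true(all(gti$kinetic_separated))
})
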