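test_that("warm-up exclusion removes the first two per side per block", {
  perts <- data.frame(block = 1, side_ordinal = rep(1:12, 2))
  expect_equal(sum(!exclude_warmup(perts)), 20)   # 10 retained per side
  perts2 <- data.frame(block = 1, side_ordinal = rep(1:2, 2))
  expect_true(all(exclude_warmup(perts2)))
  # two blocks of 5 per side: 3 retained per side per block
  perts3 <- data.frame(block = rep(1:2, each = 10),
                       side_ordinal = rep(1:5, 4))
  expect_equal(sum(!exclude_warmup(perts3)), 12)
})

test_that("onset-phase check is inclusive at the 20% boundary", {
  expect_true(check_onset_phase(0))
  expect_true(check_onset_phase(0.20))
  expect_false(check_onset_phase(0.21))
  expect_false(check_onset_phase(NA))
})

test_that("handrail grabs require both speed and duration thresholds", {
  rate <- 100
  n <- 400
  t <- (0:(n - 1)) / rate
  # piecewise-linear AP path: 0.9 m/s baseline, 0.04 m/s inside the slow span
  mk_fingers <- function(slow_dur) {
    speed <- ifelse(t >= 2 & t < 2 + slow_dur, 0.04, 0.9)
    x <- cumsum(speed) / rate
    list(LFIN = cbind(x, 0.3, 0.9), RFIN = cbind(x + 0.5, -0.3, 0.9))
  }
  # 60 ms at 4 cm/s: one grab
  g1 <- detect_handrail_grabs(mk_fingers(0.060), rate)
  expect_equal(nrow(g1), 1)
  # 40 ms at 4 cm/s: duration below 50 ms, no grab
  g2 <- detect_handrail_grabs(mk_fingers(0.040), rate)
  expect_equal(nrow(g2), 0)
  expect_error(detect_handrail_grabs(list(LFIN = NULL), rate),
               class = "screening_failure")
  # injected grabs on synthetic trials are all detected
  cfg <- noiseless_config(seed = 4, n_per_side = 2,
                          handrail_grab_probability = 1)
  st <- simulate_trial(cfg)
  tr <- preprocess_trial(st$trial)
  for (i in seq_len(nrow(st$truth$grabs))) {
    g <- st$truth$grabs[i, ]
    det <- detect_handrail_grabs(tr$markers, tr$marker_rate,
                                 window = c(g$start - 0.5, g$end + 0.5))
    expect_gte(nrow(det), 1)
  }
})

test_that("marker completeness applies the 5% bound per marker", {
  masks <- list(C7 = rep(TRUE, 1000), CLAV = rep(TRUE, 1000))
  expect_true(check_marker_completeness(masks, 100, c(0, 10)))
  masks$C7[1:50] <- FALSE   # exactly 5%: pass
  expect_true(check_marker_completeness(masks, 100, c(0, 10)))
  masks$C7[51] <- FALSE     # 5.1%: fail
  expect_false(check_marker_completeness(masks, 100, c(0, 10)))
  # pooled mode averages across markers
  expect_true(check_marker_completeness(masks, 100, c(0, 10),
                                        per_marker = FALSE))
})

test_that("belt separation fails when a plate stays loaded through a cycle", {
  rate <- 1000
  n <- 3000
  t <- (0:(n - 1)) / rate
  # clean alternating gait: each plate unloaded ~38% of each cycle
  fzL <- ifelse(t %% 1.2 < 0.744, 500, 0)
  fzR <- ifelse((t - 0.6) %% 1.2 < 0.744, 500, 0)
  cycles <- data.frame(start = c(0, 1.2), end = c(1.2, 2.4))
  expect_true(check_belt_separation(fzL, fzR, rate, cycles))
  # mid-line crossing: one plate loaded >= 20 N for > 85% of a cycle
  fzR2 <- fzR + 30
  expect_false(check_belt_separation(fzL, fzR2, rate, cycles))
  # boundary: exactly 15% unloaded passes (inclusive)
  fzR3 <- ifelse(t %% 1.2 < 1.02, 500, 0)
  expect_true(check_belt_separation(fzL, fzR3, rate,
                                    data.frame(start = 0, end = 1.2)))
  # window without a full cycle fails with a reason
  res <- check_belt_separation(fzL, fzR, rate,
                               data.frame(start = numeric(), end = numeric()))
  expect_false(res)
  expect_match(attr(res, "reason"), "cycle")
})

test_that("screening aggregates the rules into per-family inclusion", {
  cc <- cached_trial()
  sc <- cc$res$screening
  # uncorrupted trial: only warm-up exclusions
  expect_true(all(sc$include_kinematic[sc$side_ordinal > 2]))
  expect_true(all(!sc$include_kinematic[sc$side_ordinal <= 2]))
  expect_identical(sc$include_kinematic, sc$include_kinetic)
  expect_true(all(!sc$handrail_grab))

  # corruption: inclusion flags match the ground-truth prediction exactly
  cfg <- simulation_config(n_perturbations_per_side = 3, seed = 21,
                           noise_sd = c(sway = 0, vel = 0, grf = 0),
                           marker_noise_sd = 0, force_noise_sd = 0,
                           handrail_grab_probability = 0.5,
                           dropout_probability = 0.4,
                           midline_cross_probability = 0.4)
  st <- simulate_trial(cfg)
  res <- analyze_trial(st$trial, generate_static_trial(cfg))
  gti <- ground_truth_inclusion(st$truth)
  expect_identical(res$screening$include_kinematic, gti$include_kinematic)
  expect_identical(res$screening$include_kinetic, gti$include_kinetic)
  expect_identical(res$screening$handrail_grab, gti$handrail_grab)
  # a kinematic-only dropout leaves the kinetic family usable
  kin_only <- gti$kinetic_separated & !gti$kinematic_complete &
    !gti$warmup_excluded & !gti$handrail_grab
  if (any(kin_only)) {
    expect_true(all(res$screening$include_kinetic[kin_only]))
    expect_true(all(!res$screening$include_kinematic[kin_only]))
  }
})

test_that("relaxing thresholds never excludes a previously included trial", {
  cfg <- simulation_config(n_perturbations_per_side = 3, seed = 22,
                           handrail_grab_probability = 0.3,
                           dropout_probability = 0.3,
                           midline_cross_probability = 0.3)
  st <- simulate_trial(cfg)
  strict <- analyze_trial(st$trial, generate_static_trial(cfg))$screening
  relaxed_cfg <- pipeline_config(max_missing_fraction = 0.2,
                                 min_swing_fraction = 0.05,
                                 onset_max_fraction = 0.5)
  relaxed <- analyze_trial(st$trial, generate_static_trial(cfg),
                           relaxed_cfg)$screening
  expect_true(all(relaxed$include_kinematic >= strict$include_kinematic))
  expect_true(all(relaxed$include_kinetic >= strict$include_kinetic))
})
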