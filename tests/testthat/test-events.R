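test_that("gait events match ground truth on noiseless synthetic gait", {
  cfg <- noiseless_config(n_per_side = 0)
  sg <- generate_steady_gait(cfg, duration = 30)
  tr <- preprocess_trial(sg$trial)
  ev <- detect_gait_events(tr$markers, tr$marker_rate)
  for (side in c("left", "right")) {
    for (ty in c("heel_strike", "toe_off")) {
      gt <- if (ty == "heel_strike") sg$truth$heel_strikes[[side]]
      else sg$truth$toe_offs[[side]]
      det <- ev$time[ev$side == side & ev$type == ty]
      d <- vapply(gt, function(g) min(abs(det - g)), numeric(1))
      expect_lte(max(d), 1 / tr$marker_rate + 1e-9)
    }
  }
  # alternation within each side
  for (side in c("left", "right")) {
    ty <- ev$type[ev$side == side]
    expect_true(all(ty[-1] != ty[-length(ty)]))
  }
})

test_that("a stationary record yields no gait events", {
  m <- flat_markers(500)
  m$LHEE <- m$RHEE <- m$LTOE <- m$RTOE <-
    matrix(rep(c(0.1, 0.1, 0.05), each = 500), 500, 3)
  w <- capture_warnings(ev <- detect_gait_events(m, 100))
  expect_match(w, "fewer than two", all = TRUE)
  expect_equal(nrow(ev), 0)
})

test_that("event detection is translation invariant", {
  cfg <- noiseless_config(n_per_side = 0)
  sg <- generate_steady_gait(cfg, duration = 20)
  tr <- preprocess_trial(sg$trial)
  ev <- detect_gait_events(tr$markers, tr$marker_rate)
  shift <- 150L  # crop 1.5 s: all events shift by exactly -1.5 s
  tr2 <- tr
  tr2$markers <- lapply(tr$markers, function(m) m[-(1:shift), , drop = FALSE])
  ev2 <- detect_gait_events(tr2$markers, tr$marker_rate)
  dt <- shift / tr$marker_rate
  common <- ev$time > dt + 1 & ev$time < max(ev$time) - 1
  shifted <- ev$time[common] - dt
  for (ti in seq_along(shifted)) {
    sel <- ev2$side == ev$side[common][ti] & ev2$type == ev$type[common][ti]
    expect_lt(min(abs(ev2$time[sel] - shifted[ti])), 1e-9)
  }
})

test_that("time-reversed input mirrors the event sequence", {
  cfg <- noiseless_config(n_per_side = 0)
  sg <- generate_steady_gait(cfg, duration = 20)
  tr <- preprocess_trial(sg$trial)
  ev <- detect_gait_events(tr$markers, tr$marker_rate)
  n <- nrow(tr$markers$LHEE)
  trR <- tr
  trR$markers <- lapply(tr$markers, function(m) m[n:1, , drop = FALSE])
  evR <- detect_gait_events(trR$markers, tr$marker_rate)
  dur <- (n - 1) / tr$marker_rate
  # every interior strike reappears at the mirrored time
  interior <- ev$time > 2 & ev$time < dur - 2 & ev$type == "heel_strike"
  for (ti in ev$time[interior]) {
    sel <- evR$type == "heel_strike"
    expect_lte(min(abs(evR$time[sel] - (dur - ti))),
               2 / tr$marker_rate + 1e-9)
  }
})

test_that("perturbations are detected with onset, duration and stance side", {
  cc <- cached_trial()
  tr <- cc$res$trial
  pd <- detect_perturbations(tr$belt_speed, tr$force_rate, cc$res$events,
                             tr$meta)
  gt <- cc$truth$perturbations
  expect_equal(nrow(pd), nrow(gt))
  expect_true(all(abs(pd$onset - gt$onset) <= 2 / tr$force_rate))
  expect_equal(pd$side, gt$side)
  # 800 ms profile detected within 2 ms
  expect_true(all(abs(pd$duration - 0.8) <= 0.002))
  # constant belt speed: no perturbations
  pd0 <- detect_perturbations(rep(1, 5000), 1000, cc$res$events, tr$meta)
  expect_equal(nrow(pd0), 0)
  # an excursion that never returns is malformed
  sp <- c(rep(1, 1000), seq(1, 2, length.out = 1000))
  expect_error(detect_perturbations(sp, 1000, cc$res$events, tr$meta),
               class = "malformed_trial")
})

test_that("gait-cycle fraction interpolates between heel strikes", {
  ev <- data.frame(time = c(1, 1.7, 2.2, 2.9),
                   side = "left",
                   type = c("heel_strike", "toe_off", "heel_strike", "toe_off"))
  expect_equal(gait_cycle_fraction(1.0, ev, "left"), 0)
  expect_equal(gait_cycle_fraction(1.6, ev, "left"), 0.5)
  expect_error(gait_cycle_fraction(2.5, ev, "left"),
               class = "undefined_fraction")
  # synthetic onsets triggered at the 100 N crossing land in early stance
  cc <- cached_trial()
  for (i in seq_len(nrow(cc$truth$perturbations))) {
    p <- cc$truth$perturbations[i, ]
    expect_lt(gait_cycle_fraction(p$onset, cc$res$events, p$side), 0.20)
  }
})

test_that("recovery steps tile and alternate stance sides correctly", {
  cc <- cached_trial()
  for (i in seq_len(nrow(cc$truth$perturbations))) {
    p <- cc$truth$perturbations[i, ]
    seg <- segment_recovery_steps(p, cc$res$events)
    expect_equal(seg$label, c("pert", "rec1", "rec2", "rec3"))
    contra <- if (p$side == "left") "right" else "left"
    expect_equal(seg$stance_side, c(p$side, contra, p$side, contra))
    # tiling: each step ends where the next begins
    expect_equal(seg$end[1:3], seg$start[2:4])
    # boundaries are heel-strike times
    for (b in unique(c(seg$start, seg$end))) {
      strikes <- cc$res$events$time[cc$res$events$type == "heel_strike"]
      expect_lt(min(abs(strikes - b)), 1e-9)
    }
  }
  # intact-side perturbation: rec1 stance is prosthetic, rec2 intact
  p_int <- cc$truth$perturbations[cc$truth$perturbations$side_label == "intact", ][1, ]
  seg <- segment_recovery_steps(p_int, cc$res$events)
  pros <- cc$trial$meta$prosthetic_side
  expect_equal(seg$stance_side[seg$label == "rec1"], pros)
  expect_true(seg$stance_side[seg$label == "rec2"] != pros)
  # truncated recovery raises a structured error naming missing steps
  late <- list(onset = max(cc$res$events$time) - 0.2, side = p_int$side)
  expect_error(segment_recovery_steps(late, cc$res$events),
               class = "truncated_recovery")
})
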