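#' Generate a static (T-pose) force-plate trial
#'
#' Emits per-plate 3-D force series for a participant standing still, split
#' evenly across the two plates, so that the time-average magnitude of the
#' summed plate forces equals body weight (mass x 9.81 m/s^2) up to sensor
#' noise.
#'
#' @param config a [simulation_config()].
#' @param duration trial length (s).
#' @return an object of class `static_trial` with per-plate force matrices
#'   (columns `fx`, `fy`, `fz`, in N) and the sampling rate.
#' @export
generate_static_trial <- function(config, duration = 5) {
  if (config$participant_mass <= 0)
    abort_stumblr("participant mass must be positive", "invalid_config")
  if (duration <= 0)
    abort_stumblr("static trial duration must be positive", "invalid_config")
  n <- round(duration * config$force_rate)
  half <- config$participant_mass * GRAVITY / 2
  set.seed(config$seed + 5L)
  mk <- function() {
    noise <- if (config$force_noise_sd > 0)
      matrix(rnorm(3 * n, sd = config$force_noise_sd), n, 3) else matrix(0, n, 3)
    out <- noise
    out[, 3] <- out[, 3] + half
    colnames(out) <- c("fx", "fy", "fz")
    out
  }
  structure(list(forces = list(left = mk(), right = mk()),
                 rate = config$force_rate, duration = duration),
            class = "static_trial")
}

#' Generate a steady unperturbed treadmill walking trial
#'
#' Builds periodic gait at the configured cadence from smooth harmonic
#' templates: per-side stance vertical GRF is a double-hump curve (zero in
#' swing), the heel marker's anterior-posterior position relative to the
#' pelvis peaks at each heel strike and the toe marker's attains its
#' minimum at each toe-off, the trunk axis oscillates with a small baseline
#' amplitude, and the finger markers swing continuously.
#'
#' @param config a [simulation_config()].
#' @param duration trial length (s).
#' @return a list with elements `trial` (a `trial_recording`) and `truth`
#'   (a `ground_truth` with per-side heel-strike and toe-off times).
#' @export
generate_steady_gait <- function(config, duration = 60) {
  plan <- new_gait_plan(config, duration)
  if (plan$n_stride < 2)
    abort_stumblr("trial too short for two gait cycles", "invalid_config")
  trial <- render_trial(plan)
  list(trial = trial, truth = plan_ground_truth(plan))
}

#' Triangular belt-speed perturbation profile
#'
#' Belt speed holds at `v0` outside the perturbation and follows a
#' piecewise-linear triangle inside it: accelerating at `accel` for the
#' first half of `duration` and decelerating at the same rate for the
#' second half, peaking at `v0 + accel * duration / 2`.
#'
#' @param v0 steady belt speed (m/s).
#' @param accel belt acceleration magnitude (m/s^2).
#' @param duration total perturbation duration (s).
#' @param onset perturbation onset time (s).
#' @param rate sampling rate of the returned series (Hz).
#' @param total_duration length of the returned series (s).
#' @return numeric belt-speed series sampled at `rate` from t = 0.
#' @export
make_belt_profile <- function(v0, accel, duration, onset, rate,
                              total_duration = onset + duration + 1) {
  if (v0 <= 0 || duration <= 0 || onset < 0 || rate <= 0 || accel < 0)
    abort_stumblr("belt profile arguments must be positive", "invalid_config")
  n <- round(total_duration * rate)
  apply_belt_pulses(rep(v0, n), rate, v0,
                    data.frame(onset = onset, duration = duration,
                               accel = accel))
}

#' Schedule GRF-triggered belt perturbations into a steady trial
#'
#' Places the configured number of perturbations per side, sides drawn by
#' seeded permutation, onsets at least `min_spacing` strides apart.  Each
#' onset is the first force sample of the chosen stance at which that
#' side's vertical GRF exceeds 100 N, emulating the treadmill's early
#' stance trigger; the belt-speed series receives the triangular profile at
#' that sample.
#'
#' @param trial a `trial_recording` from [generate_steady_gait()].
#' @param truth its `ground_truth`.
#' @param config the [simulation_config()] used to build the trial.
#' @param trigger_force vertical GRF trigger threshold (N).
#' @return updated `list(trial, truth)` with perturbations recorded in the
#'   ground truth (onset, side, duration, onset gait-cycle fraction).
#' @export
schedule_perturbations <- function(trial, truth, config, trigger_force = 100) {
  plan <- trial$plan
  n_side <- config$n_perturbations_per_side
  if (n_side == 0) return(list(trial = trial, truth = truth))
  n_tot <- 2L * n_side
  set.seed(config$seed + 1L)
  sides <- sample(rep(c("left", "right"), each = n_side))
  jitter <- sample(0:2, n_tot, replace = TRUE)
  stride_idx <- cumsum(c(2L, head(config$min_spacing + 1L + jitter, -1L)))
  last_needed <- plan$first_strike[["right"]] +
    max(stride_idx) * plan$T_stride + 4 * plan$T_step + config$padding
  if (max(stride_idx) >= plan$n_stride || last_needed > plan$duration)
    abort_stumblr(sprintf(
      "trial too short to fit %d perturbations at %d-stride spacing: needs %.1f s, has %.1f s",
      n_tot, config$min_spacing, last_needed, plan$duration), "scheduling_error")

  ordinal <- stats::ave(seq_len(n_tot), sides, FUN = seq_along)
  side_label <- ifelse(sides == config$prosthetic_side, "prosthetic", "intact")
  perts <- data.frame(id = seq_len(n_tot), side = sides,
                      side_label = side_label,
                      stance_index = stride_idx,
                      stance_time = plan$first_strike[sides] +
                        stride_idx * plan$T_stride,
                      onset = NA_real_, duration = config$perturbation_duration,
                      cycle_fraction = NA_real_, block = 1L,
                      side_ordinal = as.integer(ordinal))
  for (i in seq_len(n_tot)) {
    perts$onset[i] <- plan_trigger_onset(plan, perts$side[i],
                                         perts$stance_index[i], trigger_force)
    perts$cycle_fraction[i] <- (perts$onset[i] - perts$stance_time[i]) /
      plan$T_stride
  }
  plan$perturbations <- perts
  plan$belt_pulses <- data.frame(onset = perts$onset,
                                 duration = perts$duration,
                                 accel = config$perturbation_accel)
  trial <- render_trial(plan)
  list(trial = trial, truth = plan_ground_truth(plan))
}

#' Inject step-wise stumble responses after each scheduled perturbation
#'
#' For each perturbation and each step label (`pert`, `rec1`, `rec2`,
#' `rec3`) the trunk-angle trace is reshaped into a raised-cosine flexion
#' excursion and the stance GRF first-hump peak is re-targeted so that the
#' step's trunk angular sway, peak flexion angular velocity and first
#' ||GRF|| peak equal baseline + effect-profile offset + Gaussian noise.
#' The realized targets are recorded in the ground truth; traces remain
#' continuous at step boundaries.
#'
#' @inheritParams schedule_perturbations
#' @return updated `list(trial, truth)` with `truth$injected` holding the
#'   realized per-step metric values.
#' @export
inject_recovery_response <- function(trial, truth, config) {
  plan <- trial$plan
  perts <- plan$perturbations
  if (!nrow(perts)) return(list(trial = trial, truth = truth))
  base <- config$baseline_profile
  eff <- config$effect_profile
  ## the flexion excursion (delay + rise + fall) must fit inside one step;
  ## the rise-duration band and fall length are calibrated so the 6 Hz
  ## zero-phase marker filter reproduces the analytic sway and peak
  ## velocity to well under 1% (shorter rises are eroded, shorter falls
  ## ring into the sway range)
  avail <- plan$T_step - 0.03 - plan$pulse_delay
  rise_min <- 0.23
  fall_len <- 0.26
  if (avail - fall_len < rise_min) {  # very high cadence: best-effort split
    rise_min <- 0.45 * avail
    fall_len <- 0.50 * avail
  }
  rise_max <- avail - fall_len
  set.seed(config$seed + 2L)
  rows <- vector("list", nrow(perts) * 4L)
  pulses <- plan$trunk_pulses
  overrides <- plan$grf_overrides
  for (i in seq_len(nrow(perts))) {
    p <- perts[i, ]
    off <- eff[[p$side_label]]
    contra <- if (p$side == "left") "right" else "left"
    for (k in 0:3) {
      lab <- STEP_LABELS[k + 1]
      stance_side <- if (k %% 2 == 0) p$side else contra
      grf_clean <- base$grf[[lab]] + off[lab, "grf"]
      if (grf_clean <= 0)
        abort_stumblr("effect profile produces a non-positive GRF peak",
                      "invalid_config")
      A <- base$sway[[lab]] + off[lab, "sway"] +
        rnorm(1, sd = config$noise_sd[["sway"]])
      v <- base$vel[[lab]] + off[lab, "vel"] +
        rnorm(1, sd = config$noise_sd[["vel"]])
      g <- grf_clean + rnorm(1, sd = config$noise_sd[["grf"]])
      A <- max(A, 0.3)
      rise <- pi * A / (2 * v)
      rise <- min(max(rise, rise_min), rise_max)
      v <- pulse_peak_velocity(A, rise)   # realized peak flexion velocity
      g <- max(g, 30)
      wstart <- p$stance_time + k * plan$T_step
      pulses <- rbind(pulses,
                      data.frame(start = wstart, A = A, rise = rise,
                                 fall = fall_len))
      st_idx <- round((wstart - plan$first_strike[[stance_side]]) /
                        plan$T_stride)
      overrides <- rbind(overrides,
                         data.frame(side = stance_side, stance_index = st_idx,
                                    v1 = g, v2 = max(g - 5, 20)))
      rows[[(i - 1) * 4 + k + 1]] <- data.frame(
        pert_id = p$id, label = lab, stance_side = stance_side,
        sway = A, vel = v, grf = g)
    }
  }
  plan$trunk_pulses <- pulses
  plan$grf_overrides <- overrides
  plan$injected <- do.call(rbind, rows)
  ## the perturbed stance's first hump changed: recompute trigger onsets
  for (i in seq_len(nrow(perts))) {
    perts$onset[i] <- plan_trigger_onset(plan, perts$side[i],
                                         perts$stance_index[i])
    perts$cycle_fraction[i] <- (perts$onset[i] - perts$stance_time[i]) /
      plan$T_stride
  }
  plan$perturbations <- perts
  plan$belt_pulses$onset <- perts$onset
  trial <- render_trial(plan)
  list(trial = trial, truth = plan_ground_truth(plan))
}

#' Corrupt a perturbed trial with the failure modes screened downstream
#'
#' With the configured probabilities each perturbation may receive (a) a
#' handrail grab: both finger markers freeze (speed < 5 cm/s) for 0.3 s
#' shortly after the first recovery heel strike; (b) a contiguous marker
#' dropout covering `dropout_fraction` of the four-step recovery window;
#' (c) a mid-line crossing: the contralateral plate carries an extra 30 N
#' vertical load for one full gait cycle.  All insertions are logged in the
#' ground truth.  Zero probabilities return the inputs unchanged.
#'
#' @inheritParams schedule_perturbations
#' @param dropout_marker marker receiving injected dropouts.
#' @return updated `list(trial, truth)`.
#' @export
corrupt_trial <- function(trial, truth, config, dropout_marker = "C7") {
  if (config$handrail_grab_probability == 0 &&
      config$dropout_probability == 0 &&
      config$midline_cross_probability == 0)
    return(list(trial = trial, truth = truth))
  plan <- trial$plan
  perts <- plan$perturbations
  set.seed(config$seed + 3L)
  window <- 4 * plan$T_step
  for (i in seq_len(nrow(perts))) {
    p <- perts[i, ]
    draws <- stats::runif(3)
    if (draws[1] < config$handrail_grab_probability) {
      start <- p$stance_time + plan$T_step + 0.10
      plan$grabs <- rbind(plan$grabs,
                          data.frame(pert_id = p$id, start = start,
                                     end = start + 0.30))
    }
    if (draws[2] < config$dropout_probability) {
      start <- p$stance_time + 0.5 * plan$T_step
      plan$dropouts <- rbind(plan$dropouts, data.frame(
        pert_id = p$id, marker = dropout_marker, start = start,
        end = start + config$dropout_fraction * window,
        fraction = config$dropout_fraction))
    }
    if (draws[3] < config$midline_cross_probability) {
      contra <- if (p$side == "left") "right" else "left"
      start <- p$stance_time + plan$T_step
      plan$midline <- rbind(plan$midline, data.frame(
        pert_id = p$id, plate = contra, start = start,
        end = start + plan$T_stride, extra = 30))
    }
  }
  trial <- render_trial(plan)
  list(trial = trial, truth = plan_ground_truth(plan))
}

#' Simulate a complete perturbation walking block
#'
#' Convenience wrapper: steady gait sized to hold the requested
#' perturbations, scheduling, recovery-response injection and corruption,
#' in that order.
#'
#' @param config a [simulation_config()].
#' @return `list(trial, truth)`.
#' @export
simulate_trial <- function(config) {
  n_tot <- 2 * config$n_perturbations_per_side
  T_stride <- 120 / config$cadence
  duration <- 2 * config$padding +
    (n_tot * (config$min_spacing + 3) + 6) * T_stride
  sg <- generate_steady_gait(config, duration = duration)
  sg <- schedule_perturbations(sg$trial, sg$truth, config)
  sg <- inject_recovery_response(sg$trial, sg$truth, config)
  corrupt_trial(sg$trial, sg$truth, config)
}

#' Ground-truth expected screening outcome of a synthetic trial
#'
#' Applies the screening rules analytically to a ground-truth annotation:
#' warm-up exclusion of the first `n_warmup` perturbations per side, the
#' onset-phase window, injected handrail grabs, injected marker dropouts
#' against the completeness bound, and injected mid-line crossings.
#'
#' @param truth a `ground_truth` from the generator.
#' @param cfg a [pipeline_config()].
#' @return data frame with one row per perturbation and logical columns
#'   `include_kinematic`, `include_kinetic`, `handrail_grab`.
#' @export
ground_truth_inclusion <- function(truth, cfg = pipeline_config()) {
  p <- truth$perturbations
  warm <- p$side_ordinal <= cfg$n_warmup
  onset_ok <- p$cycle_fraction <= cfg$onset_max_fraction
  grab <- p$id %in% truth$grabs$pert_id
  bad_drop <- truth$dropouts$pert_id[truth$dropouts$fraction >
                                       cfg$max_missing_fraction]
  kin_complete <- !(p$id %in% bad_drop)
  kinetic_sep <- !(p$id %in% truth$midline$pert_id)
  data.frame(pert_id = p$id, side = p$side, side_label = p$side_label,
             warmup_excluded = warm, onset_phase_ok = onset_ok,
             handrail_grab = grab, kinematic_complete = kin_complete,
             kinetic_separated = kinetic_sep,
             include_kinematic = !warm & onset_ok & !grab & kin_complete,
             include_kinetic = !warm & onset_ok & !grab & kinetic_sep)
}
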