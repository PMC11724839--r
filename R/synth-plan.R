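## Internal representation of a synthetic trial: a "gait plan" holds the
## timing skeleton (periodic heel strikes), per-stance force-peak targets,
## trunk excursion pulses, belt-speed pulses and corruption intervals.
## render_trial() turns a plan into sampled marker/force/belt series, so
## every generator operation edits the plan and re-renders; identical plans
## render bit-identically.

MARKER_NAMES <- c("LHEE", "RHEE", "LTOE", "RTOE", "LFIN", "RFIN",
                  "SACR", "LASI", "RASI", "C7", "CLAV")
STEP_LABELS <- c("pert", "rec1", "rec2", "rec3")

## raised-cosine hump: 0.5 * (1 + cos(pi * (s - centre) / width)) on
## |s - centre| < width, zero elsewhere
raised_cosine <- function(s, centre, width) {
  u <- (s - centre) / width
  out <- numeric(length(s))
  in_support <- !is.na(u) & abs(u) < 1
  out[in_support] <- 0.5 * (1 + cos(pi * u[in_support]))
  out
}

new_gait_plan <- function(config, duration) {
  T_step <- 60 / config$cadence
  T_stride <- 2 * T_step
  stance_dur <- config$stance_fraction * T_stride
  if (stance_dur <= 2 / config$marker_rate)
    abort_stumblr("cadence implies a non-positive (or sub-sample) stance time",
                  "invalid_config")
  ## first strikes on the marker grid; left leads by convention
  t0 <- round(2 * T_step * config$marker_rate) / config$marker_rate
  first_strike <- c(left = t0, right = t0 + T_step)
  n_stride <- floor((duration - t0) / T_stride)
  list(
    config = config,
    duration = duration,
    T_step = T_step,
    T_stride = T_stride,
    stance_dur = stance_dur,
    first_strike = first_strike,
    n_stride = n_stride,
    theta0 = 5,          # standing forward lean (deg)
    theta_base_amp = 1,  # steady-gait trunk oscillation amplitude (deg)
    pulse_delay = 0.05,  # excursion onset after the step's heel strike (s)
    trunk_len = 0.45,    # pelvis-to-shoulder axis length (m)
    heel_amp = 0.30,     # heel AP excursion relative to pelvis (m)
    toe_amp = 0.30,
    arm_amp = c(0.18, 0.05),  # AP / vertical finger swing amplitudes (m)
    grf_overrides = data.frame(side = character(), stance_index = integer(),
                               v1 = numeric(), v2 = numeric()),
    trunk_pulses = data.frame(start = numeric(), A = numeric(),
                              rise = numeric(), fall = numeric()),
    belt_pulses = data.frame(onset = numeric(), duration = numeric(),
                             accel = numeric()),
    perturbations = data.frame(id = integer(), side = character(),
                               side_label = character(), stance_time = numeric(),
                               onset = numeric(), duration = numeric(),
                               cycle_fraction = numeric(), block = integer(),
                               side_ordinal = integer()),
    injected = data.frame(pert_id = integer(), label = character(),
                          stance_side = character(), sway = numeric(),
                          vel = numeric(), grf = numeric()),
    grabs = data.frame(pert_id = integer(), start = numeric(), end = numeric()),
    dropouts = data.frame(pert_id = integer(), marker = character(),
                          start = numeric(), end = numeric(),
                          fraction = numeric()),
    midline = data.frame(pert_id = integer(), plate = character(),
                         start = numeric(), end = numeric(),
                         extra = numeric())
  )
}

plan_strikes <- function(plan, side) {
  plan$first_strike[[side]] + (seq_len(plan$n_stride) - 1) * plan$T_stride
}

## per-stance first/second hump peaks (%BW) with overrides applied
plan_stance_peaks <- function(plan, side) {
  steady <- plan$config$baseline_profile$steady_peaks
  v1 <- rep(steady[1], plan$n_stride)
  v2 <- rep(steady[2], plan$n_stride)
  ov <- plan$grf_overrides[plan$grf_overrides$side == side, , drop = FALSE]
  if (nrow(ov)) {
    v1[ov$stance_index + 1L] <- ov$v1
    v2[ov$stance_index + 1L] <- ov$v2
  }
  list(v1 = v1, v2 = v2)
}

## analytic trunk angle (deg) on an arbitrary time grid: a small baseline
## oscillation at the step frequency (zero at every heel strike), replaced
## within each response step by an asymmetric flexion excursion — a
## half-cosine rise of duration `rise` (peak flexion velocity
## pi * A / (2 * rise)) followed by a half-cosine fall of duration `fall`
plan_trunk_angle <- function(plan, t) {
  osc <- plan$theta_base_amp *
    sin(2 * pi * (t - plan$first_strike[["left"]]) / plan$T_step)
  ## fade the baseline oscillation out around each response region so the
  ## zero-phase filter carries no oscillation energy across its boundaries
  if (nrow(plan$perturbations)) {
    scale <- rep(1, length(t))
    ramp <- 0.3
    for (i in seq_len(nrow(plan$perturbations))) {
      w0 <- plan$perturbations$stance_time[i]
      w1 <- w0 + 4 * plan$T_step
      pre <- t >= w0 - ramp & t < w0
      scale[pre] <- pmin(scale[pre], (w0 - t[pre]) / ramp)
      inside <- t >= w0 & t <= w1
      scale[inside] <- 0
      post <- t > w1 & t <= w1 + ramp
      scale[post] <- pmin(scale[post], (t[post] - w1) / ramp)
    }
    osc <- osc * scale
  }
  theta <- plan$theta0 + osc
  if (nrow(plan$trunk_pulses)) {
    for (i in seq_len(nrow(plan$trunk_pulses))) {
      p <- plan$trunk_pulses[i, ]
      in_win <- t >= p$start & t < p$start + plan$T_step
      theta[in_win] <- plan$theta0
      ## the excursion starts a beat after the heel strike so that the
      ## zero-phase filter's precursor stays inside the same step
      u <- t - p$start - plan$pulse_delay
      rising <- in_win & u >= 0 & u <= p$rise
      theta[rising] <- plan$theta0 +
        p$A * 0.5 * (1 - cos(pi * u[rising] / p$rise))
      falling <- in_win & u > p$rise & u <= p$rise + p$fall
      theta[falling] <- plan$theta0 +
        p$A * 0.5 * (1 + cos(pi * (u[falling] - p$rise) / p$fall))
    }
  }
  theta
}

## peak trunk flexion velocity (deg/s) implied by a rise duration
pulse_peak_velocity <- function(A, rise) pi * A / (2 * rise)

## clean vertical GRF (N) of one side on an arbitrary time grid; also
## returns the stance phase u used for shear components
plan_side_grf <- function(plan, side, t) {
  bw_n <- plan$config$participant_mass * GRAVITY
  s1 <- plan$first_strike[[side]]
  k <- floor((t - s1) / plan$T_stride)
  u <- (t - s1 - k * plan$T_stride) / plan$stance_dur
  in_stance <- k >= 0 & u >= 0 & u <= 1
  peaks <- plan_stance_peaks(plan, side)
  fz <- numeric(length(t))
  ki <- pmin(k[in_stance] + 1L, plan$n_stride)  # steady peaks past the table
  ui <- u[in_stance]
  fz[in_stance] <- bw_n / 100 *
    (peaks$v1[ki] * raised_cosine(ui, 0.25, 0.25) +
     peaks$v2[ki] * raised_cosine(ui, 0.75, 0.25))
  u[!in_stance] <- NA_real_
  list(fz = fz, u = u)
}

## first force sample of a stance at which the clean vertical GRF exceeds
## 100 N (the perturbation trigger reference)
plan_trigger_onset <- function(plan, side, stance_index, trigger_force = 100) {
  strike <- plan$first_strike[[side]] + stance_index * plan$T_stride
  rate <- plan$config$force_rate
  ## probe on the actual force sample grid so the onset is a real sample
  j0 <- ceiling(strike * rate)
  j <- j0:(j0 + ceiling(0.5 * plan$stance_dur * rate))
  t <- j / rate
  fz <- plan_side_grf(plan, side, t)$fz
  hit <- which(fz > trigger_force)
  if (!length(hit))
    abort_stumblr("stance vertical GRF never exceeds the trigger force",
                  "invalid_config")
  t[hit[1]]
}

apply_belt_pulses <- function(speed, rate, v0, pulses) {
  if (!nrow(pulses)) return(speed)
  t <- (seq_along(speed) - 1) / rate
  for (i in seq_len(nrow(pulses))) {
    p <- pulses[i, ]
    in_p <- t >= p$onset & t <= p$onset + p$duration
    dt <- t[in_p] - p$onset
    speed[in_p] <- v0 + p$accel * pmin(dt, p$duration - dt)
  }
  speed
}

render_trial <- function(plan) {
  cfg <- plan$config
  nm <- round(plan$duration * cfg$marker_rate)
  nf <- round(plan$duration * cfg$force_rate)
  tm <- (seq_len(nm) - 1) / cfg$marker_rate
  tf <- (seq_len(nf) - 1) / cfg$force_rate

  ## ---- markers -----------------------------------------------------------
  theta <- plan_trunk_angle(plan, tm) * pi / 180
  pelvis <- c(0, 0, 0.95)
  markers <- list(
    SACR = cbind(pelvis[1] - 0.12, pelvis[2] + 0, pelvis[3] + 0.02),
    LASI = cbind(pelvis[1] + 0.10, pelvis[2] + 0.12, pelvis[3]),
    RASI = cbind(pelvis[1] + 0.10, pelvis[2] - 0.12, pelvis[3])
  )
  markers <- lapply(markers, function(m) matrix(rep(m, each = nm), nm, 3))
  centroid <- (markers$SACR + markers$LASI + markers$RASI) / 3
  mid <- centroid + plan$trunk_len * cbind(sin(theta), 0, cos(theta))
  markers$C7 <- mid + matrix(rep(c(-0.05, 0, 0), each = nm), nm, 3)
  markers$CLAV <- mid + matrix(rep(c(0.05, 0, 0), each = nm), nm, 3)

  for (side in c("left", "right")) {
    s1 <- plan$first_strike[[side]]
    ysign <- if (side == "left") 1 else -1
    ph_stride <- 2 * pi * (tm - s1) / plan$T_stride
    heel <- cbind(centroid[, 1] + plan$heel_amp * cos(ph_stride),
                  ysign * 0.10,
                  0.05 + 0.02 * pmax(0, -sin(ph_stride)))
    to1 <- s1 + plan$stance_dur
    ph_toe <- 2 * pi * (tm - to1) / plan$T_stride
    toe <- cbind(centroid[, 1] + 0.02 - plan$toe_amp * cos(ph_toe),
                 ysign * 0.10,
                 0.03 + 0.02 * pmax(0, -sin(ph_toe)))
    ## arms swing anti-phase with the ipsilateral leg; the elliptical AP /
    ## vertical path keeps finger speed well above the grab threshold
    ph_arm <- 2 * pi * (tm - s1) / plan$T_stride + pi
    fing <- cbind(0.05 + plan$arm_amp[1] * sin(ph_arm),
                  ysign * 0.35,
                  0.85 + plan$arm_amp[2] * cos(ph_arm))
    pre <- if (side == "left") "L" else "R"
    markers[[paste0(pre, "HEE")]] <- heel
    markers[[paste0(pre, "TOE")]] <- toe
    markers[[paste0(pre, "FIN")]] <- fing
  }
  markers <- markers[MARKER_NAMES]

  if (cfg$marker_noise_sd > 0) {
    set.seed(cfg$seed + 101L)
    for (nm_i in MARKER_NAMES)
      markers[[nm_i]] <- markers[[nm_i]] +
        matrix(rnorm(3 * nm, sd = cfg$marker_noise_sd), nm, 3)
  }

  ## handrail grabs: both finger markers freeze, then blend back
  if (nrow(plan$grabs)) {
    for (i in seq_len(nrow(plan$grabs))) {
      g <- plan$grabs[i, ]
      for (fm in c("LFIN", "RFIN")) {
        idx <- window_indices(g$start, g$end, cfg$marker_rate, nm)
        if (!length(idx)) next
        p0 <- markers[[fm]][idx[1], ]
        markers[[fm]][idx, ] <- matrix(rep(p0, each = length(idx)),
                                       length(idx), 3)
        bidx <- window_indices(g$end, g$end + 0.15, cfg$marker_rate, nm)
        if (length(bidx)) {
          w <- (seq_along(bidx)) / (length(bidx) + 1)
          markers[[fm]][bidx, ] <- (1 - w) %o% p0 + w * markers[[fm]][bidx, ]
        }
      }
    }
  }

  marker_valid <- setNames(lapply(MARKER_NAMES, function(x) rep(TRUE, nm)),
                           MARKER_NAMES)
  if (nrow(plan$dropouts)) {
    for (i in seq_len(nrow(plan$dropouts))) {
      d <- plan$dropouts[i, ]
      idx <- window_indices(d$start, d$end, cfg$marker_rate, nm)
      marker_valid[[d$marker]][idx] <- FALSE
      markers[[d$marker]][idx, ] <- NA_real_
    }
  }

  ## ---- forces ------------------------------------------------------------
  forces <- list()
  for (side in c("left", "right")) {
    g <- plan_side_grf(plan, side, tf)
    shear <- sin(4 * pi * g$u)
    shear[is.na(shear)] <- 0
    fx <- 0.15 * g$fz * shear
    fy <- (if (side == "left") 1 else -1) * 0.05 * g$fz * shear
    forces[[side]] <- cbind(fx = fx, fy = fy, fz = g$fz)
  }
  if (nrow(plan$midline)) {
    for (i in seq_len(nrow(plan$midline))) {
      m <- plan$midline[i, ]
      idx <- window_indices(m$start, m$end, cfg$force_rate, nf)
      forces[[m$plate]][idx, "fz"] <- forces[[m$plate]][idx, "fz"] + m$extra
    }
  }
  if (cfg$force_noise_sd > 0) {
    set.seed(cfg$seed + 202L)
    for (side in c("left", "right"))
      forces[[side]] <- forces[[side]] +
        matrix(rnorm(3 * nf, sd = cfg$force_noise_sd), nf, 3)
  }

  belt <- apply_belt_pulses(rep(cfg$preferred_speed, nf), cfg$force_rate,
                            cfg$preferred_speed, plan$belt_pulses)

  structure(list(
    marker_rate = cfg$marker_rate,
    force_rate = cfg$force_rate,
    markers = markers,
    marker_valid = marker_valid,
    forces = forces,
    belt_speed = belt,
    meta = list(participant_mass = cfg$participant_mass,
                snp_condition = cfg$snp_condition,
                perturbation_duration = cfg$perturbation_duration,
                prosthetic_side = cfg$prosthetic_side,
                preferred_speed = cfg$preferred_speed,
                cadence = cfg$cadence,
                block = 1L),
    plan = plan
  ), class = "trial_recording")
}

plan_ground_truth <- function(plan) {
  strikes <- lapply(c(left = "left", right = "right"),
                    function(s) plan_strikes(plan, s))
  toe_offs <- lapply(strikes, function(s) {
    t <- s + plan$stance_dur
    t[t <= plan$duration]
  })
  structure(list(
    heel_strikes = strikes,
    toe_offs = toe_offs,
    perturbations = plan$perturbations,
    injected = plan$injected,
    grabs = plan$grabs,
    dropouts = plan$dropouts,
    midline = plan$midline
  ), class = "ground_truth")
}
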