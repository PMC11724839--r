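#' Configuration for the synthetic treadmill-trial generator
#'
#' Bundles every tunable of the synthetic gait simulator.  Defaults encode
#' the study conditions: a split-belt instrumented treadmill accelerating at
#' 3 m/s^2 for the first half of the perturbation and decelerating at the
#' same rate for the second half, perturbations triggered in early stance
#' when the vertical ground reaction force exceeds 100 N, 12 perturbations
#' per side spaced at least 10 strides apart, markers sampled at 100 Hz and
#' force plates at 1000 Hz.
#'
#' @param preferred_speed steady belt speed (m/s).
#' @param cadence steps per minute; the step period is `60/cadence` s.
#' @param marker_rate marker sampling rate (Hz).
#' @param force_rate force-plate sampling rate (Hz).
#' @param participant_mass body mass (kg).
#' @param perturbation_accel belt acceleration during a perturbation (m/s^2).
#' @param perturbation_duration total perturbation duration (s); 0.8 or 0.6
#'   in the study conditions.
#' @param n_perturbations_per_side perturbations delivered to each side.
#' @param min_spacing minimum spacing between perturbation onsets (strides).
#' @param snp_condition `"active"` or `"inactive"` sensory-neuroprosthesis
#'   condition; carried into trial metadata and used to key effect offsets.
#' @param prosthetic_side which belt/limb is prosthetic, `"left"` or
#'   `"right"`.
#' @param effect_profile per-step additive offsets on the three outcome
#'   metrics, keyed by perturbed side and step label; see [effect_profile()].
#' @param baseline_profile per-step baseline targets for trunk sway (deg),
#'   peak flexion velocity (deg/s) and first-peak ||GRF|| (%BW); see
#'   [baseline_profile()].
#' @param noise_sd named numeric: Gaussian standard deviation added to each
#'   per-step metric target, components `sway` (deg), `vel` (deg/s),
#'   `grf` (%BW).
#' @param marker_noise_sd white positional noise on every marker coordinate
#'   (m); 1 mm emulates optical-capture jitter.
#' @param force_noise_sd white noise on every force component (N).
#' @param handrail_grab_probability probability that a perturbation is
#'   followed by a handrail grab.
#' @param dropout_probability probability that a perturbation's recovery
#'   window receives a contiguous marker dropout.
#' @param dropout_fraction length of an injected dropout as a fraction of
#'   the four-step recovery window.
#' @param midline_cross_probability probability that a perturbation's
#'   recovery is corrupted by the swing foot loading the contralateral
#'   plate (mid-line crossing).
#' @param stance_fraction stance duration as a fraction of the stride.
#' @param padding lead-in/lead-out walking time (s) before the first and
#'   after the last schedulable stride.
#' @param seed integer seed; identical configurations render bit-identical
#'   trials.
#'
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(preferred_speed = 1.0,
                              cadence = 90,
                              marker_rate = 100,
                              force_rate = 1000,
                              participant_mass = 75,
                              perturbation_accel = 3,
                              perturbation_duration = 0.8,
                              n_perturbations_per_side = 12,
                              min_spacing = 10,
                              snp_condition = c("inactive", "active"),
                              prosthetic_side = c("right", "left"),
                              effect_profile = NULL,
                              baseline_profile = NULL,
                              noise_sd = c(sway = 1.6, vel = 8, grf = 10),
                              marker_noise_sd = 0.001,
                              force_noise_sd = 2,
                              handrail_grab_probability = 0,
                              dropout_probability = 0,
                              dropout_fraction = 0.06,
                              midline_cross_probability = 0,
                              stance_fraction = 0.62,
                              padding = 5,
                              seed = 1L) {
  snp_condition <- match.arg(snp_condition)
  prosthetic_side <- match.arg(prosthetic_side)
  if (marker_rate <= 0 || force_rate <= 0)
    abort_stumblr("sampling rates must be positive", "invalid_config")
  if (participant_mass <= 0)
    abort_stumblr("participant mass must be positive", "invalid_config")
  if (perturbation_accel <= 0)
    abort_stumblr("perturbation acceleration must be positive", "invalid_config")
  if (perturbation_duration <= 0)
    abort_stumblr("perturbation duration must be positive", "invalid_config")
  if (cadence <= 0 || preferred_speed <= 0)
    abort_stumblr("cadence and preferred speed must be positive", "invalid_config")
  probs <- c(handrail_grab_probability, dropout_probability,
             midline_cross_probability, dropout_fraction)
  if (any(probs < 0 | probs > 1))
    abort_stumblr("probabilities and fractions must lie in [0, 1]", "invalid_config")
  if (stance_fraction <= 0 || stance_fraction >= 1)
    abort_stumblr("stance fraction must lie in (0, 1)", "invalid_config")
  noise <- c(sway = 0, vel = 0, grf = 0)
  noise[names(noise_sd)] <- noise_sd
  if (any(noise < 0))
    abort_stumblr("noise standard deviations must be non-negative", "invalid_config")
  cfg <- list(
    preferred_speed = preferred_speed,
    cadence = cadence,
    marker_rate = marker_rate,
    force_rate = force_rate,
    participant_mass = participant_mass,
    perturbation_accel = perturbation_accel,
    perturbation_duration = perturbation_duration,
    n_perturbations_per_side = n_perturbations_per_side,
    min_spacing = min_spacing,
    snp_condition = snp_condition,
    prosthetic_side = prosthetic_side,
    effect_profile = effect_profile %||% effect_profile_zero(),
    baseline_profile = baseline_profile %||% baseline_profile(),
    noise_sd = noise,
    marker_noise_sd = marker_noise_sd,
    force_noise_sd = force_noise_sd,
    handrail_grab_probability = handrail_grab_probability,
    dropout_probability = dropout_probability,
    dropout_fraction = dropout_fraction,
    midline_cross_probability = midline_cross_probability,
    stance_fraction = stance_fraction,
    padding = padding,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' Baseline per-step targets for the synthetic stumble response
#'
#' Targets for the four analysed steps (perturbation step and three
#' recovery steps).  Trunk sway and peak flexion velocity decay over the
#' recovery sequence; the first ||GRF|| peak is elevated on the
#' perturbation and first recovery steps.  Values are in degrees, degrees
#' per second and percent body weight.
#'
#' @param sway named per-step trunk angular sway targets (deg).
#' @param vel named per-step peak trunk flexion angular velocity targets
#'   (deg/s).
#' @param grf named per-step first-peak ||GRF|| targets (%BW).
#' @param steady_peaks first and second hump peaks of an unperturbed
#'   stance (%BW).
#' @return a list with elements `sway`, `vel`, `grf`, `steady_peaks`.
#' @export
baseline_profile <- function(sway = c(pert = 7, rec1 = 5, rec2 = 3.5, rec3 = 2.5),
                             vel = c(pert = 39, rec1 = 28, rec2 = 20, rec3 = 14),
                             grf = c(pert = 115, rec1 = 112, rec2 = 110, rec3 = 108),
                             steady_peaks = c(110, 105)) {
  labs <- c("pert", "rec1", "rec2", "rec3")
  stopifnot(all(labs %in% names(sway)), all(labs %in% names(vel)),
            all(labs %in% names(grf)))
  list(sway = sway[labs], vel = vel[labs], grf = grf[labs],
       steady_peaks = steady_peaks)
}

#' Per-step effect offsets keyed by perturbed side
#'
#' Additive offsets applied to the baseline per-step metric targets,
#' separately for intact-side and prosthetic-side perturbations.  Each
#' argument is a 4 x 3 arrangement: one row per step label
#' (`pert`, `rec1`, `rec2`, `rec3`) and columns `sway` (deg), `vel`
#' (deg/s), `grf` (%BW).
#'
#' @param intact,prosthetic matrices (or data frames) of offsets with rows
#'   `pert`, `rec1`, `rec2`, `rec3` and columns `sway`, `vel`, `grf`.
#' @return a list of class `effect_profile`.
#' @export
effect_profile <- function(intact = NULL, prosthetic = NULL) {
  zero <- matrix(0, 4, 3, dimnames = list(c("pert", "rec1", "rec2", "rec3"),
                                          c("sway", "vel", "grf")))
  fix <- function(m) {
    if (is.null(m)) return(zero)
    m <- as.matrix(m)
    out <- zero
    out[rownames(m), colnames(m)] <- m
    out
  }
  structure(list(intact = fix(intact), prosthetic = fix(prosthetic)),
            class = "effect_profile")
}

effect_profile_zero <- function() effect_profile()

#' Pipeline configuration with the study's screening and filter constants
#'
#' Every numeric constant used by the analysis stages is reachable from
#' this object: 6 Hz and 10 Hz fourth-order zero-phase Butterworth cutoffs
#' for markers and forces, a window-3 median filter, the 100 N perturbation
#' trigger reference, the 20% gait-cycle onset window, the 5 cm/s / 50 ms
#' handrail-grab detector, the 5% marker-completeness bound, the 20 N /
#' 15%-of-cycle belt-separation rule, and exclusion of the first two
#' perturbations per side per block.
#'
#' @param marker_cutoff low-pass cutoff for marker series (Hz).
#' @param force_cutoff low-pass cutoff for force series (Hz).
#' @param filter_order Butterworth design order.
#' @param median_window median-filter window length (samples).
#' @param max_gap_frames longest marker gap filled by spline interpolation
#'   (frames).
#' @param belt_dev_threshold belt-speed departure that flags a perturbation
#'   (m/s above the steady speed).
#' @param onset_max_fraction latest admissible perturbation onset as a
#'   fraction of the gait cycle.
#' @param grab_speed_threshold finger-marker speed below which a handrail
#'   grab is suspected (m/s).
#' @param grab_min_duration minimum sub-threshold duration that counts as a
#'   grab (s).
#' @param max_missing_fraction largest tolerated fraction of missing marker
#'   samples in a recovery window.
#' @param completeness_per_marker apply the missing-data bound to each
#'   required marker (`TRUE`, stricter) or pooled across markers.
#' @param swing_force_threshold vertical force below which a plate is
#'   considered unloaded (N).
#' @param min_swing_fraction minimum fraction of each gait cycle a plate
#'   must stay unloaded for valid belt separation.
#' @param n_warmup perturbations per side per block discarded as warm-up.
#' @param load_onset_force rising force that marks stance loading onset when
#'   locating the first ||GRF|| peak (N).
#' @param peak_prominence_pct prominence floor for the first-peak search
#'   (%BW).
#' @param required_markers markers whose completeness gates the kinematic
#'   family.
#' @param trunk_projection use the sagittal-plane projection of the trunk
#'   axis instead of the 3-D angle.
#' @param posthoc_family number of comparisons in the Bonferroni family
#'   (one per step label).
#' @param sphericity_alpha Mauchly p-value below which the
#'   Greenhouse-Geisser correction is applied.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(marker_cutoff = 6,
                            force_cutoff = 10,
                            filter_order = 4,
                            median_window = 3,
                            max_gap_frames = 10,
                            belt_dev_threshold = 0.05,
                            onset_max_fraction = 0.20,
                            grab_speed_threshold = 0.05,
                            grab_min_duration = 0.050,
                            max_missing_fraction = 0.05,
                            completeness_per_marker = TRUE,
                            swing_force_threshold = 20,
                            min_swing_fraction = 0.15,
                            n_warmup = 2,
                            load_onset_force = 20,
                            peak_prominence_pct = 2,
                            required_markers = c("C7", "CLAV", "SACR", "LASI", "RASI"),
                            trunk_projection = FALSE,
                            posthoc_family = 4,
                            sphericity_alpha = 0.05) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}
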