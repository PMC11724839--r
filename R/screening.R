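#' Warm-up exclusion flags
#'
#' The first `n_warmup` perturbations to each side of every walking block
#' are excluded to remove initial learning effects.
#'
#' @param perts perturbation table with `block` and `side_ordinal`.
#' @param n_warmup perturbations per side per block to discard.
#' @return logical vector, `TRUE` where the perturbation is warm-up.
#' @export
exclude_warmup <- function(perts, n_warmup = 2) {
  perts$side_ordinal <= n_warmup
}

#' Onset-phase check
#'
#' A perturbation is admissible only if initiated within the first
#' `max_fraction` of the gait cycle (inclusive).  Undefined fractions fail.
#'
#' @param cycle_fraction onset gait-cycle fraction(s) in `[0, 1]` (NA
#'   allowed).
#' @param max_fraction latest admissible fraction.
#' @return logical vector.
#' @export
check_onset_phase <- function(cycle_fraction, max_fraction = 0.20) {
  !is.na(cycle_fraction) & cycle_fraction <= max_fraction
}

#' Detect handrail grabs from finger-marker speed
#'
#' A handrail grab is any maximal interval in which a finger marker's speed
#' stays below `speed_threshold` for at least `min_duration`; overlapping
#' intervals from the two hands are merged.
#'
#' @param markers named list of marker matrices including `LFIN`, `RFIN`.
#' @param rate marker sampling rate (Hz).
#' @param window optional `c(start, end)` (s) restricting the search (the
#'   analysis window runs from perturbation onset to the end of the third
#'   recovery step).
#' @param speed_threshold grab speed threshold (m/s).
#' @param min_duration minimum sub-threshold duration (s).
#' @return data frame of grab intervals with columns `start`, `end` (s).
#' @export
detect_handrail_grabs <- function(markers, rate, window = NULL,
                                  speed_threshold = 0.05,
                                  min_duration = 0.050) {
  if (is.null(markers$LFIN) || is.null(markers$RFIN))
    abort_stumblr("finger markers missing", "screening_failure")
  intervals <- list()
  for (fm in c("LFIN", "RFIN")) {
    xyz <- markers[[fm]]
    n <- nrow(xyz)
    vel <- matrix(0, n, 3)
    vel[2:(n - 1), ] <- (xyz[3:n, ] - xyz[1:(n - 2), ]) * rate / 2
    vel[1, ] <- (xyz[2, ] - xyz[1, ]) * rate
    vel[n, ] <- (xyz[n, ] - xyz[n - 1, ]) * rate
    speed <- sqrt(rowSums(vel^2))
    slow <- speed < speed_threshold
    slow[is.na(slow)] <- FALSE
    if (!is.null(window)) {
      t <- (seq_len(n) - 1) / rate
      slow <- slow & t >= window[1] & t <= window[2]
    }
    if (!any(slow)) next
    runs <- logical_runs(slow)
    dur <- (runs[, "end"] - runs[, "start"] + 1L) / rate
    runs <- runs[dur >= min_duration, , drop = FALSE]
    if (nrow(runs))
      intervals[[fm]] <- data.frame(start = (runs[, "start"] - 1) / rate,
                                    end = (runs[, "end"] - 1) / rate)
  }
  if (!length(intervals))
    return(data.frame(start = numeric(), end = numeric()))
  iv <- do.call(rbind, intervals)
  iv <- iv[order(iv$start), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= merged$end[nrow(merged)]) {
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], iv$end[i])
    } else merged <- rbind(merged, iv[i, ])
  }
  rownames(merged) <- NULL
  merged
}

#' Marker-completeness check over a window
#'
#' Passes when the fraction of missing samples (pre-interpolation mask)
#' within the window is at most `max_missing` — per required marker by
#' default (stricter), or pooled across the required markers.
#'
#' @param valid_masks named list of logical validity vectors
#'   (pre-interpolation).
#' @param rate marker sampling rate (Hz).
#' @param window `c(start, end)` in seconds.
#' @param required markers that must be complete.
#' @param max_missing largest tolerated missing fraction.
#' @param per_marker apply the bound per marker (`TRUE`) or pooled.
#' @return `TRUE` when the window passes.
#' @export
check_marker_completeness <- function(valid_masks, rate, window,
                                      required = names(valid_masks),
                                      max_missing = 0.05,
                                      per_marker = TRUE) {
  n <- length(valid_masks[[required[1]]])
  idx <- window_indices(window[1], window[2], rate, n)
  if (!length(idx)) return(FALSE)
  miss <- vapply(required,
                 function(mk) mean(!valid_masks[[mk]][idx]), numeric(1))
  if (per_marker) all(miss <= max_missing) else mean(miss) <= max_missing
}

#' Belt-separation check over the gait cycles of a step window
#'
#' Force measurements are trustworthy only if the participant never crossed
#' the treadmill mid-line: each plate's vertical GRF must stay below
#' `swing_threshold` (a plate registering the leg in swing) for at least
#' `min_swing_fraction` of every gait cycle in the window.
#'
#' @param fz_left,fz_right vertical force series of the two plates (N).
#' @param rate force sampling rate (Hz).
#' @param cycles data frame of gait cycles with `start`, `end` (s).
#' @param swing_threshold unloaded-plate force bound (N).
#' @param min_swing_fraction minimum unloaded fraction of each cycle.
#' @return `TRUE` when every cycle passes on both plates; `FALSE` (with
#'   attribute `reason`) otherwise.
#' @export
check_belt_separation <- function(fz_left, fz_right, rate, cycles,
                                  swing_threshold = 20,
                                  min_swing_fraction = 0.15) {
  if (!nrow(cycles))
    return(structure(FALSE, reason = "window shorter than one gait cycle"))
  for (i in seq_len(nrow(cycles))) {
    idx <- window_indices(cycles$start[i], cycles$end[i], rate,
                          length(fz_left))
    if (!length(idx))
      return(structure(FALSE, reason = "window shorter than one gait cycle"))
    for (fz in list(fz_left, fz_right)) {
      if (mean(fz[idx] < swing_threshold) < min_swing_fraction)
        return(structure(FALSE, reason = "plate loaded through the cycle"))
    }
  }
  TRUE
}

#' Screen every perturbation of a trial
#'
#' Applies the five exclusion rules per perturbation: warm-up, onset phase,
#' handrail grab (finger speed < 5 cm/s for >= 50 ms between onset and the
#' end of the third recovery step), marker completeness of the kinematic
#' window, and belt separation of the kinetic window.  A perturbation
#' enters the kinematic analysis iff it is not warm-up, its onset phase is
#' admissible, no grab occurred and its markers are complete; the kinetic
#' analysis additionally requires belt separation instead of completeness.
#'
#' @param perts perturbation table from [detect_perturbations()].
#' @param trial a preprocessed `trial_recording`.
#' @param events event table from [detect_gait_events()].
#' @param cfg a [pipeline_config()].
#' @return data frame (`screening_report`): one row per perturbation with
#'   all flags, inclusion decisions and a reason string.
#' @export
screen_perturbations <- function(perts, trial, events, cfg = pipeline_config()) {
  n <- nrow(perts)
  warm <- exclude_warmup(perts, cfg$n_warmup)
  onset_ok <- check_onset_phase(perts$cycle_fraction, cfg$onset_max_fraction)
  grab <- logical(n); kin_complete <- logical(n); kinetic_sep <- logical(n)
  reasons <- character(n)
  raw_masks <- trial$marker_valid_raw %||% trial$marker_valid
  for (i in seq_len(n)) {
    seg <- try(segment_recovery_steps(perts[i, ], events), silent = TRUE)
    if (inherits(seg, "try-error")) {
      grab[i] <- FALSE; kin_complete[i] <- FALSE; kinetic_sep[i] <- FALSE
      reasons[i] <- "truncated recovery"
      next
    }
    window <- c(perts$onset[i], seg$end[4])
    grabs <- detect_handrail_grabs(trial$markers, trial$marker_rate,
                                   window = window,
                                   speed_threshold = cfg$grab_speed_threshold,
                                   min_duration = cfg$grab_min_duration)
    grab[i] <- nrow(grabs) > 0
    kin_complete[i] <- check_marker_completeness(
      raw_masks, trial$marker_rate, c(seg$start[1], seg$end[4]),
      required = cfg$required_markers, max_missing = cfg$max_missing_fraction,
      per_marker = cfg$completeness_per_marker)
    side <- perts$side[i]
    strikes <- event_times(events, side, "heel_strike")
    cyc_b <- strikes[strikes >= seg$start[1] - 1e-9 & strikes <= seg$end[4] + 1e-9]
    cycles <- if (length(cyc_b) >= 2)
      data.frame(start = head(cyc_b, -1), end = tail(cyc_b, -1))
    else data.frame(start = numeric(), end = numeric())
    kinetic_sep[i] <- isTRUE(check_belt_separation(
      trial$forces$left[, 3], trial$forces$right[, 3], trial$force_rate,
      cycles, cfg$swing_force_threshold, cfg$min_swing_fraction))
    rs <- c(if (warm[i]) "warmup", if (!onset_ok[i]) "late onset",
            if (grab[i]) "handrail grab", if (!kin_complete[i]) "markers missing",
            if (!kinetic_sep[i]) "midline crossing")
    reasons[i] <- paste(rs, collapse = "; ")
  }
  out <- cbind(perts[, c("id", "side", "side_label", "onset",
                         "cycle_fraction", "block", "side_ordinal")],
               data.frame(warmup_excluded = warm, onset_phase_ok = onset_ok,
                          handrail_grab = grab,
                          kinematic_complete = kin_complete,
                          kinetic_separated = kinetic_sep,
                          include_kinematic = !warm & onset_ok & !grab & kin_complete,
                          include_kinetic = !warm & onset_ok & !grab & kinetic_sep,
                          reason = reasons))
  class(out) <- c("screening_report", class(out))
  out
}
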