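#' Trunk angle relative to the global vertical axis
#'
#' The trunk axis runs from the pelvis origin (centroid of SACR, LASI,
#' RASI) to the midpoint of the C7 and CLAV markers.  The angle is the 3-D
#' angle between that axis and global +Z, signed positive when the
#' sagittal-plane projection tilts anteriorly (flexion) and negative in
#' extension; alternatively the pure sagittal-plane projection angle can be
#' requested.
#'
#' @param markers named list of n x 3 matrices with `C7`, `CLAV`, `SACR`,
#'   `LASI`, `RASI` (gap-filled).
#' @param projection if `TRUE` return the sagittal (X-Z) projection angle
#'   instead of the signed 3-D angle.
#' @return trunk angle series in degrees.
#' @export
trunk_angle_series <- function(markers, projection = FALSE) {
  origin <- (markers$SACR + markers$LASI + markers$RASI) / 3
  mid <- (markers$C7 + markers$CLAV) / 2
  v <- mid - origin
  len <- sqrt(rowSums(v^2))
  if (any(len < 1e-9, na.rm = TRUE))
    abort_stumblr("degenerate (zero-length) trunk axis", "invalid_geometry")
  if (projection) {
    atan2(v[, 1], v[, 3]) * 180 / pi
  } else {
    ang <- acos(pmin(1, pmax(-1, v[, 3] / len))) * 180 / pi
    ang * ifelse(v[, 1] >= 0, 1, -1)
  }
}

#' Trunk angular velocity by central differences
#'
#' Time derivative of the trunk angle: central differences at interior
#' samples, one-sided differences at the endpoints.
#'
#' @param angle_series trunk angle (deg).
#' @param rate sampling rate (Hz).
#' @return angular velocity series (deg/s).
#' @export
trunk_angular_velocity_series <- function(angle_series, rate) {
  n <- length(angle_series)
  if (n < 2)
    abort_stumblr("angular velocity needs at least two samples", "invalid_input")
  v <- numeric(n)
  v[2:(n - 1)] <- (angle_series[3:n] - angle_series[1:(n - 2)]) * rate / 2
  v[1] <- (angle_series[2] - angle_series[1]) * rate
  v[n] <- (angle_series[n] - angle_series[n - 1]) * rate
  v
}

#' Trunk angular sway over a step
#'
#' Range (max minus min) of the trunk angle over the step interval
#' `[start, end)`.
#'
#' @param angle_series trunk angle (deg).
#' @param rate sampling rate (Hz).
#' @param segment a step segment (list or one-row data frame with `start`,
#'   `end` in s).
#' @return sway in degrees.
#' @export
step_trunk_sway <- function(angle_series, rate, segment) {
  idx <- window_indices(segment$start, segment$end, rate, length(angle_series))
  if (!length(idx))
    abort_stumblr("step segment covers no samples", "invalid_segment")
  max(angle_series[idx]) - min(angle_series[idx])
}

#' Peak trunk flexion angular velocity over a step
#'
#' Maximum angular velocity in the flexion (positive) direction within the
#' step.  When the trunk never rotates into flexion the least-negative
#' velocity is returned with `flagged = TRUE`.
#'
#' @param velocity_series angular velocity (deg/s).
#' @param rate sampling rate (Hz).
#' @param segment a step segment with `start` and `end` (s).
#' @return list with `value` (deg/s) and `flagged`.
#' @export
step_peak_flexion_velocity <- function(velocity_series, rate, segment) {
  idx <- window_indices(segment$start, segment$end, rate,
                        length(velocity_series))
  if (!length(idx))
    abort_stumblr("step segment covers no samples", "invalid_segment")
  m <- max(velocity_series[idx])
  list(value = m, flagged = m <= 0)
}

#' Euclidean magnitude of a 3-D force series
#'
#' @param forces n x 3 force matrix (N).
#' @return per-sample `||GRF||` (N).
#' @export
grf_magnitude_series <- function(forces) {
  sqrt(rowSums(forces^2))
}

#' First peak of the normalized ||GRF|| over a step
#'
#' The peak `||GRF||` of a step is the value at the first local maximum of
#' the stance plate's normalized force magnitude after loading onset (the
#' magnitude rising through `load_threshold_pct`), requiring a prominence
#' of at least `min_prominence_pct`.  When the window holds no interior
#' maximum (e.g. a plateau), the window maximum is returned flagged.
#'
#' @param grf_pct_bw normalized `||GRF||` series of the stance plate (%BW).
#' @param rate sampling rate (Hz).
#' @param segment step segment with `start`, `end` (s).
#' @param load_threshold_pct loading-onset gate (%BW); the 20 N reference
#'   converted by the caller.
#' @param min_prominence_pct prominence floor for peak candidates (%BW).
#' @return list with `value` (%BW) and `flagged`.
#' @export
step_peak_grf <- function(grf_pct_bw, rate, segment, load_threshold_pct,
                          min_prominence_pct = 2) {
  idx <- window_indices(segment$start, segment$end, rate, length(grf_pct_bw))
  if (!length(idx))
    abort_stumblr("step segment covers no samples", "invalid_segment")
  w <- grf_pct_bw[idx]
  if (all(w < load_threshold_pct))
    abort_stumblr("stance plate never loaded within the step", "missing_stance")
  if (w[1] >= load_threshold_pct) {
    onset <- 1L
  } else {
    cross <- which(w[-1] >= load_threshold_pct & w[-length(w)] < load_threshold_pct)
    onset <- cross[1] + 1L
  }
  sub <- w[onset:length(w)]
  peaks <- local_maxima(sub, min_prominence_pct)
  if (length(peaks)) {
    list(value = sub[peaks[1]], flagged = FALSE)
  } else {
    list(value = max(sub), flagged = TRUE)
  }
}
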