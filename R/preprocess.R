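#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order (by default) low-pass Butterworth applied forward and
#' backward, so the net response is zero-phase with squared magnitude; the
#' series is reflection-padded before filtering to suppress end
#' transients.  At the cutoff the two-pass amplitude response is 1/2.
#'
#' @param x numeric series.
#' @param cutoff cutoff frequency (Hz); must be below the Nyquist rate.
#' @param rate sampling rate (Hz).
#' @param order filter design order.
#' @return filtered series, same length as `x`.
#' @export
lowpass_butterworth <- function(x, cutoff, rate, order = 4) {
  if (cutoff <= 0 || cutoff >= rate / 2)
    abort_stumblr("cutoff must lie in (0, rate/2)", "invalid_parameter")
  n <- length(x)
  if (n < 2) return(x)
  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  np <- min(n - 1, 10L * ceiling(rate / cutoff))
  front <- 2 * x[1] - x[(np + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(front, x, back))
  y[(np + 1):(np + n)]
}

#' Window-3 median filter with edge replication
#'
#' Replaces each interior sample by the median of its 3-sample window;
#' endpoints are handled by edge replication (equivalently, kept).
#' Removes single-sample impulse noise while leaving monotone runs
#' untouched.
#'
#' @param x numeric series of length >= 3.
#' @return filtered series.
#' @export
median_filter3 <- function(x) {
  if (length(x) < 3)
    abort_stumblr("median filter needs at least 3 samples", "invalid_input")
  as.numeric(runmed(x, 3, endrule = "keep"))
}

#' Fill short marker gaps by cubic-spline interpolation
#'
#' Invalid runs no longer than `max_gap` frames, flanked by valid samples
#' on both sides, are replaced coordinate-wise by a cubic spline fitted to
#' the nearest valid neighbours and marked filled.  Longer runs and runs
#' touching a series boundary are left invalid (no extrapolation).
#'
#' @param xyz n x 3 coordinate matrix (m).
#' @param valid logical validity mask of length n.
#' @param max_gap longest gap filled (frames).
#' @param n_support valid samples used on each side of a gap.
#' @return list with the filled `xyz`, updated `valid` mask and a logical
#'   `filled` vector marking interpolated samples.
#' @export
fill_marker_gaps <- function(xyz, valid, max_gap = 10, n_support = 6) {
  stopifnot(nrow(xyz) == length(valid))
  filled <- rep(FALSE, length(valid))
  if (all(valid)) return(list(xyz = xyz, valid = valid, filled = filled))
  runs <- logical_runs(!valid)
  for (r in seq_len(nrow(runs))) {
    i1 <- runs[r, "start"]; i2 <- runs[r, "end"]
    len <- i2 - i1 + 1L
    if (len > max_gap) next
    if (i1 == 1L || i2 == length(valid)) next
    left <- which(valid[seq_len(i1 - 1L)])
    right <- which(valid[(i2 + 1L):length(valid)]) + i2
    if (!length(left) || !length(right)) next
    sup <- c(tail(left, n_support), head(right, n_support))
    for (j in 1:3) {
      f <- splinefun(sup, xyz[sup, j], method = "fmm")
      xyz[i1:i2, j] <- f(i1:i2)
    }
    valid[i1:i2] <- TRUE
    filled[i1:i2] <- TRUE
  }
  list(xyz = xyz, valid = valid, filled = filled)
}

#' Body weight from a static trial
#'
#' Body weight is the time-average magnitude of the vector sum of the
#' forces on the two plates while the participant stands still.
#'
#' @param static a `static_trial` (or any list with `forces$left`,
#'   `forces$right` force matrices in N).
#' @return object of class `body_weight`: list with `value` (N) and
#'   `source_duration` (s).
#' @export
body_weight_from_static <- function(static) {
  fl <- static$forces$left; fr <- static$forces$right
  if (is.null(fl) || is.null(fr) || nrow(fl) == 0)
    abort_stumblr("static trial has no force samples", "invalid_input")
  total <- fl + fr
  value <- mean(sqrt(rowSums(total^2)))
  if (value <= 0)
    abort_stumblr("static trial implies non-positive body weight", "invalid_input")
  structure(list(value = value,
                 source_duration = nrow(fl) / (static$rate %||% NA_real_)),
            class = "body_weight")
}

#' Normalize a force series to percent body weight
#'
#' @param force_series numeric series (N); magnitudes or single components.
#' @param bw a `body_weight` (or positive scalar in N).
#' @return series in %BW (100 * value / body weight).
#' @export
normalize_to_bw <- function(force_series, bw) {
  value <- if (inherits(bw, "body_weight")) bw$value else bw
  if (!is.numeric(value) || value <= 0)
    abort_stumblr("body weight must be positive", "invalid_parameter")
  100 * force_series / value
}

#' Preprocess a trial exactly as the analysis prescribes
#'
#' Marker gaps are spline-filled (short gaps only), then marker coordinates
#' are low-pass filtered at 6 Hz and force components at 10 Hz with
#' fourth-order zero-phase Butterworth filters, followed by a window-3
#' median filter on both.  The pre-interpolation validity mask is kept for
#' the completeness screen; samples that remain invalid are bridged by
#' linear interpolation so filtering stays well-defined, but stay flagged
#' invalid.
#'
#' @param trial a `trial_recording`.
#' @param cfg a [pipeline_config()].
#' @return the trial with filtered `markers` and `forces`, the original
#'   mask in `marker_valid_raw`, and the post-fill mask in `marker_valid`.
#' @export
preprocess_trial <- function(trial, cfg = pipeline_config()) {
  trial$marker_valid_raw <- trial$marker_valid
  for (mk in names(trial$markers)) {
    res <- fill_marker_gaps(trial$markers[[mk]], trial$marker_valid[[mk]],
                            max_gap = cfg$max_gap_frames)
    xyz <- res$xyz
    for (j in 1:3) {
      col <- xyz[, j]
      if (anyNA(col)) {
        ok <- which(!is.na(col))
        if (length(ok) >= 2)
          col <- approx(ok, col[ok], xout = seq_along(col), rule = 2)$y
        else col[is.na(col)] <- 0
      }
      col <- lowpass_butterworth(col, cfg$marker_cutoff, trial$marker_rate,
                                 cfg$filter_order)
      xyz[, j] <- median_filter3(col)
    }
    trial$markers[[mk]] <- xyz
    trial$marker_valid[[mk]] <- res$valid
  }
  for (side in names(trial$forces)) {
    f <- trial$forces[[side]]
    for (j in 1:3)
      f[, j] <- median_filter3(lowpass_butterworth(f[, j], cfg$force_cutoff,
                                                   trial$force_rate,
                                                   cfg$filter_order))
    trial$forces[[side]] <- f
  }
  trial$preprocessed <- TRUE
  trial
}
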