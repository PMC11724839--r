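#' Construct an insole frame
#'
#' The force-sensing insole carries eight discrete force-sensing resistors
#' assigned to three plantar regions: heel (sensors 1-2), midfoot (sensor
#' 3) and metatarsal (sensors 4-8).
#'
#' @param fsr_values numeric vector of exactly 8 sensor readings.
#' @param timestamp frame time (s).
#' @return list of class `insole_frame`.
#' @export
insole_frame <- function(fsr_values, timestamp = 0) {
  if (length(fsr_values) != 8)
    abort_stumblr("an insole frame has exactly 8 FSR values", "invalid_frame")
  structure(list(fsr_values = as.numeric(fsr_values), timestamp = timestamp,
                 regions = list(heel = 1:2, midfoot = 3, metatarsal = 4:8)),
            class = "insole_frame")
}

#' Per-region insole pressures
#'
#' The pressure attributed to each region is the arithmetic mean of the
#' readings from the sensor pads within that region.
#'
#' @param frame an [insole_frame()].
#' @return named numeric vector `c(heel, midfoot, metatarsal)`.
#' @export
region_pressures <- function(frame) {
  if (!inherits(frame, "insole_frame"))
    abort_stumblr("not an insole frame", "invalid_frame")
  vapply(frame$regions, function(i) mean(frame$fsr_values[i]), numeric(1))
}

#' Per-region stimulation calibration
#'
#' Maps region pressure to a pulse-width command: zero below the sensation
#' threshold pressure, linear between threshold and saturation, clamped
#' above.  Pulse amplitude is fixed per region within the 0.8-2 mA range;
#' pulse widths stay within 0-255 us and the inter-pulse interval is fixed
#' at 50 ms.
#'
#' @param threshold_pressure pressure at which stimulation starts.
#' @param saturation_pressure pressure at which the width saturates.
#' @param width_at_threshold,width_at_saturation pulse widths (us) at the
#'   two calibration points.
#' @param amplitude fixed pulse amplitude (mA).
#' @return list of class `stim_calibration`.
#' @export
stim_calibration <- function(threshold_pressure, saturation_pressure,
                             width_at_threshold = 50,
                             width_at_saturation = 255,
                             amplitude = 1.0) {
  if (threshold_pressure >= saturation_pressure)
    abort_stumblr("threshold pressure must be below saturation pressure",
                  "invalid_config")
  if (width_at_threshold < 0 || width_at_saturation > 255 ||
      width_at_threshold > width_at_saturation)
    abort_stumblr("pulse widths must lie in [0, 255] and be non-decreasing",
                  "invalid_config")
  if (amplitude < 0.8 || amplitude > 2)
    abort_stumblr("pulse amplitude must lie in [0.8, 2] mA", "invalid_config")
  structure(list(threshold_pressure = threshold_pressure,
                 saturation_pressure = saturation_pressure,
                 width_at_threshold = width_at_threshold,
                 width_at_saturation = width_at_saturation,
                 amplitude = amplitude),
            class = "stim_calibration")
}

#' Map a region pressure to a stimulation command entry
#'
#' @param region_value region pressure.
#' @param calibration a [stim_calibration()].
#' @return list with `pulse_amplitude` (mA), `pulse_width` (us, 0 when the
#'   pressure is below threshold) and `inter_pulse_interval` (ms, fixed 50).
#' @export
pressure_to_stimulation <- function(region_value, calibration) {
  cal <- calibration
  width <- if (region_value < cal$threshold_pressure) {
    0
  } else {
    frac <- (region_value - cal$threshold_pressure) /
      (cal$saturation_pressure - cal$threshold_pressure)
    frac <- min(1, frac)
    cal$width_at_threshold +
      frac * (cal$width_at_saturation - cal$width_at_threshold)
  }
  list(pulse_amplitude = if (width > 0) cal$amplitude else 0,
       pulse_width = width,
       inter_pulse_interval = 50)
}

#' Closed-loop stimulation command stream from insole frames
#'
#' Commands are issued on a fixed 50 ms clock regardless of the insole
#' frame rate: each command latches the most recent frame at or before its
#' tick and maps every region's pressure through its calibration.
#'
#' @param frames data frame with a `time` column and 8 sensor columns
#'   (`fsr1` ... `fsr8`).
#' @param calibrations named list of [stim_calibration()]s for `heel`,
#'   `midfoot`, `metatarsal`.
#' @param period command period (s); 50 ms matches the fixed inter-pulse
#'   interval.
#' @return data frame with one row per command tick and per region:
#'   `time`, `region`, `pressure`, `pulse_amplitude`, `pulse_width`.
#' @export
snp_command_stream <- function(frames, calibrations, period = 0.05) {
  stopifnot(all(c("heel", "midfoot", "metatarsal") %in% names(calibrations)))
  sensor_cols <- paste0("fsr", 1:8)
  ticks <- seq(min(frames$time), max(frames$time), by = period)
  out <- list()
  for (ti in seq_along(ticks)) {
    i <- max(which(frames$time <= ticks[ti]))
    fr <- insole_frame(as.numeric(frames[i, sensor_cols]), frames$time[i])
    pr <- region_pressures(fr)
    for (rg in names(pr)) {
      cmd <- pressure_to_stimulation(pr[[rg]], calibrations[[rg]])
      out[[length(out) + 1]] <- data.frame(
        time = ticks[ti], region = rg, pressure = pr[[rg]],
        pulse_amplitude = cmd$pulse_amplitude, pulse_width = cmd$pulse_width)
    }
  }
  do.call(rbind, out)
}
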