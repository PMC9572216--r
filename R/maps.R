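# Per-frame calibrated channel values used by the map builders.

#' Calibrated per-channel forces of one frame
#'
#' @param trial An [insole_trial()].
#' @param frame_idx 1-based frame index.
#' @param cfg A [divider_config()].
#' @param fsr An [fsr_force_model()].
#' @return Numeric vector of 16 per-channel forces in N.
#' @export
frame_forces <- function(trial, frame_idx, cfg = divider_config(),
                         fsr = default_fsr_model()) {
  stopifnot(inherits(trial, "insole_trial"),
            frame_idx >= 1, frame_idx <= nrow(trial$frames))
  counts <- as.numeric(trial$frames[frame_idx, sprintf("p%02d", 1:16)])
  f <- numeric(16)
  loaded <- counts > 0
  if (any(loaded)) {
    v <- adc_to_voltage(counts[loaded], cfg)
    f[loaded] <- force_from_resistance(resistance_from_voltage(v, cfg), fsr)
  }
  f
}

#' Calibrated per-channel temperatures of one frame
#'
#' @inheritParams frame_forces
#' @param thermo A [thermistor_model()].
#' @return Numeric vector of 8 per-channel temperatures in degC (`NA` for a
#'   channel reading 0 or full scale, where the conversion is undefined).
#' @export
frame_temperatures <- function(trial, frame_idx, cfg = divider_config(),
                               thermo = thermistor_model()) {
  stopifnot(inherits(trial, "insole_trial"),
            frame_idx >= 1, frame_idx <= nrow(trial$frames))
  counts <- as.numeric(trial$frames[frame_idx, sprintf("t%02d", 1:8)])
  out <- rep(NA_real_, 8)
  ok <- counts > 0 & counts < cfg$adc_max
  if (any(ok))
    out[ok] <- temperature_from_adc(counts[ok], cfg, thermo, warn_range = FALSE)
  out
}

# Canonical stance-phase sampling points (fractions of the gait cycle).
default_gait_phases <- function() {
  c("heel strike" = 0.00, "foot-flat" = 0.15, "midstance" = 0.30,
    "heel-off" = 0.45, "toe-off" = 0.60, "mid-swing" = 0.80)
}

#' Plantar pressure maps at selected phases of one gait cycle
#'
#' For each requested phase (a fraction of the cycle, 0 = heel strike of
#' this cycle), takes the nearest frame inside the cycle, converts the 16
#' pressure channels to force and interpolates them over the foot template.
#' The default phase set walks through heel strike, foot-flat, midstance,
#' heel-off, toe-off and mid-swing.
#'
#' @param trial An [insole_trial()].
#' @param cycle One row of a [segment_cycles()] table (list or 1-row data
#'   frame with `start`, `end`).
#' @param phases Named or unnamed numeric vector of cycle fractions in
#'   `[0, 1]`.
#' @param layout A [sensor_layout()].
#' @param template A [foot_template()].
#' @param cfg A [divider_config()].
#' @param fsr An [fsr_force_model()].
#' @param method Interpolation method, see [interpolate_map()].
#' @return Named list of `plantar_map` objects, one per phase.
#' @export
phase_pressure_maps <- function(trial, cycle, phases = default_gait_phases(),
                                layout = default_sensor_layout(),
                                template = build_template(layout),
                                cfg = divider_config(),
                                fsr = default_fsr_model(),
                                method = "linear") {
  stopifnot(inherits(trial, "insole_trial"))
  if (any(phases < 0 | phases > 1))
    stop("phases must be fractions of the gait cycle in [0, 1]")
  start <- cycle$start; end <- cycle$end
  if (is.null(start) || is.null(end) || end <= start ||
      end > nrow(trial$frames) + 1L)
    stop("cycle boundaries do not lie within the trial")
  if (is.null(names(phases)))
    names(phases) <- sprintf("phase %.2f", phases)
  maps <- lapply(seq_along(phases), function(i) {
    idx <- start + round(phases[i] * (end - start))
    idx <- min(idx, end - 1L)
    interpolate_map(frame_forces(trial, idx, cfg, fsr), layout, template,
                    kind = "pressure", method = method,
                    phase = names(phases)[i])
  })
  stats::setNames(maps, names(phases))
}

#' Standing plantar temperature map
#'
#' Time-averages each temperature channel over the first `window_s` seconds
#' of a standing trial (calibrated through the thermistor divider) and
#' interpolates the 8 site means over the foot template.
#'
#' @param trial An [insole_trial()] (standing).
#' @param layout A [sensor_layout()].
#' @param template A [foot_template()].
#' @param cfg A [divider_config()].
#' @param thermo A [thermistor_model()].
#' @param window_s Averaging window in s (default 10; must not exceed the
#'   trial duration).
#' @param method Interpolation method, see [interpolate_map()].
#' @return A `plantar_map` in degC.
#' @export
standing_temperature_map <- function(trial, layout = default_sensor_layout(),
                                     template = build_template(layout),
                                     cfg = divider_config(),
                                     thermo = thermistor_model(),
                                     window_s = 10, method = "linear") {
  stopifnot(inherits(trial, "insole_trial"), window_s > 0)
  dur <- nrow(trial$frames) / trial$sampling_rate
  if (window_s > dur + 1e-9)
    stop(sprintf("averaging window (%g s) exceeds the trial duration (%g s)",
                 window_s, dur))
  idx <- which(trial$frames$timestamp < trial$frames$timestamp[1] + window_s)
  counts <- as.matrix(trial$frames[idx, sprintf("t%02d", 1:8)])
  temps <- matrix(NA_real_, nrow(counts), 8)
  ok <- counts > 0 & counts < cfg$adc_max
  temps[ok] <- temperature_from_adc(counts[ok], cfg, thermo, warn_range = FALSE)
  site_mean <- colMeans(temps, na.rm = TRUE)
  if (anyNA(site_mean)) stop("a temperature channel has no valid reading")
  interpolate_map(site_mean, layout, template, kind = "temperature",
                  method = method)
}
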