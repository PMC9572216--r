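#' Voltage-divider channel configuration
#'
#' Describes one pull-up voltage-divider channel read by an ADC: an unknown
#' sensor resistance to ground, a known external pull-up resistor `r_ext` to
#' the supply `vcc`, and a linear ADC of `adc_bits` bits sampling the divider
#' midpoint. The defaults correspond to a 5 V supply, a 10 kOhm pull-up and a
#' 12-bit converter (counts 0--4095).
#'
#' @param vcc Supply voltage in volts. Must be positive.
#' @param r_ext External pull-up resistance in ohms. Must be positive.
#' @param adc_bits ADC resolution in bits (positive integer).
#' @return An object of class `divider_config` with fields `vcc`, `r_ext`,
#'   `adc_bits` and the derived `adc_max = 2^adc_bits - 1`.
#' @examples
#' cfg <- divider_config()
#' cfg$adc_max  # 4095
#' @export
divider_config <- function(vcc = 5, r_ext = 10000, adc_bits = 12) {
  stopifnot(is.numeric(vcc), length(vcc) == 1, is.finite(vcc),
            is.numeric(r_ext), length(r_ext) == 1, is.finite(r_ext),
            is.numeric(adc_bits), length(adc_bits) == 1)
  if (vcc <= 0) stop("`vcc` must be positive (got ", vcc, " V)")
  if (r_ext <= 0) stop("`r_ext` must be positive (got ", r_ext, " Ohm)")
  if (adc_bits < 1 || adc_bits != round(adc_bits))
    stop("`adc_bits` must be a positive integer")
  structure(
    list(vcc = vcc, r_ext = r_ext, adc_bits = as.integer(adc_bits),
         adc_max = 2^adc_bits - 1),
    class = "divider_config"
  )
}

#' @export
print.divider_config <- function(x, ...) {
  cat(sprintf("<divider_config> Vcc = %g V, Rext = %g Ohm, %d-bit ADC (0..%d)\n",
              x$vcc, x$r_ext, x$adc_bits, x$adc_max))
  invisible(x)
}

#' Exponential NTC thermistor calibration model
#'
#' Resistance--temperature model `R(T) = a * exp(b * T)` for an NTC
#' thermistor. `a` is the resistance at 0 degC and `b` the (negative)
#' exponential rate per degC. The defaults are the calibration of a 10 kOhm
#' NTC bead fitted over its 20--50 degC working range: a = 24710 Ohm,
#' b = -0.036 /degC, which places 10 kOhm near room temperature (25 degC).
#'
#' @param a Resistance at 0 degC in ohms (positive).
#' @param b Exponential rate in 1/degC (negative for an NTC).
#' @return Object of class `thermistor_model` with fields `a` and `b`.
#' @seealso [temperature_from_resistance()], [fit_exponential_calibration()]
#' @export
thermistor_model <- function(a = 24710, b = -0.036) {
  stopifnot(is.numeric(a), length(a) == 1, is.numeric(b), length(b) == 1)
  if (a <= 0) stop("`a` must be positive (resistance at 0 degC)")
  if (b >= 0) stop("`b` must be negative for an NTC thermistor")
  structure(list(a = a, b = b), class = "thermistor_model")
}

#' @export
print.thermistor_model <- function(x, ...) {
  cat(sprintf("<thermistor_model> R(T) = %g * exp(%g * T) Ohm\n", x$a, x$b))
  invisible(x)
}

#' Thermistor resistance at a given temperature
#'
#' Forward model `R(T) = a * exp(b*T)`; the exact inverse of
#' [temperature_from_resistance()].
#'
#' @param temp_c Temperature(s) in degC.
#' @param model A [thermistor_model()].
#' @return Resistance(s) in ohms.
#' @export
thermistor_resistance_at <- function(temp_c, model = thermistor_model()) {
  stopifnot(inherits(model, "thermistor_model"), is.numeric(temp_c))
  model$a * exp(model$b * temp_c)
}

# Working range of the thermistor calibration; readings outside it are
# extrapolations of the fitted curve and only warned about, never rejected.
.temp_working_range <- c(20, 50)

#' Convert ADC counts to divider output voltage
#'
#' Linear mapping of ADC counts onto the supply span: count 0 reads 0 V and
#' the full-scale count reads `vcc`. Counts may be non-integer reals so that
#' analytic operating points are expressible; quantization belongs to the
#' acquisition (or simulation) stage, not to calibration.
#'
#' @param adc_count ADC count(s), real, in `[0, adc_max]`.
#' @param cfg A [divider_config()].
#' @param channel Optional channel label used in error messages.
#' @return Voltage(s) in volts.
#' @examples
#' adc_to_voltage(4095, divider_config())  # 5 V
#' @export
adc_to_voltage <- function(adc_count, cfg = divider_config(), channel = NULL) {
  stopifnot(inherits(cfg, "divider_config"), is.numeric(adc_count))
  bad <- which(!is.finite(adc_count) | adc_count < 0 | adc_count > cfg$adc_max)
  if (length(bad)) {
    where <- if (is.null(channel)) paste0("position ", bad[1]) else
      paste0("channel ", channel, ", position ", bad[1])
    stop(sprintf("ADC count %s out of range [0, %d] (%s)",
                 format(adc_count[bad[1]]), cfg$adc_max, where))
  }
  cfg$vcc * adc_count / cfg$adc_max
}

#' Sensor resistance from the divider output voltage
#'
#' Inverts the pull-up divider `Vout = Vcc * Rext / (Rext + R)` to
#' `R = Rext * (Vcc - Vout) / Vout`. A midpoint voltage of 0 means the sensor
#' branch is open (infinite resistance) and is rejected with a condition of
#' class `insole_open_circuit`; a voltage above `vcc` is physically invalid.
#'
#' @param vout Divider output voltage(s) in volts, in `(0, vcc]`.
#' @param cfg A [divider_config()].
#' @return Resistance(s) in ohms; `vout = vcc` gives 0 Ohm.
#' @examples
#' resistance_from_voltage(2.5, divider_config())  # 10000 Ohm
#' @export
resistance_from_voltage <- function(vout, cfg = divider_config()) {
  stopifnot(inherits(cfg, "divider_config"), is.numeric(vout))
  if (any(!is.finite(vout))) stop("non-finite voltage")
  if (any(vout <= 0)) {
    stop(structure(
      class = c("insole_open_circuit", "error", "condition"),
      list(message = "Vout <= 0: open circuit (infinite resistance)",
           call = sys.call(-1))))
  }
  if (any(vout > cfg$vcc))
    stop(sprintf("Vout = %g V above supply %g V: invalid reading",
                 max(vout), cfg$vcc))
  cfg$r_ext * (cfg$vcc - vout) / vout
}

#' Thermistor resistance directly from an ADC count
#'
#' One-step form of the divider inversion in counts,
#' `R = r_ext * (adc_max - A) / A`, algebraically identical to
#' [adc_to_voltage()] followed by [resistance_from_voltage()] for any
#' divider configuration. With the default 5 V / 10 kOhm / 12-bit
#' configuration this is `R = (40950000 - 10000*A) / A`.
#'
#' @inheritParams adc_to_voltage
#' @return Resistance(s) in ohms.
#' @examples
#' thermistor_resistance_from_adc(819)   # 40000 Ohm
#' thermistor_resistance_from_adc(4095)  # 0 Ohm (full scale)
#' @export
thermistor_resistance_from_adc <- function(adc_count, cfg = divider_config()) {
  stopifnot(inherits(cfg, "divider_config"), is.numeric(adc_count))
  if (any(!is.finite(adc_count) | adc_count > cfg$adc_max | adc_count < 0))
    stop(sprintf("ADC count out of range [0, %d]", cfg$adc_max))
  if (any(adc_count == 0)) {
    stop(structure(
      class = c("insole_open_circuit", "error", "condition"),
      list(message = "ADC count 0: open circuit (infinite resistance)",
           call = sys.call(-1))))
  }
  cfg$r_ext * (cfg$adc_max - adc_count) / adc_count
}

#' Temperature from thermistor resistance
#'
#' Inverts the exponential calibration `R = a * exp(b*T)` to
#' `T = (ln R - ln a) / b`. Readings outside the 20--50 degC working range of
#' the calibration are returned but flagged with a warning, since the fitted
#' curve is extrapolated there.
#'
#' @param r Resistance(s) in ohms, positive.
#' @param model A [thermistor_model()].
#' @param warn_range Warn when the result leaves the working range
#'   (default TRUE).
#' @return Temperature(s) in degC.
#' @examples
#' temperature_from_resistance(24710)  # ~0 degC
#' temperature_from_resistance(10000)  # ~25.1 degC
#' @export
temperature_from_resistance <- function(r, model = thermistor_model(),
                                        warn_range = TRUE) {
  stopifnot(inherits(model, "thermistor_model"), is.numeric(r))
  if (any(!is.finite(r) | r <= 0))
    stop("resistance must be positive and finite")
  temp <- (log(r) - log(model$a)) / model$b
  if (warn_range && any(temp < .temp_working_range[1] | temp > .temp_working_range[2]))
    warning(sprintf("temperature outside the %g-%g degC working range; calibration extrapolated",
                    .temp_working_range[1], .temp_working_range[2]))
  temp
}

#' Temperature directly from an ADC count (closed form)
#'
#' Closed-form composition of the divider inversion and the exponential
#' calibration: `T = (ln(r_ext*(adc_max - A)/A) - ln a) / b`. Must agree with
#' [thermistor_resistance_from_adc()] followed by
#' [temperature_from_resistance()] to floating precision for every valid
#' count. Counts of 0 (open circuit) or full scale (0 Ohm, log undefined) are
#' rejected.
#'
#' @inheritParams adc_to_voltage
#' @param model A [thermistor_model()].
#' @param warn_range Warn outside the working range (default TRUE).
#' @return Temperature(s) in degC.
#' @export
temperature_from_adc <- function(adc_count, cfg = divider_config(),
                                 model = thermistor_model(), warn_range = TRUE) {
  stopifnot(inherits(cfg, "divider_config"), inherits(model, "thermistor_model"),
            is.numeric(adc_count))
  if (any(!is.finite(adc_count) | adc_count <= 0 | adc_count >= cfg$adc_max))
    stop(sprintf("ADC count must lie strictly inside (0, %d): 0 is an open circuit, full scale a short",
                 cfg$adc_max))
  temp <- (log(cfg$r_ext * (cfg$adc_max - adc_count) / adc_count) - log(model$a)) /
    model$b
  if (warn_range && any(temp < .temp_working_range[1] | temp > .temp_working_range[2]))
    warning(sprintf("temperature outside the %g-%g degC working range; calibration extrapolated",
                    .temp_working_range[1], .temp_working_range[2]))
  temp
}

#' Fit an exponential thermistor calibration curve
#'
#' Least-squares fit of `R = a * exp(b*T)` by ordinary regression of
#' `log(R)` on `T`. Returns the fitted [thermistor_model()] together with the
#' coefficient of determination on the log-resistance scale.
#'
#' @param temperature Temperatures in degC (length >= 2, not all equal).
#' @param resistance Matching resistances in ohms (all positive).
#' @return A list of class `thermistor_fit` with elements `model`
#'   (a [thermistor_model()]), `r_squared` (R^2 of the log-linear fit) and
#'   `n` (number of points).
#' @examples
#' t <- seq(20, 50, by = 5)
#' fit <- fit_exponential_calibration(t, 24710 * exp(-0.036 * t))
#' fit$model$b       # -0.036
#' fit$r_squared     # 1
#' @export
fit_exponential_calibration <- function(temperature, resistance) {
  stopifnot(is.numeric(temperature), is.numeric(resistance),
            length(temperature) == length(resistance))
  if (length(temperature) < 2)
    stop("at least two calibration points are required")
  if (any(!is.finite(resistance) | resistance <= 0))
    stop("all resistances must be positive")
  if (length(unique(temperature)) < 2)
    stop("calibration temperatures must not all coincide")
  fit <- stats::lm(log(resistance) ~ temperature)
  co <- stats::coef(fit)
  a <- exp(unname(co[1]))
  b <- unname(co[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((log(resistance) - mean(log(resistance)))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  if (b >= 0)
    warning("fitted rate b is non-negative; the data do not look like an NTC")
  model <- structure(list(a = a, b = b), class = "thermistor_model")
  structure(list(model = model, r_squared = r2, n = length(temperature)),
            class = "thermistor_fit")
}

#' @export
print.thermistor_fit <- function(x, ...) {
  cat(sprintf("<thermistor_fit> a = %.6g Ohm, b = %.6g /degC, R^2(log R) = %.4f, n = %d\n",
              x$model$a, x$model$b, x$r_squared, x$n))
  invisible(x)
}

#' Active sensing area of a circular force sensor
#'
#' `pi * r^2` for a circular active region. The FSR-402 sensor used on the
#' insole has a radius of 6.35 mm, giving about 126.68 mm^2.
#'
#' @param radius_mm Radius in millimetres (non-negative).
#' @return Area in mm^2.
#' @examples
#' active_area(6.35)  # 126.68 mm^2
#' @export
active_area <- function(radius_mm = 6.35) {
  stopifnot(is.numeric(radius_mm))
  if (any(radius_mm < 0)) stop("radius must be non-negative")
  pi * radius_mm^2
}

#' Force on a sensor from plantar pressure
#'
#' Converts a pressure in pascal acting on an active area in mm^2 to a force
#' in newton (1 Pa = 1 N/m^2, so force = pressure * area * 1e-6).
#'
#' @param pressure_pa Pressure(s) in Pa, non-negative.
#' @param area_mm2 Active area(s) in mm^2, non-negative.
#' @return Force in N.
#' @examples
#' force_from_pressure(80000, 126.677)   # ~10 N
#' force_from_pressure(600000, 126.677)  # ~76 N
#' @export
force_from_pressure <- function(pressure_pa, area_mm2 = active_area()) {
  stopifnot(is.numeric(pressure_pa), is.numeric(area_mm2))
  if (any(pressure_pa < 0)) stop("pressure must be non-negative")
  if (any(area_mm2 < 0)) stop("area must be non-negative")
  pressure_pa * area_mm2 * 1e-6
}

#' Equivalent mass of a force
#'
#' `m = F / g` under the nominal gravitational acceleration.
#'
#' @param force_n Force(s) in N, non-negative.
#' @param g Gravitational acceleration in m/s^2 (default 9.81).
#' @return Mass in kg.
#' @export
mass_from_force <- function(force_n, g = 9.81) {
  stopifnot(is.numeric(force_n), is.numeric(g), length(g) == 1)
  if (g <= 0) stop("g must be positive")
  if (any(force_n < 0)) stop("force must be non-negative")
  force_n / g
}
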