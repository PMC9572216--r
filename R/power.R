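#' Battery power budget
#'
#' Battery-life arithmetic for the wearable: capacity and nominal cell
#' voltage give the stored energy, the measured average consumption gives
#' the continuous runtime, and the daily wear time gives the days between
#' charges. Defaults describe a 1300 mAh, 3.7 V Li-ion/LiPo cell feeding a
#' circuit that draws about 0.4 Wh per hour, worn half an hour a day.
#'
#' @param capacity_mah Battery capacity in mAh.
#' @param nominal_voltage Cell voltage in V.
#' @param consumption_wh_per_h Average energy draw in Wh per hour of use.
#' @param daily_use_h Wear time in hours per day.
#' @return Object of class `power_budget`.
#' @examples
#' b <- power_budget()
#' energy_wh(b)    # 4.81 Wh
#' runtime_h(b)    # ~12 h
#' days_of_use(b)  # ~24 days
#' @export
power_budget <- function(capacity_mah = 1300, nominal_voltage = 3.7,
                         consumption_wh_per_h = 0.4, daily_use_h = 0.5) {
  vals <- c(capacity_mah, nominal_voltage, consumption_wh_per_h, daily_use_h)
  if (any(!is.finite(vals) | vals <= 0))
    stop("all power-budget fields must be positive")
  structure(list(capacity_mah = capacity_mah,
                 nominal_voltage = nominal_voltage,
                 consumption_wh_per_h = consumption_wh_per_h,
                 daily_use_h = daily_use_h),
            class = "power_budget")
}

#' Stored battery energy
#' @param budget A [power_budget()].
#' @return Energy in Wh (`capacity_mah * nominal_voltage / 1000`).
#' @export
energy_wh <- function(budget = power_budget()) {
  stopifnot(inherits(budget, "power_budget"))
  budget$capacity_mah * budget$nominal_voltage / 1000
}

#' Continuous runtime on one charge
#' @param budget A [power_budget()].
#' @return Runtime in hours (`energy_wh / consumption_wh_per_h`).
#' @export
runtime_h <- function(budget = power_budget()) {
  stopifnot(inherits(budget, "power_budget"))
  energy_wh(budget) / budget$consumption_wh_per_h
}

#' Days of use between charges
#' @param budget A [power_budget()].
#' @return Days (`runtime_h / daily_use_h`).
#' @export
days_of_use <- function(budget = power_budget()) {
  stopifnot(inherits(budget, "power_budget"))
  runtime_h(budget) / budget$daily_use_h
}

#' @export
print.power_budget <- function(x, ...) {
  cat(sprintf(
    "<power_budget> %g mAh @ %g V = %.2f Wh; %.1f h runtime; %.1f days at %g h/day\n",
    x$capacity_mah, x$nominal_voltage, energy_wh(x), runtime_h(x),
    days_of_use(x), x$daily_use_h))
  invisible(x)
}
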