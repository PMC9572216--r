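#' Force-sensitive resistor (FSR) force--resistance model
#'
#' An FSR's resistance is effectively infinite with no load and falls
#' nonlinearly as normal force increases. Vendor data sheets publish the
#' curve as a log-log plot, so the model is an anchor table of
#' (resistance, force) pairs with log-log linear interpolation between
#' anchors. Resistances above the largest anchor are treated as unloaded
#' (0 N); below the smallest anchor the last log-log segment is extrapolated.
#'
#' The table must be strictly monotone: resistance strictly decreasing as
#' force increases. The default table passes through the FSR-402 operating
#' point of 10 kOhm under 100 g (0.981 N at g = 9.81 m/s^2).
#'
#' @param resistance Anchor resistances in ohms (>= 2 values, positive).
#' @param force Matching anchor forces in newton (non-negative, at most one
#'   zero is not allowed on the log scale, so all anchors must carry load).
#' @return Object of class `fsr_force_model`.
#' @seealso [force_from_resistance()], [resistance_from_force()]
#' @export
fsr_force_model <- function(resistance, force) {
  stopifnot(is.numeric(resistance), is.numeric(force),
            length(resistance) == length(force))
  if (length(resistance) < 2) stop("at least two anchor points are required")
  if (any(resistance <= 0)) stop("anchor resistances must be positive")
  if (any(force <= 0)) stop("anchor forces must be positive (log-log model)")
  ord <- order(resistance)
  r <- resistance[ord]
  f <- force[ord]
  if (any(diff(r) <= 0) || any(diff(f) >= 0))
    stop("anchors must be strictly monotone: resistance decreasing as force increases")
  structure(list(log_r = log(r), log_f = log(f), resistance = r, force = f),
            class = "fsr_force_model")
}

#' Default FSR-402 style anchor table
#'
#' A data-sheet-shaped curve with roughly inverse force--resistance
#' behaviour, anchored exactly at the published 10 kOhm / 100 g
#' (0.981 N) operating point and spanning 10 g to 10 kg.
#'
#' @return An [fsr_force_model()].
#' @export
default_fsr_model <- function() {
  fsr_force_model(
    resistance = c(200e3, 50e3, 10e3, 2e3, 500, 150),
    force      = c(0.0490, 0.196, 0.981, 4.905, 19.62, 65.0)
  )
}

#' @export
print.fsr_force_model <- function(x, ...) {
  cat(sprintf("<fsr_force_model> %d anchors, %s Ohm -> %s N (log-log linear)\n",
              length(x$resistance),
              paste(range(x$resistance), collapse = ".."),
              paste(signif(range(x$force), 3), collapse = "..")))
  invisible(x)
}

#' Force from FSR resistance
#'
#' Log-log linear interpolation through the model's anchor table. Exact at
#' every anchor, monotone non-increasing in resistance. Resistances above the
#' largest anchor (including `Inf`, the unloaded sensor) map to 0 N: the
#' sensor has a dead band below its lightest characterised load.
#'
#' @param r Resistance(s) in ohms, positive (`Inf` allowed).
#' @param model An [fsr_force_model()].
#' @return Force(s) in N.
#' @examples
#' force_from_resistance(10000)  # 0.981 N (100 g)
#' force_from_resistance(Inf)    # 0 N
#' @export
force_from_resistance <- function(r, model = default_fsr_model()) {
  stopifnot(inherits(model, "fsr_force_model"), is.numeric(r))
  if (any(is.na(r) | r <= 0)) stop("resistance must be positive")
  out <- numeric(length(r))
  loaded <- r <= max(model$resistance)
  if (any(loaded)) {
    lr <- log(r[loaded])
    # interpolate on descending force vs ascending log-resistance;
    # rule = 2 clamps at the high-force end, then overridden by explicit
    # extrapolation of the lowest-resistance segment
    n <- length(model$log_r)
    seg <- findInterval(lr, model$log_r, all.inside = TRUE)
    slope <- (model$log_f[seg + 1] - model$log_f[seg]) /
      (model$log_r[seg + 1] - model$log_r[seg])
    out[loaded] <- exp(model$log_f[seg] + slope * (lr - model$log_r[seg]))
  }
  out
}

#' FSR resistance that produces a given force
#'
#' Inverse of [force_from_resistance()] on the anchor table. Forces below the
#' lightest anchor (the sensor's dead band, including 0 N) return `Inf`: the
#' sensor looks unloaded. Forces above the heaviest anchor extrapolate the
#' last log-log segment.
#'
#' @param f Force(s) in N, non-negative.
#' @param model An [fsr_force_model()].
#' @return Resistance(s) in ohms (`Inf` when unloaded).
#' @export
resistance_from_force <- function(f, model = default_fsr_model()) {
  stopifnot(inherits(model, "fsr_force_model"), is.numeric(f))
  if (any(is.na(f) | f < 0)) stop("force must be non-negative")
  out <- rep(Inf, length(f))
  loaded <- f >= min(model$force)
  if (any(loaded)) {
    lf <- log(f[loaded])
    lfa <- rev(model$log_f)   # ascending force
    lra <- rev(model$log_r)
    seg <- findInterval(lf, lfa, all.inside = TRUE)
    slope <- (lra[seg + 1] - lra[seg]) / (lfa[seg + 1] - lfa[seg])
    out[loaded] <- exp(lra[seg] + slope * (lf - lfa[seg]))
  }
  out
}

#' Divider output voltage for a given sensor resistance
#'
#' Forward pull-up divider `Vout = Vcc * Rext / (Rext + R)`; `R = Inf`
#' (open sensor) reads 0 V.
#'
#' @param r Resistance(s) in ohms, non-negative or `Inf`.
#' @param cfg A [divider_config()].
#' @return Voltage(s) in volts.
#' @export
voltage_from_resistance <- function(r, cfg = divider_config()) {
  stopifnot(inherits(cfg, "divider_config"), is.numeric(r))
  if (any(is.na(r) | r < 0)) stop("resistance must be non-negative")
  v <- cfg$vcc * cfg$r_ext / (cfg$r_ext + r)
  v[is.infinite(r)] <- 0
  v
}
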