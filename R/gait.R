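#' Total vertical ground reaction force of a trial
#'
#' Converts each of the 16 pressure channels through the calibration chain
#' ADC count -> divider voltage -> FSR resistance -> force, and sums across
#' channels per frame. A zero count is an open (unloaded) sensor and
#' contributes 0 N. Calibration failures are reported with the offending
#' channel id.
#'
#' @param trial An [insole_trial()].
#' @param cfg A [divider_config()].
#' @param fsr An [fsr_force_model()].
#' @return Numeric vGRF series in newton, one value per frame.
#' @export
total_vgrf <- function(trial, cfg = divider_config(),
                       fsr = default_fsr_model()) {
  stopifnot(inherits(trial, "insole_trial"))
  nf <- nrow(trial$frames)
  if (!nf) return(numeric(0))
  force <- matrix(0, nf, 16)
  for (j in 1:16) {
    ch <- sprintf("p%02d", j)
    counts <- trial$frames[[ch]]
    loaded <- counts > 0
    if (any(loaded)) {
      f <- tryCatch({
        v <- adc_to_voltage(counts[loaded], cfg, channel = ch)
        force_from_resistance(resistance_from_voltage(v, cfg), fsr)
      }, error = function(e)
        stop(sprintf("calibration failed on channel %s: %s", ch,
                     conditionMessage(e))))
      force[loaded, j] <- f
    }
  }
  rowSums(force)
}

#' Segment gait cycles from a vGRF series
#'
#' A gait cycle runs from one heel strike to the next. A heel strike is an
#' upward crossing of `threshold_fraction` times the trial's maximum force,
#' preceded by at least one below-threshold (swing) sample. Leading and
#' trailing partial cycles are discarded, so a series with fewer than two
#' detected heel strikes (standing, or a single loaded burst) yields no
#' cycles. The threshold is relative, making segmentation invariant to a
#' uniform rescaling of the force.
#'
#' @param force vGRF series in N.
#' @param rate Sampling rate in Hz.
#' @param threshold_fraction Heel-strike threshold as a fraction of the
#'   trial maximum (default 0.05).
#' @return Data frame with one row per complete cycle: `start`, `end`
#'   (1-based frame indices, half-open `[start, end)`) and `duration_s`.
#'   Zero rows when no complete cycle exists.
#' @export
segment_cycles <- function(force, rate = 40, threshold_fraction = 0.05) {
  stopifnot(is.numeric(force), rate > 0, threshold_fraction > 0)
  empty <- data.frame(start = integer(0), end = integer(0),
                      duration_s = numeric(0))
  if (length(force) < 2 || max(force) <= 0) return(empty)
  thr <- threshold_fraction * max(force)
  above <- force >= thr
  # upward crossings with at least one swing sample before them
  hs <- which(above[-1] & !above[-length(above)]) + 1L
  if (length(hs) < 2) return(empty)
  data.frame(start = hs[-length(hs)], end = hs[-1],
             duration_s = (hs[-1] - hs[-length(hs)]) / rate)
}

#' Resample one cycle's force curve to a fixed length
#'
#' Linear interpolation of the segment onto `n_points` uniformly spaced
#' positions spanning it; the first and last samples are preserved exactly.
#'
#' @param segment Force values of one cycle (length >= 2).
#' @param n_points Output length (default 512).
#' @return Numeric vector of length `n_points`.
#' @export
resample_cycle <- function(segment, n_points = 512) {
  stopifnot(is.numeric(segment), n_points >= 2)
  if (length(segment) < 2) stop("cannot resample a segment shorter than 2 samples")
  stats::approx(seq(0, 1, length.out = length(segment)), segment,
                xout = seq(0, 1, length.out = n_points))$y
}

#' Extract and resample all complete cycles of a trial's vGRF
#'
#' Convenience wrapper: [segment_cycles()] then [resample_cycle()] on each
#' `[start, end)` span.
#'
#' @inheritParams segment_cycles
#' @param n_points Resampled cycle length (default 512).
#' @return Matrix with one row per cycle and `n_points` columns (0 rows when
#'   no cycle is found), with the cycle table as attribute `"cycles"`.
#' @export
extract_cycles <- function(force, rate = 40, threshold_fraction = 0.05,
                           n_points = 512) {
  cyc <- segment_cycles(force, rate, threshold_fraction)
  m <- matrix(numeric(0), 0, n_points)
  if (nrow(cyc)) {
    m <- t(vapply(seq_len(nrow(cyc)), function(i) {
      resample_cycle(force[cyc$start[i]:(cyc$end[i] - 1L)], n_points)
    }, numeric(n_points)))
  }
  attr(m, "cycles") <- cyc
  m
}

#' Pointwise ensemble mean and standard deviation of resampled cycles
#'
#' Computes the across-cycle mean and population standard deviation at each
#' of the resampled positions — the curve-and-band summary used to display
#' the gait ensemble.
#'
#' @param curves Matrix with one resampled cycle per row (equal lengths), or
#'   a list of equal-length numeric vectors.
#' @return Object of class `ensemble_curve`: list with `mean`, `std`
#'   (length-n vectors) and `n_cycles`.
#' @export
ensemble_stats <- function(curves) {
  if (is.list(curves)) {
    len <- unique(lengths(curves))
    if (length(len) != 1) stop("all cycles must have the same length")
    curves <- do.call(rbind, curves)
  }
  stopifnot(is.matrix(curves))
  if (!nrow(curves)) stop("at least one cycle is required")
  mu <- colMeans(curves)
  std <- sqrt(colMeans(sweep(curves, 2, mu)^2))   # population SD
  structure(list(mean = mu, std = std, n_cycles = nrow(curves)),
            class = "ensemble_curve")
}

#' @export
print.ensemble_curve <- function(x, ...) {
  cat(sprintf("<ensemble_curve> %d cycles x %d points; peak mean %.1f N (sd %.1f N)\n",
              x$n_cycles, length(x$mean), max(x$mean), x$std[which.max(x$mean)]))
  invisible(x)
}

#' Plot an ensemble vGRF curve
#'
#' Mean curve with a plus/minus one standard deviation band over normalized
#' cycle time.
#'
#' @param x An `ensemble_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ensemble_curve <- function(x, ...) {
  n <- length(x$mean)
  tt <- seq(0, 100, length.out = n)
  graphics::plot(tt, x$mean, type = "n",
                 ylim = range(0, x$mean + x$std),
                 xlab = "gait cycle (%)", ylab = "vGRF (N)",
                 main = sprintf("Ensemble of %d gait cycles", x$n_cycles), ...)
  graphics::polygon(c(tt, rev(tt)), c(x$mean + x$std, rev(x$mean - x$std)),
                    col = "grey85", border = NA)
  graphics::lines(tt, x$mean, lty = 2)
  invisible(x)
}

#' Stance fraction of a resampled gait cycle
#'
#' Fraction of the cycle's points whose force exceeds `threshold_fraction`
#' times the cycle maximum — the loaded (stance) share of the stride,
#' typically around 60%.
#'
#' @param force_curve One resampled cycle (numeric).
#' @param threshold_fraction Relative threshold (default 0.05).
#' @return Stance fraction in `[0, 1]`.
#' @export
stance_fraction <- function(force_curve, threshold_fraction = 0.05) {
  stopifnot(is.numeric(force_curve), length(force_curve) >= 1)
  mx <- max(force_curve)
  if (mx <= 0) stop("stance fraction undefined for an unloaded cycle")
  mean(force_curve >= threshold_fraction * mx)
}
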