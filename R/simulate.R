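# Synthetic walking/standing trial generator. Stands in for the insole
# hardware: it produces the same 24-channel ADC frame streams the logger
# records, plus a ground-truth sidecar so downstream stages can be tested
# against what was actually generated.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required for reproducible simulation")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Subject anthropometrics
#'
#' Profile of one study participant. The cohort emulated by the simulator
#' spans ages 20--59 years, weights 52--125 kg, heights 153--185 cm and BMI
#' 18--36.5 kg/m^2. BMI is derived from weight and height; a supplied value
#' must agree within 5%.
#'
#' @param age Age in years.
#' @param weight Weight in kg.
#' @param height Height in cm.
#' @param sex `"F"` or `"M"`.
#' @param bmi Optional BMI in kg/m^2 (checked for consistency).
#' @return Object of class `subject_profile`.
#' @export
subject_profile <- function(age, weight, height, sex = "F", bmi = NULL) {
  stopifnot(age > 0, weight > 0, height > 0)
  sex <- match.arg(sex, c("F", "M"))
  derived <- weight / (height / 100)^2
  if (!is.null(bmi) && abs(bmi - derived) / derived > 0.05)
    stop(sprintf("supplied BMI %.1f inconsistent with weight/height (%.1f)",
                 bmi, derived))
  if (age < 20 || age > 59 || weight < 52 || weight > 125 ||
      height < 153 || height > 185 || derived < 18 || derived > 36.5)
    warning("subject outside the emulated cohort ranges (age 20-59, weight 52-125 kg, height 153-185 cm, BMI 18-36.5)")
  structure(list(age = age, weight = weight, height = height,
                 bmi = derived, sex = sex),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s, %g y, %g kg, %g cm (BMI %.1f)\n",
              x$sex, x$age, x$weight, x$height, x$bmi))
  invisible(x)
}

#' Sample subjects from the emulated cohort
#'
#' Draws anthropometrics uniformly within the cohort ranges: height and BMI
#' are sampled and weight derived, then clamped into 52--125 kg (BMI is
#' recomputed after clamping so the profile stays self-consistent).
#'
#' @param n Number of subjects (default 12, one walking cohort).
#' @param seed RNG seed.
#' @return List of [subject_profile()] objects.
#' @export
sample_subjects <- function(n = 12, seed) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      age <- round(stats::runif(1, 20, 59))
      height <- stats::runif(1, 153, 185)
      bmi <- stats::runif(1, 18.5, 32)
      weight <- min(max(bmi * (height / 100)^2, 52), 125)
      subject_profile(age = age, weight = weight, height = height,
                      sex = sample(c("F", "M"), 1))
    })
  })
}

#' Gait generation parameters
#'
#' Parameters of the synthetic walking model: stance occupies
#' `stance_fraction` of each gait cycle (default 0.60), cycle durations are
#' jittered around `cycle_duration_mean` with coefficient of variation
#' `cycle_duration_cv` (stride time is not constant across a trial), and
#' the push-off vGRF peak exceeds the loading peak by
#' `peak2_to_peak1_ratio`. Trials cover a straight `walkway_length` walk at
#' `speed`; `speed = NA` means self-selected, drawn uniformly from
#' 1.0--1.4 m/s per trial.
#'
#' @param stance_fraction Stance share of the cycle, in (0, 1).
#' @param cycle_duration_mean Mean gait-cycle duration in s.
#' @param cycle_duration_cv Coefficient of variation of cycle duration.
#' @param peak2_to_peak1_ratio Push-off to loading peak ratio (> 1).
#' @param walkway_length Walkway length in m.
#' @param speed Walking speed in m/s, or `NA` for self-selected.
#' @return Object of class `gait_params`.
#' @export
gait_params <- function(stance_fraction = 0.60, cycle_duration_mean = 1.05,
                        cycle_duration_cv = 0.05, peak2_to_peak1_ratio = 1.25,
                        walkway_length = 10, speed = NA) {
  stopifnot(stance_fraction > 0, stance_fraction < 1,
            cycle_duration_mean > 0, cycle_duration_cv >= 0,
            walkway_length > 0)
  if (peak2_to_peak1_ratio <= 1)
    stop("the push-off peak must exceed the loading peak (ratio > 1)")
  structure(list(stance_fraction = stance_fraction,
                 cycle_duration_mean = cycle_duration_mean,
                 cycle_duration_cv = cycle_duration_cv,
                 peak2_to_peak1_ratio = peak2_to_peak1_ratio,
                 walkway_length = walkway_length, speed = speed),
            class = "gait_params")
}

#' First-order sensor hysteresis (relaxation lag)
#'
#' Resistive polymer sensors take time to recover after the load changes:
#' the reading lags the instantaneous value with an exponential relaxation.
#' This applies the first-order lag `y_t = x_t + (y_{t-1} - x_t) *
#' exp(-dt/tau)` to a sampled series. `relaxation_time_s = 0` is the
#' identity; after a step release from F to 0 the output has decayed to
#' `F * exp(-1)` at `t = relaxation_time_s`.
#'
#' @param series Numeric series (force or resistance over time).
#' @param relaxation_time_s Relaxation time constant tau in s (>= 0).
#' @param rate Sampling rate in Hz.
#' @return The lagged series (same length).
#' @export
apply_hysteresis <- function(series, relaxation_time_s, rate = 40) {
  stopifnot(is.numeric(series), rate > 0)
  if (relaxation_time_s < 0) stop("relaxation time must be non-negative")
  if (relaxation_time_s == 0 || length(series) < 2) return(series)
  a <- exp(-1 / (rate * relaxation_time_s))
  as.numeric(stats::filter((1 - a) * series, a, method = "recursive",
                           init = series[1]))
}

# Two-peak stance vGRF template on normalized stance time s in [0, 1]:
# Gaussian loading peak at 25% and push-off peak at 75% of stance, a
# mid-stance valley between them, and a short linear toe-off taper so the
# force reaches zero at the stance/swing transition.
stance_template <- function(s, bw_n, ratio, peak_scale = 1.15, sigma = 0.13,
                            taper = 0.12) {
  p2 <- peak_scale * bw_n
  p1 <- p2 / ratio
  f <- p1 * exp(-((s - 0.25) / sigma)^2 / 2) +
    p2 * exp(-((s - 0.75) / sigma)^2 / 2)
  tail <- s > 1 - taper
  f[tail] <- f[tail] * (1 - s[tail]) / taper
  f[s < 0 | s > 1] <- 0
  f
}

# Phase-dependent anterior-posterior load sharing across the 16 pressure
# sites, grouped by normalized heel-toe coordinate u: heel sites dominate at
# heel strike and fade out linearly, midfoot sites carry a foot-flat bump
# around midstance, metatarsal sites ramp up with stance progress, toe sites
# engage only in the final 20% of stance (heel-off to toe-off).
site_weights <- function(s, u) {
  heel <- u < 0.30
  mid <- u >= 0.30 & u < 0.55
  meta <- u >= 0.55 & u <= 0.82
  toe <- u > 0.82
  w <- matrix(0, length(s), length(u))
  w[, heel] <- (1 - s)^2                  # heel lifts well before toe-off
  w[, mid] <- (4 * s * (1 - s))^2         # foot-flat bump around midstance
  w[, meta] <- s
  w[, toe] <- pmax(0, (s - 0.8) / 0.2)
  sw <- rowSums(w)
  sw[sw == 0] <- 1
  w / sw
}

# Shared back end: force/temperature series -> noisy quantized ADC frames.
series_to_trial <- function(time_s, site_force, site_temp, foot, rate,
                            subject, trial_id, cfg, fsr, thermo, noise_lsb) {
  r_p <- resistance_from_force(as.vector(site_force), fsr)
  v_p <- voltage_from_resistance(r_p, cfg)
  r_t <- thermistor_resistance_at(as.vector(site_temp), thermo)
  v_t <- voltage_from_resistance(r_t, cfg)
  quantize <- function(v) {
    lsb <- cfg$vcc / cfg$adc_max
    noisy <- v + stats::rnorm(length(v), sd = noise_lsb * lsb)
    matrix(pmin(pmax(round(noisy / lsb), 0), cfg$adc_max),
           nrow = length(time_s))
  }
  p_adc <- quantize(v_p)
  t_adc <- quantize(v_t)
  frames <- data.frame(timestamp = time_s, foot = foot,
                       stringsAsFactors = FALSE)
  frames[sprintf("p%02d", 1:16)] <- as.data.frame(p_adc)
  frames[sprintf("t%02d", 1:8)] <- as.data.frame(t_adc)
  insole_trial(frames, sampling_rate = rate, subject = subject,
               trial_id = trial_id, foot = foot)
}

#' Simulate one walking trial
#'
#' Generates a 40 Hz single-insole recording of one straight walkway pass:
#' a two-peak stance vGRF template scaled to the subject's weight (push-off
#' peak above the loading peak), zero force in swing, cycle durations
#' jittered so stride time varies through the trial; total force shared
#' across the 16 pressure sites by a phase-dependent heel-to-toe weighting;
#' per-site force passed through the FSR model, sensor hysteresis, the
#' voltage divider, additive voltage noise and 12-bit quantization.
#' Temperature channels hold per-site baselines with a slow linear drift,
#' converted through the thermistor divider the same way. The same seed
#' reproduces the trial bit for bit.
#'
#' The returned trial carries a `ground_truth` attribute (see
#' [write_ground_truth()]): per-frame template vGRF, sensed (post-hysteresis,
#' post-dead-band) vGRF, stance flags, true site temperatures and the true
#' heel-strike frame indices.
#'
#' @param subject A [subject_profile()].
#' @param gait A [gait_params()].
#' @param layout A one-foot [sensor_layout()].
#' @param cfg A [divider_config()].
#' @param fsr An [fsr_force_model()].
#' @param thermo A [thermistor_model()].
#' @param seed RNG seed (required).
#' @param rate Sampling rate in Hz (default 40).
#' @param relaxation_time_s FSR hysteresis relaxation time in s
#'   (default 0.02).
#' @param noise_lsb Additive Gaussian voltage noise, in ADC LSB units
#'   (default 2).
#' @param temp_baseline Optional 8 per-site baseline temperatures in degC
#'   (default drawn uniformly from 29--33).
#' @param temp_drift_c_per_s Linear skin-temperature drift in degC/s
#'   (default 0.005).
#' @param foot_length_mm Foot length used to normalize site positions
#'   (default 260).
#' @param trial_id Trial identifier.
#' @return An [insole_trial()] with a `ground_truth` attribute.
#' @export
simulate_walk <- function(subject, gait = gait_params(),
                          layout = default_sensor_layout(),
                          cfg = divider_config(), fsr = default_fsr_model(),
                          thermo = thermistor_model(), seed,
                          rate = 40, relaxation_time_s = 0.02, noise_lsb = 2,
                          temp_baseline = NULL, temp_drift_c_per_s = 0.005,
                          foot_length_mm = 260, trial_id = "walk") {
  stopifnot(inherits(subject, "subject_profile"), inherits(gait, "gait_params"),
            inherits(layout, "sensor_layout"))
  press <- layout_channels(layout, "pressure")
  if (nrow(press) != 16) stop("layout must declare 16 pressure channels")
  foot <- unique(layout$foot)
  if (length(foot) != 1) stop("layout must describe a single foot")
  with_seed(seed, {
    speed <- if (is.na(gait$speed)) stats::runif(1, 1.0, 1.4) else gait$speed
    duration <- gait$walkway_length / speed
    nf <- floor(duration * rate)
    time_s <- (seq_len(nf) - 1) / rate
    # heel-strike times: lead-in swing, then jittered cycle durations
    starts <- 0.25
    repeat {
      d <- gait$cycle_duration_mean *
        max(0.4, 1 + gait$cycle_duration_cv * stats::rnorm(1))
      starts <- c(starts, starts[length(starts)] + d)
      if (starts[length(starts)] > duration) break
    }
    durs <- diff(starts)
    k <- findInterval(time_s, starts)
    phase <- rep(1, nf)                      # before first heel strike: swing
    in_cycle <- k >= 1 & k <= length(durs)
    phase[in_cycle] <- (time_s[in_cycle] - starts[k[in_cycle]]) / durs[k[in_cycle]]
    stance <- in_cycle & phase < gait$stance_fraction
    s <- phase / gait$stance_fraction        # stance progress in [0, 1)
    bw_n <- subject$weight * 9.81
    f_tot <- numeric(nf)
    f_tot[stance] <- stance_template(s[stance], bw_n,
                                     gait$peak2_to_peak1_ratio)
    u <- press$y_mm / foot_length_mm
    w <- site_weights(pmin(s, 1), u)
    site_force <- w * f_tot
    site_force <- apply(site_force, 2, apply_hysteresis,
                        relaxation_time_s = relaxation_time_s, rate = rate)
    if (is.null(temp_baseline)) temp_baseline <- stats::runif(8, 29, 33)
    stopifnot(length(temp_baseline) == 8)
    site_temp <- outer(time_s * temp_drift_c_per_s, rep(1, 8)) +
      matrix(temp_baseline, nf, 8, byrow = TRUE)
    trial <- series_to_trial(time_s, site_force, site_temp, foot, rate,
                             subject, trial_id, cfg, fsr, thermo, noise_lsb)
    sensed <- site_force
    sensed[sensed < min(fsr$force)] <- 0     # sensor dead band
    hs <- ceiling(starts * rate) + 1
    hs <- hs[hs >= 1 & hs <= nf]
    gt <- data.frame(frame = seq_len(nf), time_s = time_s,
                     vgrf_template_n = f_tot, vgrf_sensed_n = rowSums(sensed),
                     stance = as.integer(stance))
    gt[sprintf("temp%02d_c", 1:8)] <- as.data.frame(site_temp)
    attr(trial, "ground_truth") <- list(per_frame = gt,
                                        heel_strikes = as.integer(hs),
                                        speed_mps = speed)
    trial
  })
}

#' Simulate a standing-still trial
#'
#' Static double-support standing on one instrumented insole: the subject's
#' weight share (`load_share`, default half the body weight per foot) is
#' split across the pressure sites with a fixed posture distribution (50%
#' heel, 10% midfoot, 33% metatarsal, 7% toes, even within each group) plus small
#' multiplicative postural-sway noise. No gait cycles are present.
#' Temperature channels behave as in [simulate_walk()]; supplying
#' `temp_baseline` lets a hot spot be placed at a chosen site.
#'
#' @inheritParams simulate_walk
#' @param duration_s Trial duration in s (default 30).
#' @param load_share Fraction of body weight on this foot (default 0.5).
#' @param sway_cv Coefficient of variation of the per-frame sway noise
#'   (default 0.02).
#' @return An [insole_trial()] with a `ground_truth` attribute.
#' @export
simulate_standing <- function(subject, layout = default_sensor_layout(),
                              cfg = divider_config(),
                              fsr = default_fsr_model(),
                              thermo = thermistor_model(), seed,
                              duration_s = 30, rate = 40, load_share = 0.5,
                              sway_cv = 0.02, noise_lsb = 2,
                              temp_baseline = NULL,
                              temp_drift_c_per_s = 0.005,
                              foot_length_mm = 260, trial_id = "stand") {
  stopifnot(inherits(subject, "subject_profile"),
            inherits(layout, "sensor_layout"), duration_s > 0)
  press <- layout_channels(layout, "pressure")
  foot <- unique(layout$foot)
  if (length(foot) != 1) stop("layout must describe a single foot")
  with_seed(seed, {
    nf <- floor(duration_s * rate)
    time_s <- (seq_len(nf) - 1) / rate
    u <- press$y_mm / foot_length_mm
    heel <- u < 0.30; mid <- u >= 0.30 & u < 0.55
    meta <- u >= 0.55 & u <= 0.82; toe <- u > 0.82
    w <- numeric(16)
    w[heel] <- 0.50 / sum(heel)
    w[mid] <- 0.10 / sum(mid)
    w[meta] <- 0.33 / sum(meta)
    w[toe] <- 0.07 / sum(toe)
    base_force <- subject$weight * 9.81 * load_share * w
    sway <- matrix(1 + sway_cv * stats::rnorm(nf * 16), nf, 16)
    site_force <- sway * matrix(base_force, nf, 16, byrow = TRUE)
    site_force[site_force < 0] <- 0
    if (is.null(temp_baseline)) temp_baseline <- stats::runif(8, 29, 33)
    stopifnot(length(temp_baseline) == 8)
    site_temp <- outer(time_s * temp_drift_c_per_s, rep(1, 8)) +
      matrix(temp_baseline, nf, 8, byrow = TRUE)
    trial <- series_to_trial(time_s, site_force, site_temp, foot, rate,
                             subject, trial_id, cfg, fsr, thermo, noise_lsb)
    sensed <- site_force
    sensed[sensed < min(fsr$force)] <- 0
    gt <- data.frame(frame = seq_len(nf), time_s = time_s,
                     vgrf_template_n = rowSums(site_force),
                     vgrf_sensed_n = rowSums(sensed),
                     stance = 1L)
    gt[sprintf("temp%02d_c", 1:8)] <- as.data.frame(site_temp)
    attr(trial, "ground_truth") <- list(per_frame = gt,
                                        heel_strikes = integer(0))
    trial
  })
}
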