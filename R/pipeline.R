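# End-to-end orchestration behind the command-line tool: cohort simulation
# into log files, and log files into cycle tables, ensemble curves and maps.

#' Read a run configuration file
#'
#' YAML configuration surfacing every tunable constant: divider electronics
#' (`vcc`, `r_ext`, `adc_bits`), thermistor coefficients (`a`, `b`), FSR
#' anchor table, layout file path, gait parameters and simulator settings.
#' Missing keys fall back to the package defaults.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return List of class `run_config` with elements `cfg`, `thermo`, `fsr`,
#'   `layout`, `gait` and `sim` (noise/hysteresis settings).
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  pick <- function(section, key, default) {
    v <- raw[[section]][[key]]
    if (is.null(v)) default else v
  }
  cfg <- divider_config(vcc = pick("divider", "vcc", 5),
                        r_ext = pick("divider", "r_ext", 10000),
                        adc_bits = pick("divider", "adc_bits", 12))
  thermo <- thermistor_model(a = pick("thermistor", "a", 24710),
                             b = pick("thermistor", "b", -0.036))
  fsr <- if (!is.null(raw$fsr)) {
    fsr_force_model(resistance = unlist(raw$fsr$resistance),
                    force = unlist(raw$fsr$force))
  } else default_fsr_model()
  layout <- if (!is.null(raw$layout_file)) read_sensor_layout(raw$layout_file)
    else read_sensor_layout()
  gait <- gait_params(
    stance_fraction = pick("gait", "stance_fraction", 0.60),
    cycle_duration_mean = pick("gait", "cycle_duration_mean", 1.05),
    cycle_duration_cv = pick("gait", "cycle_duration_cv", 0.05),
    peak2_to_peak1_ratio = pick("gait", "peak2_to_peak1_ratio", 1.25),
    walkway_length = pick("gait", "walkway_length", 10),
    speed = pick("gait", "speed", NA))
  sim <- list(noise_lsb = pick("sim", "noise_lsb", 2),
              relaxation_time_s = pick("sim", "relaxation_time_s", 0.02),
              rate = pick("sim", "rate", 40))
  structure(list(cfg = cfg, thermo = thermo, fsr = fsr, layout = layout,
                 gait = gait, sim = sim),
            class = "run_config")
}

#' Simulate a walking cohort into log files
#'
#' Samples a cohort, simulates `n_trials` walkway passes per subject and
#' writes one log file plus one ground-truth sidecar per subject-trial. The
#' defaults reproduce the reference protocol: 12 subjects, 6 trials each,
#' a 10 m walkway at self-selected speed, 40 Hz.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_subjects Number of subjects (default 12).
#' @param n_trials Trials per subject (default 6).
#' @param seed Master seed; per-trial seeds are derived deterministically.
#' @param config A [read_run_config()] result (defaults when `NULL`).
#' @return Data frame manifest: subject, trial, seed, log path, sidecar
#'   path.
#' @export
run_simulate <- function(out_dir, n_subjects = 12, n_trials = 6, seed = 1,
                         config = NULL) {
  if (is.null(config)) config <- read_run_config()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- sample_subjects(n_subjects, seed = seed)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    for (j in seq_len(n_trials)) {
      trial_seed <- (seed + 7919L * i + 104729L * j) %% .Machine$integer.max
      id <- sprintf("s%02d_t%02d", i, j)
      trial <- simulate_walk(subjects[[i]], gait = config$gait,
                             layout = config$layout, cfg = config$cfg,
                             fsr = config$fsr, thermo = config$thermo,
                             seed = trial_seed, rate = config$sim$rate,
                             relaxation_time_s = config$sim$relaxation_time_s,
                             noise_lsb = config$sim$noise_lsb,
                             trial_id = id)
      log_path <- file.path(out_dir, paste0("walk_", id, ".csv"))
      gt_path <- file.path(out_dir, paste0("walk_", id, "_truth.csv"))
      write_log(trial, log_path)
      write_ground_truth(trial, gt_path)
      rows[[length(rows) + 1]] <- data.frame(
        subject = i, trial = j, seed = trial_seed,
        log = log_path, truth = gt_path, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the analysis pipeline over a set of log files
#'
#' For every log: total vGRF, cycle segmentation, 512-point resampling and
#' per-cycle stance fractions. Cycles from all logs are pooled into one
#' ensemble curve. Logs without any complete gait cycle (standing captures)
#' get a standing temperature map; for walking logs, phase pressure maps are
#' produced from the first complete cycle of the first such log.
#'
#' @param log_paths Character vector of log file paths (non-empty).
#' @param config A [read_run_config()] result (defaults when `NULL`).
#' @param n_points Resampled cycle length (default 512).
#' @param threshold_fraction Heel-strike threshold (default 0.05).
#' @return List of class `pipeline_report`: `cycle_table` (per-cycle rows:
#'   trial_id, cycle, start, end, duration_s, stance_fraction), `ensemble`
#'   (an `ensemble_curve`, or `NULL` with no cycles), `phase_maps`,
#'   `temperature_maps`, `n_cycles_per_log`, `mean_stance_fraction`.
#' @export
run_pipeline <- function(log_paths, config = NULL, n_points = 512,
                         threshold_fraction = 0.05) {
  if (!length(log_paths)) stop("no input log files")
  if (is.null(config)) config <- read_run_config()
  cycle_rows <- list()
  curves <- list()
  n_per_log <- integer(length(log_paths))
  phase_maps <- NULL
  temperature_maps <- list()
  template <- build_template(config$layout)
  for (k in seq_along(log_paths)) {
    trial <- read_log(log_paths[k], cfg = config$cfg)
    force <- total_vgrf(trial, config$cfg, config$fsr)
    mat <- extract_cycles(force, trial$sampling_rate, threshold_fraction,
                          n_points)
    cyc <- attr(mat, "cycles")
    n_per_log[k] <- nrow(cyc)
    if (nrow(cyc)) {
      sf <- apply(mat, 1, stance_fraction, threshold_fraction)
      cycle_rows[[length(cycle_rows) + 1]] <- data.frame(
        trial_id = trial$trial_id, cycle = seq_len(nrow(cyc)),
        start = cyc$start, end = cyc$end, duration_s = cyc$duration_s,
        stance_fraction = sf, stringsAsFactors = FALSE)
      curves[[length(curves) + 1]] <- mat
      if (is.null(phase_maps)) {
        phase_maps <- phase_pressure_maps(trial, cyc[1, ],
                                          layout = config$layout,
                                          template = template,
                                          cfg = config$cfg, fsr = config$fsr)
      }
    } else {
      window <- min(10, nrow(trial$frames) / trial$sampling_rate)
      temperature_maps[[trial$trial_id]] <-
        standing_temperature_map(trial, layout = config$layout,
                                 template = template, cfg = config$cfg,
                                 thermo = config$thermo, window_s = window)
    }
  }
  cycle_table <- if (length(cycle_rows)) do.call(rbind, cycle_rows) else
    data.frame(trial_id = character(0), cycle = integer(0),
               start = integer(0), end = integer(0),
               duration_s = numeric(0), stance_fraction = numeric(0))
  ensemble <- if (length(curves)) ensemble_stats(do.call(rbind, curves)) else
    NULL
  structure(list(cycle_table = cycle_table, ensemble = ensemble,
                 phase_maps = phase_maps, temperature_maps = temperature_maps,
                 n_cycles_per_log = n_per_log,
                 mean_stance_fraction = if (nrow(cycle_table))
                   mean(cycle_table$stance_fraction) else NA_real_),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d logs, %d complete gait cycles\n",
              length(x$n_cycles_per_log), nrow(x$cycle_table)))
  if (nrow(x$cycle_table))
    cat(sprintf("  mean stance fraction: %.1f%%  mean cycle duration: %.2f s\n",
                100 * x$mean_stance_fraction, mean(x$cycle_table$duration_s)))
  if (length(x$temperature_maps))
    cat(sprintf("  standing temperature maps: %d\n", length(x$temperature_maps)))
  invisible(x)
}
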