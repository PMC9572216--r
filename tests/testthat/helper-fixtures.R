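# Shared fixtures, built in code at test time.

fixture_subject <- function(weight = 70) {
  subject_profile(age = 30, weight = weight, height = 170)
}

# One default walking trial, computed once and reused across tests.
.fixture_env <- new.env()
fixture_walk <- function() {
  if (is.null(.fixture_env$walk))
    .fixture_env$walk <- simulate_walk(fixture_subject(), seed = 42)
  .fixture_env$walk
}

# A tiny trial data frame with all counts at a fixed value.
constant_frames <- function(n, foot = "L", p = 0L, t = 2048L, rate = 40) {
  df <- data.frame(timestamp = (seq_len(n) - 1) / rate,
                   foot = rep(foot, n), stringsAsFactors = FALSE)
  df[sprintf("p%02d", 1:16)] <- rep(list(rep(as.integer(p), n)), 16)
  df[sprintf("t%02d", 1:8)] <- rep(list(rep(as.integer(t), n)), 8)
  df
}

random_frame <- function(cfg = divider_config()) {
  insole_frame(round(stats::runif(1, 0, 100), 3),
               sample(c("L", "R"), 1),
               sample(0:cfg$adc_max, 16, replace = TRUE),
               sample(0:cfg$adc_max, 8, replace = TRUE))
}
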