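test_that("the same seed reproduces a walking trial bit for bit", {
  s <- fixture_subject()
  t1 <- simulate_walk(s, seed = 99)
  t2 <- simulate_walk(s, seed = 99)
  expect_identical(t1$frames, t2$frames)
  expect_identical(attr(t1, "ground_truth"), attr(t2, "ground_truth"))
  t3 <- simulate_walk(s, seed = 100)
  expect_false(identical(t1$frames, t3$frames))
})

test_that("trial duration follows the walkway kinematics", {
  s <- fixture_subject()
  g <- gait_params(speed = 1.25)           # 10 m walkway -> 8 s
  tr <- simulate_walk(s, gait = g, seed = 5)
  dur <- n_frames(tr) / tr$sampling_rate
  expect_lt(abs(dur - 10 / 1.25), g$cycle_duration_mean)  # within one cycle
})

test_that("stance-phase vGRF scales linearly with subject weight", {
  g <- gait_params(speed = 1.2)
  t1 <- simulate_walk(fixture_subject(weight = 60), gait = g, seed = 21)
  t2 <- suppressWarnings(           # 120 kg at 170 cm is outside the cohort
    simulate_walk(fixture_subject(weight = 120), gait = g, seed = 21))
  gt1 <- attr(t1, "ground_truth")$per_frame
  gt2 <- attr(t2, "ground_truth")$per_frame
  m1 <- mean(gt1$vgrf_template_n[gt1$stance == 1])
  m2 <- mean(gt2$vgrf_template_n[gt2$stance == 1])
  expect_equal(m2 / m1, 2, tolerance = 1e-9)
})

test_that("ADC counts are integers within the converter range", {
  tr <- fixture_walk()
  counts <- as.matrix(tr$frames[, c(sprintf("p%02d", 1:16),
                                    sprintf("t%02d", 1:8))])
  expect_true(all(counts == round(counts)))
  expect_true(all(counts >= 0 & counts <= 4095))
})

test_that("decoded temperature channels recover the generated site temperatures", {
  tr <- simulate_walk(fixture_subject(), seed = 31,
                      temp_baseline = seq(28, 35, length.out = 8))
  gt <- attr(tr, "ground_truth")$per_frame
  nf <- n_frames(tr)
  decoded <- t(vapply(seq_len(nf), function(i) frame_temperatures(tr, i),
                      numeric(8)))
  truth <- as.matrix(gt[, sprintf("temp%02d_c", 1:8)])
  # time-averaged per-site recovery within quantization error
  expect_lt(max(abs(colMeans(decoded) - colMeans(truth))), 0.1)
})

test_that("standing trials are static and cycle-free", {
  st <- simulate_standing(fixture_subject(), seed = 8, duration_s = 8)
  f <- total_vgrf(st)
  expect_equal(nrow(segment_cycles(f)), 0)
  # per-site mean force constant over time within the sway noise
  gt <- attr(st, "ground_truth")$per_frame
  half <- seq_len(nrow(gt) %/% 2)
  m1 <- mean(gt$vgrf_sensed_n[half])
  m2 <- mean(gt$vgrf_sensed_n[-half])
  expect_lt(abs(m1 - m2) / m1, 0.02)
})

test_that("generated stance fraction matches the configured duty cycle", {
  sfs <- numeric(0)
  for (seed in 1:6) {
    tr <- simulate_walk(fixture_subject(), seed = seed)
    m <- extract_cycles(total_vgrf(tr))
    sfs <- c(sfs, apply(m, 1, stance_fraction))
  }
  expect_gte(length(sfs), 20)
  expect_lt(abs(mean(sfs) - 0.60), 0.02)
})

test_that("hysteresis is a first-order lag with the documented closed form", {
  expect_identical(apply_hysteresis(c(1, 5, 2), 0), c(1, 5, 2))
  # step release from F to 0: after t = tau the value is F/e
  rate <- 40; tau <- 0.1
  x <- c(rep(10, 20), rep(0, 20))
  y <- apply_hysteresis(x, tau, rate)
  expect_equal(y[20 + tau * rate], 10 * exp(-1), tolerance = 1e-9)
  # larger relaxation time -> larger loading/unloading loop area
  tri <- c(seq(0, 10, length.out = 40), seq(10, 0, length.out = 40))
  loop_area <- function(tau) {
    y <- apply_hysteresis(tri, tau, rate)
    up <- 1:40; down <- 80:41
    sum(abs(approx(tri[down], y[down], xout = tri[up])$y - y[up]))
  }
  expect_gt(loop_area(0.2), loop_area(0.05))
  expect_error(apply_hysteresis(1:5, -1), "non-negative")
})

test_that("sampled subjects stay inside the cohort ranges", {
  subs <- sample_subjects(12, seed = 2)
  expect_length(subs, 12)
  for (s in subs) {
    expect_true(s$age >= 20 && s$age <= 59)
    expect_true(s$weight >= 52 && s$weight <= 125)
    expect_true(s$height >= 153 && s$height <= 185)
    expect_true(s$bmi >= 18 && s$bmi <= 36.5)
    expect_lt(abs(s$bmi - s$weight / (s$height / 100)^2) / s$bmi, 0.05)
  }
  expect_error(subject_profile(30, 70, 170, bmi = 40), "inconsistent")
})
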