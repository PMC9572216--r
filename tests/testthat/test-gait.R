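test_that("total vGRF sums the calibrated pressure channels", {
  # all-zero counts: every FSR open, zero force
  tr0 <- insole_trial(constant_frames(5))
  expect_equal(total_vgrf(tr0), rep(0, 5))
  # one channel at the 10 kOhm operating point (midscale count), rest open
  df <- constant_frames(3)
  df$p05 <- round(4095 / 2)
  tr1 <- insole_trial(df)
  expect_equal(total_vgrf(tr1), rep(0.981, 3), tolerance = 1e-3)
})

test_that("total vGRF matches the simulator's ground truth", {
  tr <- fixture_walk()
  f <- total_vgrf(tr)
  truth <- attr(tr, "ground_truth")$per_frame$vgrf_sensed_n
  # quantization + 2-LSB voltage noise across 16 channels
  expect_lt(sqrt(mean((f - truth)^2)) / max(truth), 0.02)
  expect_equal(f[truth == 0], rep(0, sum(truth == 0)))  # swing stays zero
})

test_that("segmentation finds heel-strike boundaries of simulated walks", {
  for (seed in c(42, 7)) {
    tr <- simulate_walk(fixture_subject(), seed = seed)
    cyc <- segment_cycles(total_vgrf(tr), tr$sampling_rate)
    hs <- attr(tr, "ground_truth")$heel_strikes
    expect_equal(nrow(cyc), length(hs) - 1)
    expect_true(all(abs(cyc$start - hs[-length(hs)]) <= 2))
    expect_true(all(abs(cyc$end - hs[-1]) <= 2))
    # boundaries partition: ordered, non-overlapping, half-open
    expect_true(all(diff(cyc$start) > 0))
    expect_true(all(cyc$end[-nrow(cyc)] == cyc$start[-1]))
  }
})

test_that("segmentation handles degenerate series", {
  expect_equal(nrow(segment_cycles(rep(0, 100))), 0)           # never loaded
  expect_equal(nrow(segment_cycles(rep(500, 100))), 0)          # standing
  burst <- c(rep(0, 20), rep(500, 30), rep(0, 20))              # one burst
  expect_equal(nrow(segment_cycles(burst)), 0)
})

test_that("segmentation is invariant to uniform force rescaling", {
  tr <- fixture_walk()
  f <- total_vgrf(tr)
  expect_identical(segment_cycles(f), segment_cycles(17.3 * f))
})

test_that("cycle resampling is linear interpolation with preserved endpoints", {
  expect_equal(resample_cycle(rep(4, 10), 512), rep(4, 512))
  seg <- runif(512)
  expect_equal(resample_cycle(seg, 512), seg, tolerance = 1e-12)
  ramp <- seq(0, 1, length.out = 37)
  expect_equal(resample_cycle(ramp, 512), seq(0, 1, length.out = 512),
               tolerance = 1e-12)
  expect_equal(resample_cycle(c(3, 9), 5)[c(1, 5)], c(3, 9))
  expect_error(resample_cycle(5), "shorter")
})

test_that("ensemble statistics equal a brute-force oracle", {
  one <- matrix(runif(64), 1)
  e1 <- ensemble_stats(one)
  expect_equal(e1$mean, as.vector(one))
  expect_equal(e1$std, rep(0, 64))
  # symmetric pair: mean is the midline everywhere
  c1 <- runif(32)
  e2 <- ensemble_stats(rbind(c1, -c1 + 6))
  expect_equal(e2$mean, rep(3, 32))
  # random set vs an independent loop implementation
  set.seed(9)
  m <- matrix(rnorm(20 * 50), 20)
  e3 <- ensemble_stats(m)
  for (j in c(1, 17, 50)) {
    mu <- sum(m[, j]) / 20
    expect_equal(e3$mean[j], mu)
    expect_equal(e3$std[j], sqrt(sum((m[, j] - mu)^2) / 20))
  }
  expect_error(ensemble_stats(list(1:3, 1:4)), "same length")
})

test_that("stance fraction measures the loaded share of a cycle", {
  curve <- c(rep(100, 307), rep(0, 205))    # loaded for exactly 60% of 512
  expect_equal(stance_fraction(curve), 307 / 512)
  expect_equal(stance_fraction(rep(50, 512)), 1.0)
  expect_error(stance_fraction(rep(0, 512)), "unloaded")
})
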