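test_that("frame lines carry 24 channels in fixed order", {
  f0 <- insole_frame(0, "L", rep(0L, 16), rep(0L, 8))
  line <- encode_frame(f0)
  fields <- strsplit(line, ",")[[1]]
  expect_length(fields, 26)
  expect_true(all(fields[3:26] == "0"))
  # hand-written line: channels 1..24 split 16 pressure + 8 temperature
  hand <- paste(c("1.250", "R", 1:24), collapse = ",")
  f <- decode_frame(hand)
  expect_equal(f$pressure_adc, 1:16)
  expect_equal(f$temperature_adc, 17:24)
  expect_equal(f$timestamp, 1.25)
  expect_equal(f$foot, "R")
})

test_that("decode rejects malformed lines with a diagnostic", {
  good <- paste(c("0.000", "L", 1:24), collapse = ",")
  expect_error(decode_frame(paste(c("0.000", "L", 1:23), collapse = ",")),
               "expected 24 channel fields, got 23")
  expect_error(decode_frame(sub("^0.000,L,1,", "0.000,L,x,", good)),
               "field 3")
  expect_error(decode_frame(paste(c("0.000", "L", 5000, 2:24), collapse = ",")),
               "above full scale")
  expect_error(decode_frame(paste(c("0.000", "X", 1:24), collapse = ",")),
               "foot tag")
})

test_that("encode/decode round-trips random frames", {
  set.seed(11)
  for (i in 1:25) {
    f <- random_frame()
    expect_identical(decode_frame(encode_frame(f)), f)
  }
})

test_that("log files round-trip trials exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  # empty trial -> header-only file -> empty trial
  empty <- insole_trial(constant_frames(0), trial_id = "empty")
  write_log(empty, path)
  back <- read_log(path)
  expect_equal(n_frames(back), 0)
  expect_equal(back$trial_id, "empty")

  # a simulated 10 s trial at 40 Hz has 400 data lines
  set.seed(12)
  df <- constant_frames(400)
  for (ch in sprintf("p%02d", 1:16)) df[[ch]] <- sample(0:4095, 400, TRUE)
  tr <- insole_trial(df, subject = fixture_subject(), trial_id = "t10s")
  write_log(tr, path)
  expect_length(grep("^#", readLines(path), invert = TRUE), 401)  # header + 400
  back <- read_log(path)
  expect_equal(back$frames, tr$frames)
  expect_equal(back$subject$weight, tr$subject$weight)
  expect_equal(back$sampling_rate, 40)
})

test_that("a truncated final line is dropped with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  tr <- insole_trial(constant_frames(5), trial_id = "trunc")
  write_log(tr, path)
  lines <- readLines(path)
  lines[length(lines)] <- substr(lines[length(lines)], 1, 20)
  writeLines(lines, path)
  expect_warning(back <- read_log(path), "truncated")
  expect_equal(n_frames(back), 4)
})

test_that("trial construction enforces the sampling contract", {
  df <- constant_frames(10)
  df$timestamp[5] <- df$timestamp[4]          # non-increasing
  expect_error(insole_trial(df), "strictly increasing")
  df <- constant_frames(10)
  df$timestamp[5] <- df$timestamp[5] + 0.01   # wrong spacing
  expect_error(insole_trial(df), "spacing")
  expect_error(insole_frame(0, "L", rep(0, 15), rep(0, 8)), "16 pressure")
  expect_no_error(insole_frame(0, "L", rep(0, 16), rep(0, 8),
                               cfg = divider_config(adc_bits = 10)))
  expect_error(insole_frame(0, "L", rep(5000, 16), rep(0, 8),
                            cfg = divider_config()), "full scale")
})

test_that("ground-truth sidecars round-trip through files", {
  tr <- fixture_walk()
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(tr, path)
  gt <- read_ground_truth(path)
  orig <- attr(tr, "ground_truth")
  expect_equal(gt$heel_strikes, orig$heel_strikes)
  expect_equal(gt$per_frame$vgrf_sensed_n, orig$per_frame$vgrf_sensed_n,
               tolerance = 1e-6)
})
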