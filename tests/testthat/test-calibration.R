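test_that("ADC-to-voltage mapping is linear with exact endpoints", {
  cfg <- divider_config()
  expect_equal(adc_to_voltage(4095, cfg), 5.0)
  expect_equal(adc_to_voltage(0, cfg), 0.0)
  expect_equal(adc_to_voltage(819, cfg), 1.0)
  # linearity on a vector of counts
  a <- c(100, 500, 2047.5, 4000)
  expect_equal(adc_to_voltage(a, cfg), 5 * a / 4095)
  expect_error(adc_to_voltage(5000, cfg), "out of range")
  expect_error(adc_to_voltage(-1, cfg, channel = "p03"), "p03")
})

test_that("divider inversion recovers resistance and flags open circuits", {
  cfg <- divider_config()
  expect_equal(resistance_from_voltage(2.5, cfg), 10000)
  expect_equal(resistance_from_voltage(1.0, cfg), 40000)
  expect_equal(resistance_from_voltage(5.0, cfg), 0)
  expect_error(resistance_from_voltage(0, cfg), class = "insole_open_circuit")
  expect_error(resistance_from_voltage(5.5, cfg), "above supply")
  # exact algebraic inverse of the forward divider for random resistances
  set.seed(1)
  r <- 10^runif(1000, 1, 6)
  v <- cfg$vcc * cfg$r_ext / (cfg$r_ext + r)
  expect_equal(resistance_from_voltage(v, cfg), r, tolerance = 1e-10)
})

test_that("one-step thermistor count conversion matches the composed path", {
  cfg <- divider_config()
  expect_equal(thermistor_resistance_from_adc(819, cfg), 40000)
  expect_equal(thermistor_resistance_from_adc(4095, cfg), 0)
  expect_equal(thermistor_resistance_from_adc(2048, cfg),
               (40950000 - 10000 * 2048) / 2048)
  expect_error(thermistor_resistance_from_adc(0, cfg),
               class = "insole_open_circuit")
  a <- seq(1, 4094, length.out = 1000)
  composed <- resistance_from_voltage(adc_to_voltage(a, cfg), cfg)
  expect_equal(thermistor_resistance_from_adc(a, cfg), composed,
               tolerance = 1e-12)
})

test_that("temperature conversion inverts the exponential model", {
  m <- thermistor_model()
  expect_equal(suppressWarnings(temperature_from_resistance(24710, m)), 0)
  expect_equal(suppressWarnings(temperature_from_resistance(10000, m)),
               (log(10000) - log(24710)) / -0.036)
  expect_equal(temperature_from_resistance(24710 * exp(-0.036 * 40), m), 40)
  # round trip across the working range
  tt <- seq(20, 50, length.out = 200)
  expect_equal(temperature_from_resistance(thermistor_resistance_at(tt, m), m,
                                           warn_range = FALSE),
               tt, tolerance = 1e-9)
  expect_error(temperature_from_resistance(-5, m), "positive")
  expect_warning(temperature_from_resistance(24710, m), "working range")
})

test_that("closed-form count-to-temperature equals the two-step path everywhere", {
  cfg <- divider_config()
  m <- thermistor_model()
  a <- seq(1, 4094, length.out = 1000)
  closed <- temperature_from_adc(a, cfg, m, warn_range = FALSE)
  two_step <- temperature_from_resistance(
    thermistor_resistance_from_adc(a, cfg), m, warn_range = FALSE)
  expect_lt(max(abs(closed - two_step)), 1e-9)
  expect_error(temperature_from_adc(4095, cfg, m), "strictly inside")
  expect_error(temperature_from_adc(0, cfg, m), "strictly inside")
  # model anchor: the count that reads 24710 Ohm decodes to ~0 degC
  a0 <- 4095 * 10000 / (10000 + 24710)
  expect_equal(temperature_from_adc(a0, cfg, m, warn_range = FALSE), 0,
               tolerance = 1e-9)
})

test_that("exponential calibration fit recovers the generating curve", {
  tt <- seq(20, 50, by = 5)
  fit <- fit_exponential_calibration(tt, 24710 * exp(-0.036 * tt))
  expect_equal(fit$model$a, 24710, tolerance = 1e-9)
  expect_equal(fit$model$b, -0.036, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # two points determine an interpolating model through both
  fit2 <- fit_exponential_calibration(c(20, 40), c(12000, 6000))
  expect_equal(thermistor_resistance_at(c(20, 40), fit2$model),
               c(12000, 6000), tolerance = 1e-9)
  expect_error(fit_exponential_calibration(c(25, 25), c(1e4, 2e4)),
               "coincide")
  expect_error(fit_exponential_calibration(c(20, 30), c(1e4, -1)), "positive")
})

test_that("calibration fit tolerates realistic multiplicative noise", {
  # tolerance established by a 200-seed Monte-Carlo at this noise level
  set.seed(7)
  tt <- 20:50
  for (i in 1:20) {
    r <- 24710 * exp(-0.036 * tt) * (1 + 0.02 * rnorm(31))
    fit <- fit_exponential_calibration(tt, r)
    expect_lt(abs(fit$model$b - (-0.036)) / 0.036, 0.05)
  }
})

test_that("pressure, force and mass arithmetic match the sensor data sheet", {
  expect_equal(active_area(6.35), 126.68, tolerance = 0.005 / 126.68)
  expect_equal(active_area(0), 0)
  expect_equal(active_area(1), pi)
  expect_error(active_area(-1), "non-negative")

  f_lo <- force_from_pressure(80000, 126.677)
  f_hi <- force_from_pressure(600000, 126.677)
  expect_equal(round(f_lo), 10)
  expect_equal(round(f_hi), 76)
  expect_equal(force_from_pressure(0, 126.677), 0)
  # linear scaling in pressure
  expect_equal(force_from_pressure(3 * 80000, 126.677), 3 * f_lo)

  expect_equal(round(mass_from_force(f_lo), 2), 1.03)
  expect_equal(round(mass_from_force(f_hi), 2), 7.75)
  expect_equal(mass_from_force(0), 0)
  expect_error(mass_from_force(10, g = 0), "positive")
})
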