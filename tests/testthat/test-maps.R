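test_that("the foot template rasterizes the outline deterministically", {
  lay <- default_sensor_layout()
  tpl1 <- build_template(lay)
  tpl2 <- build_template(lay)
  expect_identical(tpl1, tpl2)
  # halving the resolution (doubling cell size) quarters the cell count
  tpl2mm <- build_template(lay, resolution_mm = 2)
  expect_equal(sum(tpl1$mask) / sum(tpl2mm$mask), 4, tolerance = 0.05)
  # rasterized area approaches the outline polygon area
  a_mask <- sum(tpl1$mask) * tpl1$resolution_mm^2
  expect_equal(a_mask, template_outline_area(tpl1), tolerance = 0.02)
})

test_that("sensors outside the outline are rejected by id", {
  lay <- default_sensor_layout()
  lay$y_mm[lay$id == "P01"] <- -50
  expect_error(build_template(lay), "P01")
})

test_that("linear interpolation is node-exact and bounded", {
  lay <- default_sensor_layout()
  tpl <- build_template(lay, resolution_mm = 2)
  set.seed(13)
  for (i in 1:5) {
    v <- runif(16, 0, 50)
    mp <- interpolate_map(v, lay, tpl, kind = "pressure")
    # exact at each sensor's cell
    expect_equal(mp$grid[cbind(mp$sites$row, mp$sites$col)], v)
    # bounded by the input range on the whole mask
    expect_gte(min(mp$grid, na.rm = TRUE), min(v) - 1e-9)
    expect_lte(max(mp$grid, na.rm = TRUE), max(v) + 1e-9)
  }
  # all sites equal -> uniform map
  mp_u <- interpolate_map(rep(7, 16), lay, tpl, kind = "pressure")
  expect_true(all(abs(mp_u$grid[tpl$mask] - 7) < 1e-9))
  # a single hot site carries the map maximum
  v1 <- rep(0, 16); v1[11] <- 5
  mp1 <- interpolate_map(v1, lay, tpl, kind = "pressure")
  peak <- which(mp1$grid == max(mp1$grid, na.rm = TRUE), arr.ind = TRUE)
  expect_true(any(abs(tpl$ys[peak[, 1]] - lay$y_mm[11]) <= tpl$resolution_mm &
                    abs(tpl$xs[peak[, 2]] - lay$x_mm[11]) <= tpl$resolution_mm))
})

test_that("interpolation rejects degenerate site sets", {
  lay <- default_sensor_layout()
  tpl <- build_template(lay, resolution_mm = 2)
  expect_error(interpolate_map(rep(1, 15), lay, tpl, kind = "pressure"),
               "expected 16")
  collinear <- lay
  collinear$x_mm[collinear$kind == "temperature"] <- 0
  expect_error(interpolate_map(rep(1, 8), collinear, tpl,
                               kind = "temperature"), "collinear")
})

test_that("mirroring the layout mirrors the map grid", {
  lay <- default_sensor_layout()
  tpl <- build_template(lay, resolution_mm = 2)
  set.seed(14)
  v <- runif(16, 0, 30)
  mp_l <- interpolate_map(v, lay, tpl, kind = "pressure")
  mp_r <- interpolate_map(v, mirror_layout(lay), tpl, kind = "pressure")
  flipped <- mp_r$grid[, rev(seq_len(ncol(mp_r$grid)))]
  expect_equal(mp_l$grid, flipped, tolerance = 1e-9)
})

test_that("phase pressure maps track the heel-to-toe load progression", {
  tr <- fixture_walk()
  cyc <- segment_cycles(total_vgrf(tr))
  lay <- default_sensor_layout()
  tpl <- build_template(lay, resolution_mm = 2)
  phases <- c("heel strike" = 0, "midstance" = 0.30, "late stance" = 0.55,
              "mid-swing" = 0.80)
  maps <- phase_pressure_maps(tr, cyc[1, ], phases = phases, layout = lay,
                              template = tpl)
  centroid_y <- function(mp) {
    w <- mp$grid; w[is.na(w)] <- 0
    sum(w * mp$ys[row(w)]) / sum(w)
  }
  l <- tpl$foot_length_mm
  expect_lt(centroid_y(maps[["heel strike"]]), l / 3)      # posterior third
  expect_gt(centroid_y(maps[["late stance"]]), 2 * l / 3)  # anterior third
  expect_gt(centroid_y(maps[["midstance"]]),               # monotone progression
            centroid_y(maps[["heel strike"]]))
  # swing: near-zero force everywhere
  expect_lt(max(maps[["mid-swing"]]$grid, na.rm = TRUE),
            0.02 * max(maps[["midstance"]]$grid, na.rm = TRUE))
  expect_error(phase_pressure_maps(tr, cyc[1, ], phases = 1.5), "\\[0, 1\\]")
})

test_that("standing temperature maps recover uniform fields and hot spots", {
  s <- fixture_subject()
  lay <- default_sensor_layout()
  tpl <- build_template(lay, resolution_mm = 2)
  # uniform 30 degC, no drift: uniform map within quantization tolerance
  st <- simulate_standing(s, seed = 15, duration_s = 12,
                          temp_baseline = rep(30, 8), temp_drift_c_per_s = 0)
  mp <- standing_temperature_map(st, lay, tpl, window_s = 10)
  expect_lt(max(abs(mp$grid[tpl$mask] - 30)), 0.1)
  expect_equal(mp$units, "degC")
  # +4 degC hot spot at temperature site 5: map maximum lands there
  base <- rep(30, 8); base[5] <- 34
  st2 <- simulate_standing(s, seed = 16, duration_s = 12,
                           temp_baseline = base, temp_drift_c_per_s = 0)
  mp2 <- standing_temperature_map(st2, lay, tpl, window_s = 10)
  tch <- layout_channels(lay, "temperature")
  peak <- which(mp2$grid == max(mp2$grid, na.rm = TRUE), arr.ind = TRUE)
  expect_true(any(abs(tpl$ys[peak[, 1]] - tch$y_mm[5]) <= tpl$resolution_mm &
                    abs(tpl$xs[peak[, 2]] - tch$x_mm[5]) <= tpl$resolution_mm))
  # constant field: any averaging window gives the same map
  mp3 <- standing_temperature_map(st, lay, tpl, window_s = 5)
  expect_equal(mp3$grid, mp$grid, tolerance = 0.05)
  expect_error(standing_temperature_map(st, lay, tpl, window_s = 60),
               "exceeds the trial")
})
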