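test_that("reference volume and landmarks follow the closed form", {
  ph <- prolate_phantom()
  expect_equal(phantom_volume(ph, 1), 4 / 3 * pi * 20 * 20 * 40)
  expect_equal(ph$roof_apex, c(0, 0, 80))
  expect_equal(ph$annulus_center, c(0, 0, 0))
  expect_equal(unname(ph$scales[ph$events$mitral_closure, ]), c(1, 1, 1))
  # tilt angle is realized between LA and LV axes
  ph15 <- prolate_phantom(theta = 15)
  expect_equal(acos(sum(ph15$la_axis * ph15$lv_axis)) * 180 / pi, 15)
  expect_equal(prolate_phantom(theta = 0)$lv_axis, c(0, 0, 1))
})

test_that("prescribed LAVmax/LAVmin/pre-A volumes are interpolated exactly", {
  ph <- make_phantom(20, 20, 40, volume_curve_params = list(
    lavmax = 82000, lavmin = 38000))
  ev <- ph$events
  expect_equal(phantom_volume(ph, ev$mitral_closure), 38000)
  expect_equal(phantom_volume(ph, ev$mitral_opening), 82000)
  expect_equal(phantom_volume(ph, ev$pre_A), 38000 + 0.4 * 44000)
  # mesh path agrees within 0.5% at the default resolution, and the
  # volume-curve extrema sit on the event frames
  expect_equal(phantom_volume(ph, ev$mitral_opening, method = "mesh"),
               82000, tolerance = 0.005)
  vols <- phantom_volume_series(ph)
  expect_equal(which.max(vols), ev$mitral_opening)
  expect_equal(which.min(vols), ev$mitral_closure)
})

test_that("mesh and closed-form volumes agree within 0.5% at every phase", {
  ph <- make_phantom(18, 24, 38, volume_curve_params = list(
    lavmax = 90000, lavmin = 40000), n_phases = 25)
  for (phase in seq(1, 25, by = 6)) {
    expect_equal(phantom_volume(ph, phase, method = "mesh"),
                 phantom_volume(ph, phase, method = "analytic"),
                 tolerance = 0.005)
  }
})

test_that("roof blunting attenuates displacement and volume", {
  ph <- prolate_phantom()
  phase <- ph$events$mitral_opening
  # lambda = 0: displaced surface is the affine-scaled ellipsoid exactly
  p <- cbind(c(20, 0, 0, 0), c(0, 20, 0, 0), c(40, 45, 75, 80))
  s <- ph$scales[phase, ]
  expect_equal(roof_blunted_displacement(ph, p, phase, lambda = 0),
               cbind(p[, 1] * s[1], p[, 2] * s[2], p[, 3] * s[3]))
  # lambda = 1: the roof apex never moves
  apex <- rbind(c(0, 0, 80))
  for (f in seq_len(ph$n_phases))
    expect_equal(roof_blunted_displacement(ph, apex, f, lambda = 1), apex)
  # lambda = 0.5 at z' = 0.75: displacement scaled by 0.75
  pt <- rbind(c(10 * sqrt(3), 0, 60))  # on the surface, z' = 0.75
  full <- roof_blunted_displacement(ph, pt, phase, lambda = 0)
  got <- roof_blunted_displacement(ph, pt, phase, lambda = 0.5)
  expect_equal(got - pt, 0.75 * (full - pt))
  # blunting removes displacement, hence volume, at expansion phases
  ph_l <- make_phantom(20, 20, 40, lambda = 0.5)
  expect_lt(phantom_volume(ph_l, phase, method = "mesh"),
            phantom_volume(ph, phase, method = "mesh"))
  # weight is monotonically non-increasing toward the roof
  zp <- seq(0, 1, by = 0.05)
  w <- 1 - 0.7 * pmax(0, (zp - 0.5) / 0.5)
  expect_true(all(diff(w) <= 0))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(make_phantom(30, 20, 25), "prolate")
  expect_error(make_phantom(20, 20, 40, theta_deg = 90), "90")
  expect_error(make_phantom(20, 20, 40, theta_deg = -5), "90")
  expect_error(make_phantom(20, 20, 40, lambda = 1.5), "lambda")
  expect_error(make_phantom(20, 20, 40, volume_curve_params = list(
    lavmax = 30000, lavmin = 38000)), "LAVmin")
  expect_error(make_phantom(20, 20, 40, volume_curve_params = list(
    lavmax = 82000, lavmin = 38000, prea = 90000)), "pre-A")
  ph <- prolate_phantom()
  expect_error(phantom_volume(ph, 0), "phase")
  expect_error(phantom_volume(ph, ph$n_phases + 1), "phase")
})

test_that("volume curve is periodic with a pre-A shoulder", {
  ev <- list(mitral_closure = 1L, mitral_opening = 10L, pre_A = 21L)
  v <- volume_curve(25, ev, 38000, 82000, 55600)
  expect_equal(v[1], 38000)
  expect_equal(v[10], 82000)
  expect_equal(v[21], 55600)
  expect_true(all(v >= 38000 - 1e-9 & v <= 82000 + 1e-9))
  # rises to the max, falls to pre-A, then empties toward the wrap
  expect_true(all(diff(v[1:10]) >= 0))
  expect_true(all(diff(v[10:21]) <= 0))
  expect_true(all(diff(v[21:25]) <= 0))
})
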