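test_that("biplane area-length evaluates the printed formula with the Lmin rule", {
  a <- pi * 20 * 40
  expect_equal(biplane_area_length(a, a, 80, 80), 0.85 * a^2 / 80)
  expect_equal(biplane_area_length(a, a, 80, 80) / 1000, 67.11, tolerance = 1e-4)
  # the shorter length is used, whichever view it comes from
  expect_equal(biplane_area_length(2000, 1800, 70, 65), 0.85 * 2000 * 1800 / 65)
  expect_equal(biplane_area_length(2000, 1800, 65, 70), 0.85 * 2000 * 1800 / 65)
  expect_error(biplane_area_length(0, 1800, 70, 65), "positive")
  expect_error(biplane_area_length(2000, 1800, 70, -1), "positive")
})

test_that("biplane volume on focused views obeys the ellipsoid identity", {
  # for any principal-axis ellipsoid the area-length estimate is
  # 0.85/(8/(3*pi)) = 1.00138 times the true volume, at every phase
  for (axes in list(c(20, 20, 40), c(18, 25, 42), c(30, 30, 33))) {
    ph <- make_phantom(axes[1], axes[2], axes[3], volume_curve_params = list(
      lavmax = 82000, lavmin = 38000))
    foc <- prescribe_focused_planes(ph)
    for (phase in c(1L, 7L, ph$events$mitral_opening)) {
      m2 <- measure_contour(section(ph, foc$focused_2ch, phase))
      m4 <- measure_contour(section(ph, foc$focused_4ch, phase))
      v <- biplane_area_length(m4$area, m2$area,
                               m4$long_axis_length, m2$long_axis_length)
      expect_equal(v / phantom_volume(ph, phase), 0.85 * 3 * pi / 8,
                   tolerance = 0.005)
    }
  }
})

test_that("disk summation is thickness times summed areas and converges", {
  expect_equal(disk_volume(c(1000, 500), 6), 9000)
  expect_equal(disk_volume(rep(0, 10), 6), 0)
  expect_error(disk_volume(numeric(0), 6), "empty")
  expect_error(disk_volume(c(100, -1), 6), "non-negative")
  # midpoint-rule disk sum on a static sphere vs the analytic volume
  sph <- static_sphere(30)
  stack <- prescribe_short_axis_stack(sph, 1)
  areas <- vapply(stack, function(pl)
    measure_contour(section(sph, pl, 1))$area, numeric(1))
  expect_equal(disk_volume(areas, 1), 4 / 3 * pi * 30^3, tolerance = 0.005)
})

test_that("phase selection takes argmax/argmin with earlier-frame ties", {
  fr <- select_phases(c(38, 60, 82, 70, 45))
  expect_equal(fr$max_frame, 3L)
  expect_equal(fr$min_frame, 1L)
  fr2 <- select_phases(rep(50, 6))
  expect_equal(c(fr2$max_frame, fr2$min_frame), c(1L, 1L))
  expect_error(select_phases(42), "two phases")
  # phantom-generated series peak on the prescribed event frames
  ph <- make_phantom(20, 20, 40, theta_deg = 12, volume_curve_params = list(
    lavmax = 82000, lavmin = 38000))
  m <- measure_phantom(ph)
  expect_equal(m$reference$max_frame, ph$events$mitral_opening)
  expect_equal(m$reference$min_frame, ph$events$mitral_closure)
  expect_equal(m$standard$max_frame, ph$events$mitral_opening)
  expect_equal(m$focused$min_frame, ph$events$mitral_closure)
})

test_that("emptying fraction follows its definition and scale invariance", {
  expect_equal(laef(100, 50), 50)
  expect_equal(laef(82, 38), 53.66, tolerance = 1e-4)
  expect_equal(laef(82, 38), 100 * 44 / 82)
  expect_equal(laef(70, 70), 0)
  expect_error(laef(0, 0), "positive")
  expect_error(laef(50, 60), "exceed")
  for (k in c(0.1, 2, 1000)) expect_equal(laef(82 * k, 38 * k), laef(82, 38))
})

test_that("BSA indexing divides by body surface area", {
  expect_equal(index_to_bsa(82, 1.88), 82 / 1.88)
  expect_equal(round(index_to_bsa(82, 1.88), 1), 43.6)
  expect_equal(index_to_bsa(0, 2), 0)
  expect_equal(index_to_bsa(57, 1), 57)
  expect_error(index_to_bsa(82, 0), "positive")
})

test_that("severity categories partition indexed LAVmax without gaps", {
  expect_equal(as.character(classify_severity(42)), "normal")
  expect_equal(as.character(classify_severity(c(0, 52.99))), c("normal", "normal"))
  expect_equal(as.character(classify_severity(53)), "mild")
  expect_equal(as.character(classify_severity(62.99)), "mild")
  expect_equal(as.character(classify_severity(63)), "moderate")
  expect_equal(as.character(classify_severity(73)), "moderate")
  expect_equal(as.character(classify_severity(73.01)), "severe")
  expect_error(classify_severity(-1), "non-negative")
  # every non-negative value lands in exactly one ordered category
  x <- seq(0, 120, by = 0.25)
  f <- classify_severity(x)
  expect_false(anyNA(f))
  expect_true(is.ordered(f))
  expect_true(all(diff(as.integer(f)) >= 0))
})

test_that("volume series bundles derived quantities consistently", {
  vols <- volume_curve(25, list(mitral_closure = 1L, mitral_opening = 10L,
                                pre_A = 21L), 38000, 82000, 55600)
  vs <- volume_series(vols, bsa = 1.88, method = "reference")
  expect_equal(vs$lavmax_ml, 82)
  expect_equal(vs$lavmin_ml, 38)
  expect_equal(vs$laef, laef(82, 38))
  expect_equal(vs$lavmax_i, 82 / 1.88)
  expect_equal(as.character(vs$severity), "normal")
  expect_output(print(vs), "LAEF 53.7")
})
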