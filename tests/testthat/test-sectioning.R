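test_that("focused planes pass through annulus and roof, 2ch parallel to septum", {
  ph <- prolate_phantom(theta = 20)
  foc <- prescribe_focused_planes(ph)
  for (pl in foc) {
    expect_equal(sum(pl$normal * (ph$annulus_center - pl$origin)), 0)
    expect_equal(sum(pl$normal * (ph$roof_apex - pl$origin)), 0)
    expect_equal(sqrt(sum(pl$normal^2)), 1)
  }
  expect_equal(abs(sum(foc$focused_2ch$normal * ph$septum_normal)), 1)
  expect_equal(sum(foc$focused_2ch$normal * foc$focused_4ch$normal), 0)
})

test_that("standard planes contain the annulus and the LV axis; tilt 0 recovers focused", {
  ph <- prolate_phantom(theta = 25)
  std <- prescribe_standard_planes(ph)
  for (pl in std) {
    expect_equal(sum(pl$normal * (ph$annulus_center - pl$origin)), 0)
    expect_equal(sum(pl$normal * ph$lv_axis), 0, tolerance = 1e-12)
  }
  expect_equal(sum(std$standard_2ch$normal * std$standard_4ch$normal), 0,
               tolerance = 1e-12)
  ph0 <- prolate_phantom(theta = 0)
  std0 <- prescribe_standard_planes(ph0)
  foc0 <- prescribe_focused_planes(ph0)
  expect_equal(abs(sum(std0$standard_2ch$normal * foc0$focused_2ch$normal)), 1)
  expect_equal(abs(sum(std0$standard_4ch$normal * foc0$focused_4ch$normal)), 1)
})

test_that("focused sections of the ellipsoid match the principal closed form", {
  ph <- prolate_phantom()
  foc <- prescribe_focused_planes(ph)
  for (phase in c(1L, ph$events$mitral_opening)) {
    s <- ph$scales[phase, ]
    m2 <- measure_contour(section(ph, foc$focused_2ch, phase))
    m4 <- measure_contour(section(ph, foc$focused_4ch, phase))
    expect_equal(m2$area, pi * 20 * s[["sy"]] * 40 * s[["sz"]], tolerance = 1e-4)
    expect_equal(m4$area, pi * 20 * s[["sx"]] * 40 * s[["sz"]], tolerance = 1e-4)
    expect_equal(m2$long_axis_length, 80 * s[["sz"]], tolerance = 1e-6)
  }
})

test_that("central sphere section is a circle; mesh and analytic paths agree", {
  sph <- static_sphere(30)
  pl <- prescribe_short_axis_stack(sph, 30)[[1]]  # mid-plane at z = 15
  expect_equal(measure_contour(section(sph, pl, 1))$area,
               pi * (30^2 - 15^2), tolerance = 1e-4)
  # equatorial plane through the center
  eq <- prescribe_short_axis_stack(sph, 60)[[1]]  # mid-plane at z = 30
  m <- measure_contour(section(sph, eq, 1))
  expect_equal(m$area, pi * 900, tolerance = 1e-4)
  expect_equal(m$perimeter, 188.4956, tolerance = 1e-4)
  # cross-validation of the two internal section paths on a tilted plane
  ph <- prolate_phantom(theta = 18)
  std <- prescribe_standard_planes(ph)
  for (pl in std) {
    ma <- measure_contour(section(ph, pl, 5, path = "analytic"))
    mm <- measure_contour(section(ph, pl, 5, path = "mesh"))
    expect_equal(mm$area, ma$area, tolerance = 0.005)
    expect_equal(mm$long_axis_length, ma$long_axis_length, tolerance = 0.005)
  }
})

test_that("short-axis stack covers the phantom with ceil(extent/thickness) slices", {
  sph <- static_sphere(30)
  expect_length(prescribe_short_axis_stack(sph, 1), 60)
  ph <- prolate_phantom()  # expands beyond 80 mm over the cycle
  stack6 <- prescribe_short_axis_stack(ph, 6)
  extent <- 2 * 40 * max(ph$scales[, "sz"])
  expect_length(stack6, ceiling(extent / 6))
  # a static 80 mm phantom needs exactly ceil(80/6) = 14 slices
  st <- make_phantom(20, 20, 40, volume_curve_params = list(
    lavmin = 4 / 3 * pi * 20 * 20 * 40, lavmax = 4 / 3 * pi * 20 * 20 * 40))
  expect_length(prescribe_short_axis_stack(st, 6), 14)
  # every surface point lies between the first and last slab face
  top <- max(vapply(seq_len(ph$n_phases), function(f)
    max(laquant:::phantom_vertices(ph, f)[, 3]), numeric(1)))
  expect_lte(top, length(stack6) * 6)
  expect_error(prescribe_short_axis_stack(ph, 0), "positive")
})

test_that("planes beyond the roof return the explicit no-section sentinel", {
  ph <- prolate_phantom()
  beyond <- laquant:::imaging_plane(c(0, 0, 300), c(0, 0, 1), c(0, 1, 0), "sax_99")
  expect_true(is_no_section(section(ph, beyond, 1)))
  m <- measure_contour(section(ph, beyond, 1))
  expect_equal(m$area, 0)
  expect_equal(m$perimeter, 0)
  ph_l <- prolate_phantom(lambda = 0.4)
  expect_true(is_no_section(section(ph_l, beyond, 1)))
})

test_that("contour measures: square, ellipse, landmark length", {
  sq <- laquant:::new_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                              "sax_01", 1L)
  m <- measure_contour(sq)
  expect_equal(m$area, 1)
  expect_equal(m$perimeter, 4)
  expect_true(is.na(m$long_axis_length))
  t <- seq(0, 2 * pi, length.out = 513)[-513]
  ell <- laquant:::new_contour(cbind(20 * cos(t), 40 * sin(t)), "focused_2ch",
                               1L, landmark = c(0, -40))
  me <- measure_contour(ell)
  expect_equal(me$area, pi * 800, tolerance = 0.001)
  expect_equal(me$long_axis_length, 80)
  expect_error(measure_contour(laquant:::new_contour(rbind(c(0, 0), c(1, 0)),
                                                     "x", 1L)), "3 vertices")
})

test_that("contours round-trip through CSV", {
  ph <- prolate_phantom(lambda = 0.3)
  cts <- list(section(ph, prescribe_focused_planes(ph)$focused_2ch, 1),
              section(ph, prescribe_short_axis_stack(ph, 6)[[3]], 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours_csv(cts, path)
  back <- read_contours_csv(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$vertices, unname(cts[[1]]$vertices))
  expect_equal(measure_contour(back[[2]])$area,
               measure_contour(cts[[2]])$area)
  expect_error(read_contours_csv(withr::local_tempfile(lines = "a,b\n1,2")),
               "columns")
})
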