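test_that("effective magnification follows the tube/reference focal ratio", {
  expect_equal(effective_magnification(4, 150, 180), 4 * 150 / 180)
  expect_equal(effective_magnification(10, 150, 180), 10 * 150 / 180)
  # identity when the tube lens matches the reference
  for (f in c(90, 180, 200)) expect_equal(effective_magnification(7, f, f), 7)
  expect_error(effective_magnification(-4, 150, 180), "positive")
  expect_error(effective_magnification(4, 0, 180), "positive")
})

test_that("LED wave vectors follow the direction sines of the geometry", {
  # hand trigonometry oracle: LED 28 mm off-axis, 70 mm below the stage
  theta <- atan2(28, 70)
  expect_equal(wavevector_for_led(28, 0, 70, 0.53)$kx_per_um,
               2 * pi * sin(theta) / 0.53, tolerance = 1e-12)
  expect_equal(wavevector_for_led(28, 0, 70, 0.53)$sin_theta_x,
               28 / sqrt(28^2 + 70^2), tolerance = 1e-12)
  # on-axis LED
  k0 <- wavevector_for_led(0, 0, 70, 0.53)
  expect_identical(c(k0$kx_per_um, k0$ky_per_um), c(0, 0))
  # swapping x and y swaps the components
  a <- wavevector_for_led(12, -5, 70, 0.53)
  b <- wavevector_for_led(-5, 12, 70, 0.53)
  expect_equal(a$kx_per_um, b$ky_per_um)
  expect_equal(a$ky_per_um, b$kx_per_um)
  expect_error(wavevector_for_led(1, 1, 0, 0.53), "distance")
})

test_that("illumination NA reflects the outermost used LEDs", {
  geom <- led_array()
  expect_equal(illumination_na(geom), 28 / sqrt(28^2 + 70^2), tolerance = 1e-12)
  expect_gt(illumination_na(geom, "diagonal"), illumination_na(geom))
  # single on-axis LED
  expect_equal(illumination_na(led_array(used_rows = 1, used_cols = 1)), 0)
  # shrinking the stage distance strictly increases the NA
  nas <- vapply(c(90, 70, 50, 30), function(d)
    illumination_na(led_array(stage_distance_mm = d)), numeric(1))
  expect_true(all(diff(nas) > 0))
  # invariant under swapping rows and columns (90 degree rotation)
  g1 <- led_array(used_rows = 15, used_cols = 11)
  g2 <- led_array(used_rows = 11, used_cols = 15)
  expect_equal(illumination_na(g1), illumination_na(g2))
  expect_equal(illumination_na(g1, "diagonal"), illumination_na(g2, "diagonal"))
})

test_that("equivalent NA is the symmetric sum of objective and illumination NA", {
  expect_equal(equivalent_na(0.1, 0.38), 0.48)
  expect_equal(equivalent_na(0.25, 0.38), 0.63)
  expect_equal(equivalent_na(0.3, 0.2), equivalent_na(0.2, 0.3))
  expect_equal(equivalent_na(0.25, 0), 0.25)
  expect_error(equivalent_na(1.2, 0.3))
})

test_that("coherent cutoff converts NA and wavelength to lp/mm linearly", {
  expect_equal(coherent_cutoff_lp_per_mm(0.1, 0.53), 0.1 / 0.00053)
  expect_equal(coherent_cutoff_lp_per_mm(0.48, 0.53), 0.48 / 0.00053)
  expect_equal(coherent_cutoff_lp_per_mm(0.2, 0.53),
               2 * coherent_cutoff_lp_per_mm(0.1, 0.53))
})

test_that("USAF frequencies follow the 2^(g + (e-1)/6) law and increase strictly", {
  expect_equal(usaf_frequency(9, 1), 512)
  expect_equal(usaf_frequency(7, 3), 2^(7 + 2 / 6))
  # strict lexicographic monotonicity over several groups
  f <- unlist(lapply(5:10, function(g) usaf_frequency(g, 1:6)))
  expect_true(all(diff(f) > 0))
  expect_error(usaf_frequency(7, 0), "element")
  expect_error(usaf_frequency(7, 7), "element")
  expect_error(usaf_frequency(7.5, 3), "integer")
})

test_that("Rayleigh conversions round-trip and match the half-pitch law", {
  expect_equal(rayleigh_halfpitch_um(0.1, 0.53), 0.61 * 0.53 / 0.1)
  expect_equal(halfpitch_to_lp_per_mm(2), 250)
  for (x in c(0.05, 0.1, 0.33, 0.8)) {
    expect_equal(na_from_halfpitch(rayleigh_halfpitch_um(x, 0.53), 0.53), x,
                 tolerance = 1e-12)
  }
  hp <- rayleigh_halfpitch_um(0.25, 0.53)
  expect_equal(1000 / (2 * halfpitch_to_lp_per_mm(hp)), hp, tolerance = 1e-12)
})

test_that("make_pupil builds the exact binary disk and conjugates under -z", {
  # sampling chosen so the disk radius is exactly 10 px
  na <- 0.1; lam <- 0.53
  ds <- 2 * pi * na / lam / 10
  p <- make_pupil(c(64, 64), ds, na, lam)
  # brute-force per-pixel check
  q <- (1:64) - 33
  inside <- outer(q^2, q^2, `+`) <= 10^2 + 1e-9
  expect_identical(unname(p$mask), unname(inside))
  expect_true(all(p$array[p$mask] == 1))
  expect_true(all(p$array[!p$mask] == 0))
  # disk area ~ pi r^2 within a one-pixel perimeter band
  expect_lt(abs(sum(p$mask) - pi * 100), 2 * pi * 10 + 10)
  # defocus +z / -z are complex conjugates; z = 0 is real binary
  pz <- make_pupil(c(64, 64), ds, na, lam, defocus_um = 7)
  pm <- make_pupil(c(64, 64), ds, na, lam, defocus_um = -7)
  expect_equal(pz$array, Conj(pm$array), tolerance = 1e-12)
  expect_true(all(Mod(pz$array[pz$mask]) - 1 < 1e-12))
  # disk exceeding the grid Nyquist extent is refused
  expect_error(make_pupil(c(16, 16), ds, 0.9, lam), "Nyquist")
})

test_that("illumination plan enumerates the used sub-grid with on-axis entry first in spiral order", {
  plan <- illumination_plan(led_array(), 0.53)
  expect_equal(nrow(plan), 225)
  expect_equal(plan$x_mm[1], 0)
  expect_equal(plan$y_mm[1], 0)
  expect_equal(plan$kx_per_um[1], 0)
  # spiral order is non-decreasing in |k|
  r <- plan$sin_theta_x^2 + plan$sin_theta_y^2
  expect_true(all(diff(r) >= -1e-15))
  expect_error(led_array(used_rows = 40), "fit inside")
  expect_error(led_array(used_rows = 4), "odd")
})
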