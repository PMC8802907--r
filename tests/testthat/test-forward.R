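test_that("FFT forward path agrees with the brute-force DFT oracle", {
  set.seed(42)
  f <- 2
  config <- matched_config(0.1, 4, 0.4, f)
  plan <- illumination_plan(led_array(), 0.53)
  picks <- c(1, 60, 140, 225)
  for (rep in 1:3) {
    n <- 32
    obj <- complex_object(matrix(runif(n * n, 0.2, 1), n, n),
                          matrix(runif(n * n, -1, 1), n, n), 0.4)
    st <- simulate_acquisition(obj, config, plan[picks, ],
                               acquisition_options(downsample_factor = f))
    for (i in seq_along(picks)) {
      bf <- brute_force_forward(obj, config,
                                c(plan$kx_per_um[picks[i]],
                                  plan$ky_per_um[picks[i]]), f)
      expect_lt(sqrt(mean((st$images[[i]] - bf)^2)), 1e-10)
    }
  }
  expect_error(brute_force_forward(
    complex_object(matrix(1, 128, 128), pixel_um = 0.4), config, c(0, 0)),
    "64x64")
})

test_that("a clear sample under bright-field illumination gives a unit image", {
  config <- matched_config(0.1, 4, 0.4, 2)
  plan <- on_axis_plan(illumination_plan(led_array(), 0.53))
  obj <- complex_object(matrix(1, 32, 32), pixel_um = 0.4)
  st <- simulate_acquisition(obj, config, plan,
                             acquisition_options(downsample_factor = 2))
  expect_equal(st$images[[1]], matrix(1, 16, 16), tolerance = 1e-12)
})

test_that("a pupil covering the object band acts as the identity filter", {
  # band-limited object, pupil radius comfortably larger than its band
  obj <- make_bandlimited_object(48, 0.2, radius_px = 6, seed = 3)
  config <- matched_config(0.6, 4, 0.2, 1)  # radius ~ 13.6 px > 6
  plan <- on_axis_plan(illumination_plan(led_array(), 0.53))
  st <- simulate_acquisition(obj, config, plan,
                             acquisition_options(downsample_factor = 1))
  expect_equal(st$images[[1]], Mod(as_complex_field(obj))^2, tolerance = 1e-10)
  # Parseval: an all-pass filter conserves power
  expect_equal(sum(st$images[[1]]), sum(obj$amplitude^2), tolerance = 1e-10)
})

test_that("a phase-ramp object on-axis equals a uniform object under the tilted LED", {
  config <- matched_config(0.1, 4, 0.4, 2)
  plan <- illumination_plan(led_array(), 0.53)
  m <- which(plan$row == 2 & plan$col == -3)
  n <- 32
  dk <- 2 * pi / (n * 0.4)
  sx <- round(plan$kx_per_um[m] / dk); sy <- round(plan$ky_per_um[m] / dk)
  jx <- 0:(n - 1)
  ramp <- exp(2i * pi * (outer(sy * jx, rep(1, n)) +
                         outer(rep(1, n), sx * jx)) / n)
  obj_u <- complex_object(matrix(1, n, n), pixel_um = 0.4)
  obj_r <- complex_object(Mod(ramp), Arg(ramp), 0.4)
  st_tilt <- simulate_acquisition(obj_u, config, plan[m, ],
                                  acquisition_options(downsample_factor = 2))
  st_ramp <- simulate_acquisition(obj_r, config, on_axis_plan(plan),
                                  acquisition_options(downsample_factor = 2))
  expect_equal(st_tilt$images[[1]], st_ramp$images[[1]], tolerance = 1e-10)
})

test_that("dark-field images are dimmer than bright-field for a weak scatterer", {
  set.seed(9)
  n <- 64
  amp <- matrix(1, n, n); amp[20:40, 20:40] <- 0.9  # weakly absorbing patch
  obj <- complex_object(amp, pixel_um = 0.2)
  config <- matched_config(0.1, 4, 0.2, 2)
  plan <- illumination_plan(led_array(), 0.53)
  corner <- which.max(plan$sin_theta_x^2 + plan$sin_theta_y^2)
  st <- simulate_acquisition(obj, config, plan[c(1, corner), ],
                             acquisition_options(downsample_factor = 2))
  expect_lt(mean(st$images[[2]]), mean(st$images[[1]]))
})

test_that("noise is seed-deterministic and absent when disabled", {
  obj <- make_bandlimited_object(32, 0.4, 5, seed = 2)
  config <- matched_config(0.1, 4, 0.4, 2)
  plan <- on_axis_plan(illumination_plan(led_array(), 0.53))
  a <- simulate_acquisition(obj, config, plan,
        acquisition_options(downsample_factor = 2, noise = "gaussian",
                            noise_sigma = 0.05, seed = 11))
  b <- simulate_acquisition(obj, config, plan,
        acquisition_options(downsample_factor = 2, noise = "gaussian",
                            noise_sigma = 0.05, seed = 11))
  d <- simulate_acquisition(obj, config, plan,
        acquisition_options(downsample_factor = 2, noise = "gaussian",
                            noise_sigma = 0.05, seed = 12))
  clean <- simulate_acquisition(obj, config, plan,
        acquisition_options(downsample_factor = 2))
  expect_identical(a$images, b$images)
  expect_false(identical(a$images, d$images))
  expect_true(all(a$images[[1]] >= 0))
  clean2 <- simulate_acquisition(obj, config, plan,
        acquisition_options(downsample_factor = 2))
  expect_identical(clean$images, clean2$images)
  expect_error(acquisition_options(noise = "poisson"), "seed")
})

test_that("zero defocus reproduces the in-focus stack bit-exactly", {
  obj <- make_bandlimited_object(32, 0.4, 5, seed = 4)
  config <- matched_config(0.1, 4, 0.4, 2)
  plan <- illumination_plan(led_array(), 0.53)[1:5, ]
  a <- simulate_acquisition(obj, config, plan,
                            acquisition_options(downsample_factor = 2))
  b <- simulate_acquisition(obj, config, plan,
                            acquisition_options(downsample_factor = 2,
                                                defocus_um = 0))
  expect_identical(a$images, b$images)
})

test_that("bar contrast decays monotonically with defocus under low NA", {
  ph <- generate_usaf_phantom(groups = 6, elements = 6, pixel_um = 0.2,
                              shape = c(192, 192), orientations = "vertical")
  config <- matched_config(0.1, 4, 0.2, 4)
  plan <- on_axis_plan(illumination_plan(led_array(), 0.53))
  roi <- ph$truth[1, ]
  contrasts <- vapply(c(0, 5, 10, 20), function(z) {
    st <- simulate_acquisition(ph, config, plan,
            acquisition_options(downsample_factor = 4, defocus_um = z))
    bar_contrast(fpmicro:::bilinear_upsample(st$images[[1]], 4), roi,
                 ph$pixel_um)$contrast
  }, numeric(1))
  expect_true(all(diff(contrasts) <= 1e-9))
})
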