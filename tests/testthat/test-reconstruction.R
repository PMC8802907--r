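# Small shared stack for the state-level operation tests
recon_fixture <- local({
  pre <- fpm_preset("4x", object_pixel_um = 0.2, downsample_factor = 4)
  obj <- generate_chromosome_phantom(n_chromosomes = 2, shape = c(96, 96),
                                     pixel_um = 0.2, seed = 5)
  stack <- simulate_acquisition(obj, pre$config, pre$plan,
             acquisition_options(downsample_factor = 4,
                                 downsample_method = "sample"))
  list(pre = pre, obj = obj, stack = stack)
})

test_that("initialization holds one subregion per raw image and a delta spectrum for flat data", {
  st <- initialize_reconstruction(recon_fixture$stack)
  expect_equal(nrow(st$centers), length(recon_fixture$stack$images))
  expect_equal(anyDuplicated(st$centers[, c("cx", "cy")]), 0)

  # constant on-axis image -> all spectrum energy in the DC bin
  pre <- recon_fixture$pre
  flat <- complex_object(matrix(1, 64, 64), pixel_um = 0.2)
  stack1 <- simulate_acquisition(flat, pre$config, on_axis_plan(pre$plan),
              acquisition_options(downsample_factor = 4))
  s1 <- initialize_reconstruction(stack1, upsampling = 4)
  S <- Mod(s1$spectrum)
  dc <- floor(64 / 2) + 1
  expect_equal(sum(S) - S[dc, dc], 0, tolerance = 1e-8 * S[dc, dc])

  # too-small upsampling is refused
  expect_error(initialize_reconstruction(recon_fixture$stack, upsampling = 1),
               "upsampling")
})

test_that("forward subregion filters with the pupil and respects energy bounds", {
  st <- initialize_reconstruction(recon_fixture$stack)
  # Airy-like pattern: all-ones window times the binary pupil
  dcn <- floor(st$n / 2) + 1
  st$spectrum <- matrix(0 + 0i, st$n, st$n)
  w <- fpmicro:::window_indices(st, 1)
  st$spectrum[w$rows, w$cols] <- 1 + 0i
  fw <- forward_subregion(st, 1)
  # independent explicit inverse DFT of the pupil disk
  nl <- st$n_low
  q <- (1:nl) - (floor(nl / 2) + 1)
  jx <- 0:(nl - 1)
  Winv <- exp(2i * pi * outer(jx + 1 - (floor(nl / 2) + 1), q) / nl)
  ref <- (Winv %*% st$pupil %*% t(Winv)) / st$n^2
  expect_lt(max(Mod(fw$psi - ref)), 1e-8)
  # energy: |Psi| <= |window| since |P| <= 1
  expect_true(all(Mod(fw$Psi) <= 1 + 1e-12))
  # zero spectrum -> zero field
  st$spectrum[] <- 0 + 0i
  expect_true(all(Mod(forward_subregion(st, 1)$psi) == 0))
})

test_that("the intensity constraint replaces magnitudes exactly", {
  set.seed(1)
  psi <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  psi[1, 1] <- 0 + 0i
  Ip <- matrix(runif(64, 0, 2), 8, 8)
  phi <- intensity_constraint(psi, Ip)
  expect_equal(Mod(phi)^2, Ip, tolerance = 1e-14)
  # zero-magnitude pixels take the positive real root
  expect_equal(phi[1, 1], complex(real = sqrt(Ip[1, 1]), imaginary = 0))
  # fixed point when the model already matches
  psi2 <- psi; psi2[1, 1] <- 1 + 1i
  phi2 <- intensity_constraint(psi2, Mod(psi2)^2)
  expect_equal(phi2, psi2, tolerance = 1e-12)
  expect_error(intensity_constraint(psi, -Ip), "non-negative")
})

test_that("a converged subregion is left unchanged by the update", {
  st <- initialize_reconstruction(recon_fixture$stack)
  fw <- forward_subregion(st, 3)
  spec_before <- st$spectrum
  pupil_before <- st$pupil
  gauss_newton_update(st, 3, fw$psi)  # phi = psi -> dPsi = 0
  expect_equal(st$spectrum, spec_before, tolerance = 1e-12)
  expect_equal(st$pupil, pupil_before, tolerance = 1e-12)
})

test_that("the single-image bright-field case is solved in one sweep", {
  pre <- recon_fixture$pre
  obj <- recon_fixture$obj
  stack1 <- simulate_acquisition(obj, matched_config(0.1, 4, 0.2, 1),
              on_axis_plan(pre$plan),
              acquisition_options(downsample_factor = 1))
  state <- initialize_reconstruction(stack1, upsampling = 1,
             reconstruction_options(pupil_recovery = FALSE))
  n <- nrow(obj$amplitude)
  state$pupil <- matrix(1 + 0i, n, n)       # all-pass filter
  state$pupil_mask <- matrix(TRUE, n, n)
  fw <- forward_subregion(state, 1)
  phi <- intensity_constraint(fw$psi, stack1$images[[1]])
  gauss_newton_update(state, 1, phi)
  amp <- Mod(fpmicro:::cifft2(state$spectrum))
  expect_equal(amp, sqrt(stack1$images[[1]]), tolerance = 1e-10)
})

test_that("residuals are non-increasing on noiseless data with a known pupil", {
  rec <- fpm_reconstruct(recon_fixture$stack,
           options = reconstruction_options(max_iterations = 10, tolerance = 0,
                                            pupil_recovery = FALSE))
  expect_gte(length(rec$residual_history), 10)
  expect_true(all(diff(rec$residual_history) <= 1e-12))
})

test_that("reconstruction is shift-equivariant", {
  pre <- recon_fixture$pre
  obj <- recon_fixture$obj
  obj2 <- complex_object(circ_shift(obj$amplitude, 8, 16),
                         circ_shift(obj$phase, 8, 16), obj$pixel_um)
  opts <- acquisition_options(downsample_factor = 4,
                              downsample_method = "sample")
  ropt <- reconstruction_options(max_iterations = 8, tolerance = 0)
  r1 <- fpm_reconstruct(simulate_acquisition(obj, pre$config, pre$plan, opts),
                        options = ropt)
  r2 <- fpm_reconstruct(simulate_acquisition(obj2, pre$config, pre$plan, opts),
                        options = ropt)
  expect_lt(max(abs(circ_shift(r1$amplitude, 8, 16) - r2$amplitude)), 1e-8)
})

test_that("the reported phase uses the brightest-pixel piston gauge", {
  rec <- fpm_reconstruct(recon_fixture$stack,
           options = reconstruction_options(max_iterations = 3))
  expect_equal(rec$phase[which.max(rec$amplitude)], 0)
  expect_true(all(rec$amplitude >= 0))
})

test_that("non-finite measurements abort with a diagnostic", {
  bad <- recon_fixture$stack
  bad$images[[2]][1, 1] <- NaN
  expect_error(fpm_reconstruct(bad, options = reconstruction_options(
    max_iterations = 2)), "non-finite")
})
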