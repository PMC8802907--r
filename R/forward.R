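# Coherent oblique-illumination forward model. Illuminating a thin sample
# s(x) with a tilted plane wave of transverse wave vector k_m shifts its
# spectrum to S(k - k_m); the objective passes the circular pupil band and
# the camera records |field|^2 at its own (coarser) sampling. Illumination
# wave vectors are rounded to the reconstruction frequency grid (integer
# spectrum-pixel shifts), the standard FPM discretization; the rounding
# residual is recorded with the stack.

#' Acquisition options for the forward simulation
#'
#' @param downsample_factor Integer ratio between the high-resolution object
#'   grid and the camera grid (>= 1; must divide the object shape).
#' @param defocus_um Sample defocus in micrometres, applied identically for
#'   every LED through the pupil phase.
#' @param noise `"none"` (default), `"gaussian"` (additive, sd
#'   `noise_sigma`) or `"poisson"` (shot noise at `photon_scale` expected
#'   photons per unit intensity).
#' @param noise_sigma Gaussian noise standard deviation (intensity units).
#' @param photon_scale Photons per unit intensity for Poisson noise.
#' @param seed Integer seed used for the noise draw; `NULL` only when
#'   `noise = "none"`.
#' @param downsample_method `"box"` (default) box-averages the
#'   high-resolution intensity over camera pixels, modelling pixel
#'   integration; `"sample"` takes the band-limited field directly at the
#'   camera sampling (the measurement model the reconstruction itself
#'   assumes — use it for algorithm-consistency experiments).
#' @return A list of class `"acquisition_options"`.
#' @export
acquisition_options <- function(downsample_factor = 4, defocus_um = 0,
                                noise = c("none", "gaussian", "poisson"),
                                noise_sigma = 0.01, photon_scale = 1e4,
                                seed = NULL,
                                downsample_method = c("box", "sample")) {
  noise <- match.arg(noise)
  downsample_method <- match.arg(downsample_method)
  stopifnot(downsample_factor >= 1, downsample_factor == round(downsample_factor))
  if (noise != "none" && is.null(seed)) {
    stop("a seed is required when noise is enabled")
  }
  structure(list(downsample_factor = as.integer(downsample_factor),
                 defocus_um = defocus_um, noise = noise,
                 noise_sigma = noise_sigma, photon_scale = photon_scale,
                 seed = seed, downsample_method = downsample_method),
            class = "acquisition_options")
}

# Integer spectrum-pixel centers for each plan entry, plus rounding residual.
# Returns a data frame with cx, cy (signed pixel offsets of the sampled
# subregion center, i.e. -round(k_m / dk)) and the residuals in rad/um.
#' @noRd
plan_pixel_centers <- function(plan, dk) {
  sx <- round(plan$kx_per_um / dk)
  sy <- round(plan$ky_per_um / dk)
  data.frame(led_index = plan$led_index,
             cx = -as.integer(sx), cy = -as.integer(sy),
             residual_kx = plan$kx_per_um - sx * dk,
             residual_ky = plan$ky_per_um - sy * dk)
}

#' Simulate a Fourier ptychography acquisition
#'
#' For every LED of the illumination plan, shifts the object spectrum by the
#' LED wave vector, applies the (possibly defocused) pupil low-pass, forms
#' the intensity image at the camera sampling and optionally adds noise.
#' Exposure is normalized so an on-axis bright-field image of a clear
#' (unit-transmission) sample has mean intensity 1.
#'
#' @param object A [complex_object()] on a square grid whose side is
#'   divisible by `options$downsample_factor`.
#' @param config An [optical_system()]. Its object-plane camera sampling
#'   should equal `object$pixel_um * downsample_factor` (a mismatch beyond
#'   0.1% triggers a warning).
#' @param plan An [illumination_plan()].
#' @param options An [acquisition_options()].
#' @return An object of class `"raw_stack"`: list with `images` (list of
#'   camera-sampling intensity matrices, plan order), `plan`, `config`,
#'   `options`, `object_pixel_um` (high-resolution grid), `centers`
#'   (integer spectrum shifts with rounding residuals) and `seed`.
#' @examples
#' pre <- fpm_preset("4x")
#' obj <- complex_object(matrix(1, 64, 64), pixel_um = 0.2)
#' st <- simulate_acquisition(obj, pre$config,
#'                            pre$plan[pre$plan$row == 0 & pre$plan$col == 0, ],
#'                            acquisition_options(downsample_factor = 2))
#' mean(st$images[[1]])  # ~1: clear-field normalization
#' @export
simulate_acquisition <- function(object, config, plan,
                                 options = acquisition_options()) {
  stopifnot(inherits(object, "complex_object"),
            inherits(config, "optical_system"),
            is.data.frame(plan),
            inherits(options, "acquisition_options"))
  n <- nrow(object$amplitude)
  if (ncol(object$amplitude) != n) stop("object must be square")
  f <- options$downsample_factor
  if (n %% f != 0) stop("downsample_factor must divide the object side")
  n_low <- n %/% f
  p <- object$pixel_um
  lam <- config$wavelength_um

  cam_obj_px <- config$camera_pixel_um / config$effective_magnification
  if (abs(cam_obj_px - p * f) / (p * f) > 1e-3) {
    warning(sprintf(paste0("camera sampling at the object plane (%.4g um) does not ",
                           "match object pixel x downsample (%.4g um)"),
                    cam_obj_px, p * f))
  }
  # Nyquist advisory for the synthesized band
  na_ill <- max(sqrt(plan$sin_theta_x^2 + plan$sin_theta_y^2))
  if (p > lam / (2 * (config$objective_na + na_ill))) {
    warning(sprintf(paste0("object pixel %.3g um undersamples the synthesized band ",
                           "(recommended <= %.3g um)"),
                    p, lam / (2 * (config$objective_na + na_ill))))
  }

  dk <- 2 * pi / (n * p)
  centers <- plan_pixel_centers(plan, dk)
  s <- as_complex_field(object)
  S <- cfft2(s)

  if (options$downsample_method == "sample") {
    pupil <- make_pupil(c(n_low, n_low), dk, config$objective_na, lam,
                        options$defocus_um)
    dc <- dc_index(n)
    half_lo <- dc_index(n_low) - 1L
    lo <- -(half_lo)
    hi <- n_low - half_lo - 1L
    if (any(dc + centers$cy + lo < 1 | dc + centers$cy + hi > n |
            dc + centers$cx + lo < 1 | dc + centers$cx + hi > n)) {
      stop("an illumination subregion falls outside the object spectrum; enlarge the object grid")
    }
    images <- lapply(seq_len(nrow(centers)), function(i) {
      rows <- (dc + centers$cy[i] + lo):(dc + centers$cy[i] + hi)
      cols <- (dc + centers$cx[i] + lo):(dc + centers$cx[i] + hi)
      psi <- cifft2(S[rows, cols] * pupil$array) * (n_low^2 / n^2)
      Mod(psi)^2
    })
  } else {
    pupil <- make_pupil(c(n, n), dk, config$objective_na, lam,
                        options$defocus_um)
    images <- lapply(seq_len(nrow(centers)), function(i) {
      # spectrum shifted so that S(k - k_m): content moves by +round(k_m/dk)
      Ssh <- circular_shift(S, -centers$cy[i], -centers$cx[i])
      field <- cifft2(Ssh * pupil$array)
      box_downsample(Mod(field)^2, f)
    })
  }

  if (options$noise != "none") {
    images <- with_seed(options$seed, {
      lapply(images, function(I) {
        if (options$noise == "gaussian") {
          pmax(I + stats::rnorm(length(I), 0, options$noise_sigma), 0)
        } else {
          matrix(stats::rpois(length(I), pmax(I, 0) * options$photon_scale) /
                   options$photon_scale, nrow(I), ncol(I))
        }
      })
    })
  }

  structure(list(images = images, plan = plan, config = config,
                 options = options, object_pixel_um = p,
                 centers = centers, seed = options$seed),
            class = "raw_stack")
}

# Circularly shift a matrix by (dy, dx): element [i, j] moves to
# [i + dy, j + dx] (wrapped).
#' @noRd
circular_shift <- function(x, dy, dx) {
  n1 <- nrow(x); n2 <- ncol(x)
  i <- ((seq_len(n1) - 1 - dy) %% n1) + 1
  j <- ((seq_len(n2) - 1 - dx) %% n2) + 1
  x[i, j, drop = FALSE]
}

#' @export
print.raw_stack <- function(x, ...) {
  cat(sprintf("Raw FPM stack: %d images of %d x %d px (camera), object grid %d px at %.3g um\n",
              length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]),
              nrow(x$images[[1]]) * x$options$downsample_factor,
              x$object_pixel_um))
  cat(sprintf("  %gx/%.2f NA, defocus %g um, noise %s, downsampling %s (factor %d)\n",
              x$config$nominal_magnification, x$config$objective_na,
              x$options$defocus_um, x$options$noise,
              x$options$downsample_method, x$options$downsample_factor))
  invisible(x)
}

#' Brute-force forward model (direct-DFT oracle)
#'
#' Computes the same physics as [simulate_acquisition()] for a single LED by
#' explicit DFT matrix products (the double sum written out; no FFT
#' involved): modulate the object by the tilted plane wave rounded to the
#' frequency grid, transform, apply the full-grid pupil, inverse transform,
#' square, box-downsample. Quartic cost; refuses objects larger than 64x64.
#'
#' This function exists as an independent cross-check of the FFT pipeline
#' and is deliberately kept free of shared spectral plumbing.
#'
#' @param object A square [complex_object()] of side <= 64.
#' @param config An [optical_system()].
#' @param k_m Numeric length-2 vector `c(kx, ky)` in rad/um.
#' @param downsample_factor Integer camera downsampling factor.
#' @param defocus_um Defocus in micrometres.
#' @return The camera-sampling intensity matrix.
#' @export
brute_force_forward <- function(object, config, k_m, downsample_factor = 1,
                                defocus_um = 0) {
  stopifnot(inherits(object, "complex_object"), length(k_m) == 2)
  n <- nrow(object$amplitude)
  if (ncol(object$amplitude) != n) stop("object must be square")
  if (n > 64) stop("brute_force_forward is limited to objects up to 64x64")
  p <- object$pixel_um
  lam <- config$wavelength_um
  dk <- 2 * pi / (n * p)

  # tilted illumination rounded to the frequency grid
  sx <- round(k_m[1] / dk); sy <- round(k_m[2] / dk)
  jx <- 0:(n - 1)
  ramp <- exp(2i * pi * (outer(sy * jx, rep(1, n)) +
                         outer(rep(1, n), sx * jx)) / n)
  t_field <- as_complex_field(object) * ramp

  # explicit centered DFT matrices (rows act on y, cols on x)
  q <- centered_freqs(n)
  W <- exp(-2i * pi * outer(q, jx) / n)     # [freq, space]
  S <- W %*% t_field %*% t(W)

  # full-grid pupil, built per-pixel from first principles
  k_na <- 2 * pi * config$objective_na / lam
  k2 <- outer((q * dk)^2, (q * dk)^2, `+`)
  P <- matrix(0 + 0i, n, n)
  inside <- k2 <= k_na^2
  if (defocus_um == 0) {
    P[inside] <- 1
  } else {
    P[inside] <- exp(1i * defocus_um * sqrt((2 * pi / lam)^2 - k2[inside]))
  }

  Winv <- Conj(W)                            # inverse DFT matrices
  field <- (t(Winv) %*% (S * P) %*% Winv) / n^2
  box_downsample(Mod(field)^2, downsample_factor)
}
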