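# Iterative Fourier-ptychography reconstruction with embedded pupil
# recovery. The high-resolution spectrum is divided into one circular
# subregion per LED; each sweep visits every subregion and applies three
# steps: (1) filter the windowed spectrum with the current pupil and
# inverse-transform to the low-resolution field, (2) replace the field
# magnitude with the square root of the measured intensity (keeping the
# phase), (3) update both the spectrum window and the pupil by regularized
# Gauss-Newton steps driven by the frequency-domain mismatch (the EPRY
# update). Sweeps repeat until the relative residual change drops below
# tolerance or the sweep budget is exhausted.

#' Reconstruction options
#'
#' @param max_iterations Maximum number of full sweeps over all subregions
#'   (default 50).
#' @param tolerance Relative change of the data residual between consecutive
#'   sweeps below which iteration stops (default 1e-4).
#' @param ordering Subregion traversal order: `"spiral"` visits subregions
#'   by increasing |k_m| (bright field first, the usual convention);
#'   `"raster"` follows the stored plan order.
#' @param delta1,delta2 Gauss-Newton regularizers for the spectrum and pupil
#'   steps. `NULL` (default) uses `1e-8 * max(|.|^2)` of the respective
#'   divisor, recomputed per update.
#' @param pupil_recovery Logical: jointly update the pupil (default `TRUE`).
#' @return A list of class `"reconstruction_options"`.
#' @export
reconstruction_options <- function(max_iterations = 50, tolerance = 1e-4,
                                   ordering = c("spiral", "raster"),
                                   delta1 = NULL, delta2 = NULL,
                                   pupil_recovery = TRUE) {
  ordering <- match.arg(ordering)
  stopifnot(max_iterations >= 1, tolerance >= 0)
  if (!is.null(delta1)) stopifnot(delta1 > 0)
  if (!is.null(delta2)) stopifnot(delta2 > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, ordering = ordering,
                 delta1 = delta1, delta2 = delta2,
                 pupil_recovery = isTRUE(pupil_recovery)),
            class = "reconstruction_options")
}

#' Initialize the reconstruction state
#'
#' Builds the working state: the high-resolution spectrum estimate (Fourier
#' transform of the bilinearly upsampled square root of the on-axis
#' intensity image, with zero phase), the ideal pupil for the configured
#' objective, and the integer spectrum-window centers (one per LED).
#'
#' @param stack A `raw_stack` from [simulate_acquisition()] or
#'   [read_stack()].
#' @param upsampling Integer ratio of the reconstruction grid to the camera
#'   grid. Defaults to the stack's acquisition `downsample_factor`. Must be
#'   large enough that every subregion window (center offset plus pupil
#'   half-width) fits inside the reconstruction spectrum.
#' @param options A [reconstruction_options()].
#' @return An environment of class `"fpm_state"` with fields `spectrum`,
#'   `pupil` (complex matrix), `pupil_mask`, `centers`, `images`,
#'   `iteration`, `residual_history` and grid bookkeeping.
#' @export
initialize_reconstruction <- function(stack, upsampling = NULL,
                                      options = reconstruction_options()) {
  stopifnot(inherits(stack, "raw_stack"),
            inherits(options, "reconstruction_options"))
  n_low <- nrow(stack$images[[1]])
  if (any(vapply(stack$images, function(m) !all(dim(m) == n_low), logical(1)))) {
    stop("all raw images must be square and identically sized")
  }
  if (length(stack$images) != nrow(stack$plan)) {
    stop("stack/plan mismatch: image count differs from plan entries")
  }
  if (any(vapply(stack$images, function(m) any(!is.finite(m)), logical(1)))) {
    stop("non-finite values in the raw stack; reconstruction aborted")
  }
  if (is.null(upsampling)) upsampling <- stack$options$downsample_factor
  upsampling <- as.integer(upsampling)
  stopifnot(upsampling >= 1)
  n <- n_low * upsampling
  p_high <- stack$object_pixel_um * stack$options$downsample_factor / upsampling
  dk <- 2 * pi / (n * p_high)
  lam <- stack$config$wavelength_um

  centers <- plan_pixel_centers(stack$plan, dk)
  pupil <- make_pupil(c(n_low, n_low), dk, stack$config$objective_na, lam)
  r_px <- 2 * pi * stack$config$objective_na / lam / dk
  max_off <- max(abs(c(centers$cx, centers$cy)))
  if (max_off + dc_index(n_low) - 1 > floor(n / 2)) {
    stop(sprintf(paste0("upsampling %d is too small: the outermost subregion ",
                        "(offset %d px + window half-width %d px) exceeds the ",
                        "spectrum half-width %d px"),
                 upsampling, max_off, dc_index(n_low) - 1, floor(n / 2)))
  }

  # ordering of subregion visits
  visit <- switch(options$ordering,
    spiral = order(stack$plan$sin_theta_x^2 + stack$plan$sin_theta_y^2,
                   atan2(stack$plan$ky_per_um, stack$plan$kx_per_um)),
    raster = seq_len(nrow(stack$plan))
  )

  on_axis <- which.min(stack$plan$sin_theta_x^2 + stack$plan$sin_theta_y^2)
  amp0 <- bilinear_upsample(sqrt(pmax(stack$images[[on_axis]], 0)), upsampling)

  st <- new.env(parent = emptyenv())
  st$spectrum <- cfft2(amp0 + 0i)
  st$pupil <- pupil$array
  st$pupil_mask <- pupil$mask
  st$pupil_meta <- pupil
  st$centers <- centers
  st$images <- stack$images
  st$visit <- visit
  st$n <- n; st$n_low <- n_low; st$dk <- dk
  st$pixel_um <- p_high
  st$config <- stack$config
  st$options <- options
  st$iteration <- 0L
  st$residual_history <- numeric(0)
  class(st) <- "fpm_state"
  st
}

# window row/col index ranges for subregion m
#' @noRd
window_indices <- function(state, m) {
  dc <- dc_index(state$n)
  half <- dc_index(state$n_low) - 1L
  lo <- -half; hi <- state$n_low - half - 1L
  list(rows = (dc + state$centers$cy[m] + lo):(dc + state$centers$cy[m] + hi),
       cols = (dc + state$centers$cx[m] + lo):(dc + state$centers$cx[m] + hi))
}

#' Forward step for one subregion
#'
#' Extracts the pupil-sized spectrum window of subregion `m`, multiplies by
#' the current pupil and inverse-transforms to the modelled low-resolution
#' field.
#'
#' @param state An `"fpm_state"` from [initialize_reconstruction()].
#' @param m Subregion (LED) index, in plan order.
#' @return List with `Psi` (filtered spectrum window) and `psi` (complex
#'   low-resolution field).
#' @export
forward_subregion <- function(state, m) {
  stopifnot(inherits(state, "fpm_state"), m >= 1, m <= nrow(state$centers))
  w <- window_indices(state, m)
  Psi <- state$spectrum[w$rows, w$cols] * state$pupil
  psi <- cifft2(Psi) * (state$n_low^2 / state$n^2)
  list(Psi = Psi, psi = psi)
}

#' Apply the measured-intensity constraint
#'
#' Replaces the magnitude of the modelled field with the square root of the
#' measured intensity while keeping its phase:
#' `phi = sqrt(Ip) * psi / |psi|`. Where `|psi| = 0` the phase factor is
#' taken as 1, so `phi = sqrt(Ip)` there.
#'
#' @param psi Complex modelled field.
#' @param Ip Measured intensity matrix (non-negative, same shape).
#' @return The constrained complex field, satisfying `|phi|^2 == Ip`
#'   elementwise.
#' @export
intensity_constraint <- function(psi, Ip) {
  stopifnot(all(dim(psi) == dim(Ip)))
  if (any(Ip < 0)) stop("measured intensities must be non-negative")
  mag <- Mod(psi)
  unit <- psi / mag
  unit[mag == 0] <- 1 + 0i
  sqrt(Ip) * unit
}

#' Gauss-Newton update of the spectrum window and pupil
#'
#' Given the constrained field of subregion `m`, forms the frequency-domain
#' mismatch `dPsi = Phi - Psi` and applies the regularized Gauss-Newton
#' (EPRY-style) steps: the spectrum window moves along `conj(P)` and the
#' pupil along the conjugate of the pre-update window, each scaled by
#' `|.| / (max|.| * (|.|^2 + delta))`. The pupil is re-clipped to its ideal
#' disk support after every update; the state is modified in place.
#'
#' @param state An `"fpm_state"`.
#' @param m Subregion index.
#' @param phi Constrained complex field from [intensity_constraint()].
#' @return The updated state, invisibly.
#' @export
gauss_newton_update <- function(state, m, phi) {
  stopifnot(inherits(state, "fpm_state"))
  w <- window_indices(state, m)
  W_old <- state$spectrum[w$rows, w$cols]
  P <- state$pupil
  Psi <- W_old * P
  Phi <- cfft2(phi) * (state$n^2 / state$n_low^2)
  dPsi <- Phi - Psi

  absP <- Mod(P)
  d1 <- state$options$delta1
  if (is.null(d1)) d1 <- 1e-8 * max(absP)^2
  stepW <- Conj(P) * absP / (max(absP) * (absP^2 + d1))
  state$spectrum[w$rows, w$cols] <- W_old + stepW * dPsi

  if (state$options$pupil_recovery) {
    absW <- Mod(W_old)
    d2 <- state$options$delta2
    if (is.null(d2)) d2 <- 1e-8 * max(absW)^2
    stepP <- Conj(W_old) * absW / (max(absW) * (absW^2 + d2))
    Pnew <- P + stepP * dPsi
    Pnew[!state$pupil_mask] <- 0
    state$pupil <- Pnew
  }
  invisible(state)
}

#' Reconstruct a high-resolution complex image from an FPM stack
#'
#' Runs full sweeps of forward filtering, intensity constraint and
#' Gauss-Newton updates over all spectrum subregions until the relative
#' residual change falls below `options$tolerance` or
#' `options$max_iterations` sweeps have run. The per-sweep data residual is
#' `sqrt(sum_m sum_r (|psi_m| - sqrt(I_m))^2 / sum_m sum_r I_m)`, evaluated
#' as each subregion is visited.
#'
#' The result phase is reported in the piston gauge: the phase at the
#' brightest amplitude pixel is subtracted, so outputs are comparable
#' across runs (a global phase is unobservable from intensities).
#'
#' @param stack A `raw_stack`.
#' @param upsampling Integer reconstruction upsampling (see
#'   [initialize_reconstruction()]).
#' @param options A [reconstruction_options()].
#' @return An object of class `"fpm_reconstruction"`: list with `amplitude`,
#'   `phase` (radians), `field` (complex image), `pupil` (recovered
#'   [make_pupil()]-style object), `residual_history`, `iterations`,
#'   `pixel_um` and an echo of `options`.
#' @examples
#' pre <- fpm_preset("4x")
#' obj <- generate_chromosome_phantom(2, shape = c(64, 64), seed = 3)
#' plan9 <- pre$plan[abs(pre$plan$row) <= 1 & abs(pre$plan$col) <= 1, ]
#' st <- simulate_acquisition(obj, pre$config, plan9,
#'                            acquisition_options(downsample_factor = 2))
#' rec <- fpm_reconstruct(st, options = reconstruction_options(max_iterations = 5))
#' @export
fpm_reconstruct <- function(stack, upsampling = NULL,
                            options = reconstruction_options()) {
  state <- initialize_reconstruction(stack, upsampling, options)
  N <- nrow(state$centers)
  prev <- Inf
  for (it in seq_len(options$max_iterations)) {
    num <- 0; den <- 0
    for (m in state$visit) {
      fw <- forward_subregion(state, m)
      Ip <- state$images[[m]]
      num <- num + sum((Mod(fw$psi) - sqrt(Ip))^2)
      den <- den + sum(Ip)
      phi <- intensity_constraint(fw$psi, Ip)
      gauss_newton_update(state, m, phi)
    }
    res <- sqrt(num / den)
    if (!is.finite(res)) stop("non-finite residual encountered; reconstruction aborted")
    state$iteration <- it
    state$residual_history <- c(state$residual_history, res)
    if (is.finite(prev) && prev > 0 &&
        abs(prev - res) / prev < options$tolerance) break
    prev <- res
  }

  field <- cifft2(state$spectrum)
  amp <- Mod(field)
  piston <- Arg(field[which.max(amp)])
  field <- field * exp(-1i * piston)
  pupil <- state$pupil_meta
  pupil$array <- state$pupil

  structure(list(amplitude = Mod(field), phase = Arg(field), field = field,
                 pupil = pupil, residual_history = state$residual_history,
                 iterations = state$iteration, pixel_um = state$pixel_um,
                 options = options),
            class = "fpm_reconstruction")
}

#' @export
print.fpm_reconstruction <- function(x, ...) {
  cat(sprintf("FPM reconstruction: %d x %d px at %.3g um/px\n",
              nrow(x$amplitude), ncol(x$amplitude), x$pixel_um))
  cat(sprintf("  %d sweeps, final residual %.4g (pupil recovery %s)\n",
              x$iterations, utils::tail(x$residual_history, 1),
              if (x$options$pupil_recovery) "on" else "off"))
  invisible(x)
}
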