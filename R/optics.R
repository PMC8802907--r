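# Optical bookkeeping for an LED-array Fourier ptychography microscope:
# system configuration, illumination geometry, wave vectors, NA arithmetic
# and the standard USAF 1951 / Rayleigh conversions shared by every other
# part of the package.

#' Optical system configuration
#'
#' Bundles the objective and camera parameters of the microscope and derives
#' the object-plane pixel size. This object is the single source of truth
#' for scale conversions throughout the package.
#'
#' @param objective_na Numerical aperture of the objective (0 < NA < 1).
#' @param nominal_magnification Nominal magnification engraved on the
#'   objective (e.g. 4 or 10).
#' @param tube_focal_length_mm Focal length of the tube lens actually
#'   mounted, in mm. Default 150.
#' @param reference_focal_length_mm Reference tube focal length the
#'   objective was designed for, in mm; 180 is the Olympus infinity-corrected
#'   standard. The effective magnification is
#'   `nominal_magnification * tube_focal_length_mm / reference_focal_length_mm`.
#' @param wavelength_um Illumination wavelength in micrometres. Default 0.53
#'   (green LED).
#' @param camera_pixel_um Physical camera pixel pitch in micrometres.
#' @return An object of class `"optical_system"`: a list with the above
#'   fields plus `effective_magnification` and `object_pixel_um`
#'   (`camera_pixel_um / effective_magnification`, the camera sampling
#'   referred to the object plane).
#' @examples
#' optical_system(0.1, 4)
#' @export
optical_system <- function(objective_na,
                           nominal_magnification,
                           tube_focal_length_mm = 150,
                           reference_focal_length_mm = 180,
                           wavelength_um = 0.53,
                           camera_pixel_um = 2.4) {
  stopifnot(is.numeric(objective_na), length(objective_na) == 1)
  if (!(objective_na > 0 && objective_na < 1)) {
    stop("objective_na must lie strictly between 0 and 1")
  }
  for (v in c(nominal_magnification, tube_focal_length_mm,
              reference_focal_length_mm, wavelength_um, camera_pixel_um)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("all optical lengths and magnifications must be positive finite numbers")
    }
  }
  mag <- effective_magnification(nominal_magnification, tube_focal_length_mm,
                                 reference_focal_length_mm)
  structure(list(
    objective_na = objective_na,
    nominal_magnification = nominal_magnification,
    tube_focal_length_mm = tube_focal_length_mm,
    reference_focal_length_mm = reference_focal_length_mm,
    wavelength_um = wavelength_um,
    camera_pixel_um = camera_pixel_um,
    effective_magnification = mag,
    object_pixel_um = camera_pixel_um / mag
  ), class = "optical_system")
}

#' @export
print.optical_system <- function(x, ...) {
  cat(sprintf("Optical system: %gx/%.2f NA objective\n",
              x$nominal_magnification, x$objective_na))
  cat(sprintf("  tube lens %g mm (reference %g mm) -> effective magnification %.4g\n",
              x$tube_focal_length_mm, x$reference_focal_length_mm,
              x$effective_magnification))
  cat(sprintf("  wavelength %.3g um, camera pixel %.3g um (%.4g um at object plane)\n",
              x$wavelength_um, x$camera_pixel_um, x$object_pixel_um))
  invisible(x)
}

#' Effective magnification of an infinity-corrected objective
#'
#' An infinity-corrected objective rated `M`x for a reference tube focal
#' length `f_ref` delivers `M * f_tube / f_ref` when used with a tube lens of
#' focal length `f_tube`. A 4x Olympus objective (reference 180 mm) behind a
#' 150 mm tube lens therefore magnifies by about 3.3x.
#'
#' @param nominal_mag Nominal magnification (dimensionless, > 0).
#' @param tube_mm Tube lens focal length in mm (> 0).
#' @param reference_mm Reference focal length in mm (> 0); 180 for Olympus.
#' @return Effective magnification (dimensionless).
#' @examples
#' effective_magnification(4, 150, 180)   # ~3.33
#' effective_magnification(10, 150, 180)  # ~8.33
#' @export
effective_magnification <- function(nominal_mag, tube_mm, reference_mm = 180) {
  if (any(!is.finite(nominal_mag)) || any(nominal_mag <= 0) ||
      any(!is.finite(tube_mm)) || any(tube_mm <= 0) ||
      any(!is.finite(reference_mm)) || any(reference_mm <= 0)) {
    stop("nominal_mag, tube_mm and reference_mm must all be positive")
  }
  nominal_mag * tube_mm / reference_mm
}

#' LED array geometry
#'
#' Describes the planar LED panel used for angle-varied illumination: the
#' full grid, the centered sub-grid actually switched on, the LED pitch and
#' the vertical distance from the panel to the sample.
#'
#' @param grid_rows,grid_cols Full panel dimensions (counts).
#' @param pitch_mm Center-to-center LED spacing in mm.
#' @param stage_distance_mm Vertical LED-panel-to-sample distance in mm.
#' @param used_rows,used_cols Dimensions of the centered sub-grid actually
#'   used for acquisition; must be odd (so an on-axis LED exists) and fit
#'   inside the full grid.
#' @return An object of class `"led_array"`.
#' @examples
#' led_array()  # the 32x32 panel with a 15x15 centered sub-grid
#' @export
led_array <- function(grid_rows = 32, grid_cols = 32, pitch_mm = 4,
                      stage_distance_mm = 70, used_rows = 15, used_cols = 15) {
  stopifnot(pitch_mm > 0, stage_distance_mm > 0,
            grid_rows >= 1, grid_cols >= 1, used_rows >= 1, used_cols >= 1)
  if (used_rows > grid_rows || used_cols > grid_cols) {
    stop("used sub-grid must fit inside the full LED grid")
  }
  if (used_rows %% 2 == 0 || used_cols %% 2 == 0) {
    stop("used_rows and used_cols must be odd so that an on-axis LED exists")
  }
  structure(list(
    grid_rows = grid_rows, grid_cols = grid_cols,
    pitch_mm = pitch_mm, stage_distance_mm = stage_distance_mm,
    used_rows = used_rows, used_cols = used_cols
  ), class = "led_array")
}

#' Illumination wave vector of an off-axis LED
#'
#' An LED at lateral position (x, y) mm, a distance `z` mm below the sample,
#' illuminates with direction sines `sin(theta_x) = x / sqrt(x^2+y^2+z^2)`
#' (and symmetrically in y). The transverse wave vector is
#' `k = 2 * pi * sin(theta) / lambda`. An LED at +x gives `kx > 0`; the raw
#' image for that LED samples the object-spectrum disk centered at `-k`
#' (see `simulate_acquisition()`).
#'
#' @param x_mm,y_mm Lateral LED offsets from the optical axis in mm
#'   (vectorized).
#' @param distance_mm Panel-to-sample distance in mm (> 0).
#' @param wavelength_um Wavelength in micrometres (> 0).
#' @return A list with components `kx_per_um`, `ky_per_um` (rad/um) and the
#'   direction sines `sin_theta_x`, `sin_theta_y`.
#' @examples
#' wavevector_for_led(28, 0, 70, 0.53)  # kx ~ 4.40 rad/um
#' @export
wavevector_for_led <- function(x_mm, y_mm, distance_mm, wavelength_um) {
  if (any(distance_mm <= 0)) stop("distance_mm must be > 0")
  if (any(wavelength_um <= 0)) stop("wavelength_um must be > 0")
  r <- sqrt(x_mm^2 + y_mm^2 + distance_mm^2)
  sx <- x_mm / r
  sy <- y_mm / r
  list(kx_per_um = 2 * pi * sx / wavelength_um,
       ky_per_um = 2 * pi * sy / wavelength_um,
       sin_theta_x = sx, sin_theta_y = sy)
}

#' Illumination plan for an LED array
#'
#' Enumerates the used LEDs of an array with their lateral positions and
#' transverse wave vectors, ordered for reconstruction. The default
#' `"spiral"` rule orders LEDs by increasing illumination angle (bright
#' field first, the usual Fourier-ptychography update order); `"raster"`
#' is row-major.
#'
#' @param geometry An [led_array()] object.
#' @param wavelength_um Wavelength in micrometres.
#' @param ordering `"spiral"` (by |k|, then angle) or `"raster"`.
#' @return A data frame of class `"illumination_plan"` with one row per LED:
#'   `led_index`, `row`, `col` (signed grid offsets), `x_mm`, `y_mm`,
#'   `sin_theta_x`, `sin_theta_y`, `kx_per_um`, `ky_per_um`. Attributes
#'   `ordering_rule`, `geometry` and `wavelength_um` record provenance.
#' @examples
#' plan <- illumination_plan(led_array(), 0.53)
#' head(plan)
#' @export
illumination_plan <- function(geometry, wavelength_um = 0.53,
                              ordering = c("spiral", "raster")) {
  stopifnot(inherits(geometry, "led_array"))
  ordering <- match.arg(ordering)
  hr <- (geometry$used_rows - 1) / 2
  hc <- (geometry$used_cols - 1) / 2
  g <- expand.grid(row = -hr:hr, col = -hc:hc)
  x <- g$col * geometry$pitch_mm
  y <- g$row * geometry$pitch_mm
  k <- wavevector_for_led(x, y, geometry$stage_distance_mm, wavelength_um)
  plan <- data.frame(
    led_index = seq_len(nrow(g)),
    row = g$row, col = g$col, x_mm = x, y_mm = y,
    sin_theta_x = k$sin_theta_x, sin_theta_y = k$sin_theta_y,
    kx_per_um = k$kx_per_um, ky_per_um = k$ky_per_um
  )
  ord <- switch(ordering,
    spiral = order(plan$sin_theta_x^2 + plan$sin_theta_y^2,
                   atan2(plan$ky_per_um, plan$kx_per_um)),
    raster = order(plan$row, plan$col)
  )
  plan <- plan[ord, ]
  plan$led_index <- seq_len(nrow(plan))
  rownames(plan) <- NULL
  structure(plan,
            ordering_rule = ordering,
            geometry = geometry,
            wavelength_um = wavelength_um,
            class = c("illumination_plan", "data.frame"))
}

#' Illumination numerical aperture of an LED array
#'
#' The largest direction sine reached by the used LEDs. Bar-target
#' resolution is set by the band extension along the bar normal, so the
#' default reports the axis-aligned maximum (largest `|sin theta|` along a
#' grid axis); `which = "diagonal"` reports the overall maximum
#' `sqrt(sin^2 theta_x + sin^2 theta_y)`, reached at a corner LED.
#'
#' For the 15x15, 4 mm pitch, 70 mm geometry the axis-aligned value is
#' 28 / sqrt(28^2 + 70^2) = 0.3714.
#'
#' @param geometry An [led_array()] object.
#' @param which `"axis"` (default) or `"diagonal"`.
#' @return Dimensionless illumination NA.
#' @export
illumination_na <- function(geometry, which = c("axis", "diagonal")) {
  stopifnot(inherits(geometry, "led_array"))
  which <- match.arg(which)
  if (geometry$used_rows < 1 || geometry$used_cols < 1) {
    stop("empty illumination plan")
  }
  z <- geometry$stage_distance_mm
  hx <- (geometry$used_cols - 1) / 2 * geometry$pitch_mm
  hy <- (geometry$used_rows - 1) / 2 * geometry$pitch_mm
  if (which == "axis") {
    h <- max(hx, hy)
    h / sqrt(h^2 + z^2)
  } else {
    sqrt(hx^2 + hy^2) / sqrt(hx^2 + hy^2 + z^2)
  }
}

#' Equivalent (synthesized) numerical aperture
#'
#' Angle-varied illumination extends the coherent passband from `2*pi*NA/lambda`
#' to `2*pi*(sin theta_max + NA)/lambda`; the synthesized system behaves like
#' one of numerical aperture `NA_obj + NA_illum`.
#'
#' @param objective_na Objective NA, in (0, 1).
#' @param illumination_na Illumination NA, in [0, 1).
#' @return Their sum (dimensionless; may exceed 1, which is reported, not
#'   clipped).
#' @examples
#' equivalent_na(0.1, 0.38)   # 0.48
#' equivalent_na(0.25, 0.38)  # 0.63
#' @export
equivalent_na <- function(objective_na, illumination_na) {
  if (any(objective_na <= 0) || any(objective_na >= 1)) {
    stop("objective_na must lie in (0, 1)")
  }
  if (any(illumination_na < 0) || any(illumination_na >= 1)) {
    stop("illumination_na must lie in [0, 1)")
  }
  objective_na + illumination_na
}

#' Coherent cutoff frequency in line pairs per millimetre
#'
#' The coherent transfer of a circular pupil cuts off at spatial frequency
#' `2*pi*NA/lambda` in angular units, i.e. `NA/lambda` in cycles; expressed in
#' the engineering unit of line pairs per mm this is `NA / lambda_mm`.
#'
#' @param na Numerical aperture (> 0).
#' @param wavelength_um Wavelength in micrometres (> 0).
#' @return Cutoff in lp/mm.
#' @examples
#' coherent_cutoff_lp_per_mm(0.1, 0.53)  # ~188.7
#' @export
coherent_cutoff_lp_per_mm <- function(na, wavelength_um) {
  if (any(na <= 0) || any(wavelength_um <= 0)) stop("na and wavelength must be > 0")
  na / (wavelength_um * 1e-3)
}

#' USAF 1951 element spatial frequency
#'
#' Element `e` of group `g` on a USAF 1951 target has spatial frequency
#' `2^(g + (e - 1)/6)` line pairs per mm.
#'
#' @param group Integer group number (vectorized; may be negative).
#' @param element Element number, 1 to 6 (vectorized).
#' @param rounded If `TRUE`, round to the nearest integer lp/mm (the form
#'   usually printed alongside target readouts, e.g. 161 for group 7
#'   element 3).
#' @return Spatial frequency in lp/mm.
#' @examples
#' usaf_frequency(7, 3)                  # 161.27
#' usaf_frequency(7, 3, rounded = TRUE)  # 161
#' usaf_frequency(9, 1)                  # 512 exactly
#' @export
usaf_frequency <- function(group, element, rounded = FALSE) {
  if (any(element < 1 | element > 6 | element != round(element))) {
    stop("element must be an integer between 1 and 6")
  }
  if (any(group != round(group))) stop("group must be an integer")
  f <- 2^(group + (element - 1) / 6)
  if (rounded) round(f) else f
}

#' Rayleigh half-pitch resolution and its inverse
#'
#' Under the Rayleigh criterion a system of numerical aperture `NA` resolves
#' a half-pitch of `0.61 * lambda / NA`; conversely an observed resolvable
#' half-pitch `r` implies an effective NA of `0.61 * lambda / r`. One line
#' pair spans a full period (two half-pitches), so a half-pitch `r` um
#' corresponds to `1000 / (2 r)` lp/mm.
#'
#' @param na Numerical aperture (> 0).
#' @param halfpitch_um Half-pitch in micrometres (> 0).
#' @param wavelength_um Wavelength in micrometres (> 0).
#' @return `rayleigh_halfpitch_um()`: half-pitch in um.
#'   `na_from_halfpitch()`: dimensionless NA.
#'   `halfpitch_to_lp_per_mm()`: frequency in lp/mm.
#' @examples
#' rayleigh_halfpitch_um(0.1, 0.53)             # 3.233 um
#' halfpitch_to_lp_per_mm(3.233)                # ~154.7 lp/mm
#' na_from_halfpitch(0.98, 0.53)                # ~0.33
#' @export
rayleigh_halfpitch_um <- function(na, wavelength_um) {
  if (any(na <= 0) || any(wavelength_um <= 0)) stop("inputs must be > 0")
  0.61 * wavelength_um / na
}

#' @rdname rayleigh_halfpitch_um
#' @export
na_from_halfpitch <- function(halfpitch_um, wavelength_um) {
  if (any(halfpitch_um <= 0) || any(wavelength_um <= 0)) stop("inputs must be > 0")
  0.61 * wavelength_um / halfpitch_um
}

#' @rdname rayleigh_halfpitch_um
#' @export
halfpitch_to_lp_per_mm <- function(halfpitch_um) {
  if (any(halfpitch_um <= 0)) stop("halfpitch_um must be > 0")
  1000 / (2 * halfpitch_um)
}

#' Construct a (possibly defocused) pupil function
#'
#' The objective acts on the object spectrum as a circular low-pass filter of
#' radius `2*pi*NA/lambda`. Defocus by `z` multiplies the passband by
#' `exp(1i * z * kz)` with `kz = sqrt((2*pi*n/lambda)^2 - |k|^2)` and
#' refractive index n = 1 (air).
#'
#' @param shape Integer vector of length 2, the (rows, cols) of the spectrum
#'   grid; both at least 2.
#' @param spectrum_sampling Spatial-frequency sampling interval in rad/um per
#'   pixel (> 0).
#' @param na Numerical aperture of the pupil (0 < NA < 1).
#' @param wavelength_um Wavelength in micrometres.
#' @param defocus_um Defocus distance z in micrometres; 0 gives a real,
#'   binary pupil.
#' @return An object of class `"pupil_function"`: list with the complex
#'   `array`, the binary support `mask`, and the construction parameters.
#' @examples
#' p <- make_pupil(c(64, 64), 0.2, 0.1, 0.53)
#' sum(p$mask)  # ~ pi * r^2 pixels
#' @export
make_pupil <- function(shape, spectrum_sampling, na, wavelength_um,
                       defocus_um = 0) {
  stopifnot(length(shape) == 2, all(shape >= 2), spectrum_sampling > 0,
            na > 0, na < 1, wavelength_um > 0)
  n1 <- as.integer(shape[1]); n2 <- as.integer(shape[2])
  k_na <- 2 * pi * na / wavelength_um
  k_nyq <- spectrum_sampling * min(floor(n1 / 2), floor(n2 / 2))
  if (k_na > k_nyq) {
    stop(sprintf(paste0("pupil radius (%.3g rad/um) exceeds the Nyquist extent ",
                        "of the %dx%d grid (%.3g rad/um); enlarge the grid or ",
                        "coarsen the sampling"), k_na, n1, n2, k_nyq))
  }
  ky <- centered_freqs(n1) * spectrum_sampling
  kx <- centered_freqs(n2) * spectrum_sampling
  k2 <- outer(ky^2, kx^2, `+`)
  mask <- k2 <= k_na^2
  arr <- matrix(0 + 0i, n1, n2)
  if (defocus_um == 0) {
    arr[mask] <- 1 + 0i
  } else {
    k0 <- 2 * pi / wavelength_um           # n = 1
    kz <- sqrt(pmax(k0^2 - k2[mask], 0))
    arr[mask] <- exp(1i * defocus_um * kz)
  }
  structure(list(
    array = arr, mask = mask, na = na, wavelength_um = wavelength_um,
    spectrum_pixel_per_um = spectrum_sampling, defocus_um = defocus_um
  ), class = "pupil_function")
}

#' @export
print.pupil_function <- function(x, ...) {
  cat(sprintf("Pupil function: %dx%d grid, NA %.3g, lambda %.3g um, defocus %g um\n",
              nrow(x$array), ncol(x$array), x$na, x$wavelength_um, x$defocus_um))
  cat(sprintf("  support: %d pixels (radius %.2f px)\n", sum(x$mask),
              2 * pi * x$na / x$wavelength_um / x$spectrum_pixel_per_um))
  invisible(x)
}

#' Preset optical configurations
#'
#' Convenience constructor for the two acquisition configurations studied in
#' the package: a 4x/0.1 NA or 10x/0.25 NA objective behind a 150 mm tube
#' lens, green 0.53 um illumination from a 15x15 sub-grid of a 4 mm pitch
#' LED panel 70 mm below the stage.
#'
#' @param preset `"4x"` or `"10x"`.
#' @param object_pixel_um Desired high-resolution object-plane pixel in um
#'   (used to derive a consistent camera pixel pitch for simulation).
#' @param downsample_factor Integer ratio of high-resolution grid to camera
#'   grid.
#' @return A list with elements `config` ([optical_system()]), `geometry`
#'   ([led_array()]) and `plan` ([illumination_plan()]).
#' @examples
#' fpm_preset("4x")
#' @export
fpm_preset <- function(preset = c("4x", "10x"), object_pixel_um = 0.2,
                       downsample_factor = 4) {
  preset <- match.arg(preset)
  na <- if (preset == "4x") 0.1 else 0.25
  mag <- if (preset == "4x") 4 else 10
  effmag <- effective_magnification(mag, 150, 180)
  config <- optical_system(
    objective_na = na, nominal_magnification = mag,
    tube_focal_length_mm = 150, reference_focal_length_mm = 180,
    wavelength_um = 0.53,
    camera_pixel_um = object_pixel_um * downsample_factor * effmag
  )
  geometry <- led_array()
  plan <- illumination_plan(geometry, config$wavelength_um)
  list(config = config, geometry = geometry, plan = plan)
}
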