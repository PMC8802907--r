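# Stack interchange format: a multi-page 32-bit TIFF (one page per LED,
# plan order) plus a JSON manifest holding the optical configuration, the
# illumination plan with wave vectors, the acquisition options and per-page
# checksums. Pages are stored divided by a global intensity scale (recorded
# in the manifest) so every stored value lies in [0, 1]; 32-bit samples
# quantize at 2^-32 of full scale, far below any optical tolerance in this
# package. Checksums are computed from the pages as stored, so read-time
# validation is exact.

#' @noRd
page_checksum <- function(m) {
  sprintf("%.10e|%.10e", sum(m), sum(m * seq_along(m)))
}

#' Write a raw FPM stack to disk
#'
#' @param stack A `raw_stack`.
#' @param path Path of the TIFF file to write; the manifest is written next
#'   to it as `<path>.json`.
#' @return Invisibly, the manifest list.
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "raw_stack"))
  scale <- max(1e-12, max(vapply(stack$images, max, numeric(1))))
  pages <- lapply(stack$images, function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  stored <- tiff::readTIFF(path, all = TRUE)
  geometry <- attr(stack$plan, "geometry")
  manifest <- list(
    schema_version = 1L,
    config = stack$config[c("objective_na", "nominal_magnification",
                            "tube_focal_length_mm", "reference_focal_length_mm",
                            "wavelength_um", "camera_pixel_um")],
    geometry = if (!is.null(geometry)) unclass(geometry) else NULL,
    ordering_rule = attr(stack$plan, "ordering_rule"),
    plan = as.data.frame(stack$plan),
    options = unclass(stack$options),
    object_pixel_um = stack$object_pixel_um,
    intensity_scale = scale,
    seed = stack$seed,
    n_pages = length(pages),
    page_shape = dim(stack$images[[1]]),
    checksums = vapply(stored, page_checksum, character(1))
  )
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Read a raw FPM stack from disk
#'
#' Reads a TIFF + JSON manifest pair written by [write_stack()], validating
#' the page count, page shapes and per-page checksums against the manifest.
#'
#' @param path Path of the TIFF file (manifest expected at `<path>.json`).
#' @return A `raw_stack`.
#' @export
read_stack <- function(path) {
  mpath <- paste0(path, ".json")
  if (!file.exists(path)) stop("stack TIFF not found: ", path)
  if (!file.exists(mpath)) stop("stack manifest not found: ", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != man$n_pages) {
    stop(sprintf("corrupt stack: manifest declares %d pages but TIFF holds %d",
                 man$n_pages, length(pages)))
  }
  for (i in seq_along(pages)) {
    if (!all(dim(pages[[i]]) == man$page_shape)) {
      stop(sprintf("corrupt stack: page %d has shape %dx%d, expected %dx%d",
                   i, nrow(pages[[i]]), ncol(pages[[i]]),
                   man$page_shape[1], man$page_shape[2]))
    }
    if (page_checksum(pages[[i]]) != man$checksums[i]) {
      stop(sprintf("corrupt stack: checksum mismatch on page %d", i))
    }
  }
  config <- optical_system(
    objective_na = man$config$objective_na,
    nominal_magnification = man$config$nominal_magnification,
    tube_focal_length_mm = man$config$tube_focal_length_mm,
    reference_focal_length_mm = man$config$reference_focal_length_mm,
    wavelength_um = man$config$wavelength_um,
    camera_pixel_um = man$config$camera_pixel_um
  )
  plan <- as.data.frame(man$plan)
  if (nrow(plan) != man$n_pages) {
    stop(sprintf("corrupt stack: %d plan entries for %d pages",
                 nrow(plan), man$n_pages))
  }
  if (!is.null(man$geometry)) {
    attr(plan, "geometry") <- do.call(led_array, man$geometry)
  }
  attr(plan, "ordering_rule") <- man$ordering_rule
  attr(plan, "wavelength_um") <- config$wavelength_um
  class(plan) <- c("illumination_plan", "data.frame")
  opts <- man$options
  options <- acquisition_options(
    downsample_factor = opts$downsample_factor,
    defocus_um = opts$defocus_um,
    noise = opts$noise,
    noise_sigma = opts$noise_sigma,
    photon_scale = opts$photon_scale,
    seed = if (is.null(opts$seed)) NULL else opts$seed,
    downsample_method = opts$downsample_method
  )
  images <- lapply(pages, function(m) m * man$intensity_scale)
  dk <- 2 * pi / (nrow(images[[1]]) * options$downsample_factor *
                    man$object_pixel_um)
  structure(list(images = images, plan = plan, config = config,
                 options = options, object_pixel_um = man$object_pixel_um,
                 centers = plan_pixel_centers(plan, dk), seed = options$seed),
            class = "raw_stack")
}

#' Save a complex-object phantom as paired TIFFs plus a truth sidecar
#'
#' Writes `<prefix>_amplitude.tif`, `<prefix>_phase.tif` (32-bit samples;
#' the phase page is stored affinely mapped to [0, 1] with the range
#' recorded in the sidecar) and `<prefix>_truth.json`.
#'
#' @param object A [complex_object()].
#' @param prefix File path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_phantom <- function(object, prefix) {
  stopifnot(inherits(object, "complex_object"))
  fa <- paste0(prefix, "_amplitude.tif")
  fp <- paste0(prefix, "_phase.tif")
  ft <- paste0(prefix, "_truth.json")
  tiff::writeTIFF(object$amplitude, fa, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  rng <- range(object$phase)
  ph01 <- if (rng[1] == rng[2]) object$phase * 0 else
    (object$phase - rng[1]) / (rng[2] - rng[1])
  tiff::writeTIFF(ph01, fp, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(pixel_um = object$pixel_um, phase_range = rng, truth = object$truth),
    ft, auto_unbox = TRUE, digits = NA, null = "null", dataframe = "columns")
  invisible(c(fa, fp, ft))
}
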