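#' Complex-valued object (sample transmission function)
#'
#' A thin sample is modelled by its complex transmission
#' `s(x) = A(x) * exp(1i * phi(x))` with amplitude `A` in [0, 1] and phase
#' `phi` in radians, sampled on a square pixel grid.
#'
#' @param amplitude Numeric matrix in [0, 1].
#' @param phase Numeric matrix of the same shape, radians. Default all zero.
#' @param pixel_um Pixel size in micrometres (> 0).
#' @param truth Optional ground-truth annotation attached by a generator.
#' @return An object of class `"complex_object"`.
#' @export
complex_object <- function(amplitude, phase = NULL, pixel_um, truth = NULL) {
  stopifnot(is.matrix(amplitude), is.numeric(amplitude))
  if (is.null(phase)) phase <- matrix(0, nrow(amplitude), ncol(amplitude))
  stopifnot(is.matrix(phase), all(dim(phase) == dim(amplitude)))
  if (any(!is.finite(amplitude)) || any(amplitude < 0) || any(amplitude > 1 + 1e-9)) {
    stop("amplitude must be finite and lie in [0, 1]")
  }
  if (any(!is.finite(phase))) stop("phase must be finite")
  stopifnot(is.numeric(pixel_um), length(pixel_um) == 1, pixel_um > 0)
  structure(list(amplitude = pmin(amplitude, 1), phase = phase,
                 pixel_um = pixel_um, truth = truth),
            class = "complex_object")
}

#' Complex field of a complex_object
#'
#' @param object A [complex_object()].
#' @return The complex matrix `amplitude * exp(1i * phase)`.
#' @export
as_complex_field <- function(object) {
  stopifnot(inherits(object, "complex_object"))
  object$amplitude * exp(1i * object$phase)
}

#' @export
print.complex_object <- function(x, ...) {
  cat(sprintf("Complex object: %d x %d pixels at %.3g um/px (%.3g x %.3g um)\n",
              nrow(x$amplitude), ncol(x$amplitude), x$pixel_um,
              nrow(x$amplitude) * x$pixel_um, ncol(x$amplitude) * x$pixel_um))
  cat(sprintf("  amplitude range [%.3g, %.3g], phase range [%.3g, %.3g] rad\n",
              min(x$amplitude), max(x$amplitude), min(x$phase), max(x$phase)))
  if (!is.null(x$truth)) cat("  ground-truth annotation attached\n")
  invisible(x)
}
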