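# USAF 1951 bar-target phantom. Elements are rendered as the standard
# three-bar pattern (bar length : width = 5 : 1, both orientations) at 4x
# supersampling followed by box downsampling, so that bar edges are
# antialiased rather than snapped to the object grid.

#' Generate a synthetic USAF 1951 bar-target phantom
#'
#' Renders three-bar elements for the requested groups/elements in both
#' orientations on a clear (transmission 1) background, together with a
#' machine-readable index of every rendered element (position, orientation
#' and spatial frequency) used by the evaluation functions.
#'
#' Dark bars have amplitude transmission `1 - amplitude_contrast` and an
#' optional phase step of `phase_contrast` radians. The physical chrome
#' target contains no phase structure; `phase_contrast = 0` (the default)
#' mimics it, while a nonzero value produces a mixed amplitude/phase target.
#'
#' @param groups Integer vector of USAF group numbers to render.
#' @param elements Integer vector of elements within each group (subset of
#'   1:6). Default all six.
#' @param pixel_um Object pixel size in micrometres. Must give at least 2
#'   samples per half-pitch of the finest requested element (Nyquist guard).
#' @param amplitude_contrast Bar amplitude contrast in [0, 1]; 1 renders
#'   opaque bars.
#' @param phase_contrast Phase step on the bars, radians.
#' @param orientations Character vector, subset of
#'   `c("vertical", "horizontal")`. `"vertical"` bars run along y and
#'   modulate along x.
#' @param shape Optional c(rows, cols) canvas size in pixels; the layout is
#'   centered on it. If `NULL` a snug canvas is chosen.
#' @param supersample Integer antialiasing factor (default 4).
#' @return A [complex_object()] whose `truth` field is the bar-pattern index:
#'   a data frame with columns `group`, `element`, `orientation`, `row0`,
#'   `col0`, `n_row`, `n_col` (tight 1-based pixel rectangle around the three
#'   bars), `period_um` and `lp_per_mm`.
#' @examples
#' ph <- generate_usaf_phantom(groups = 8, pixel_um = 0.2)
#' head(ph$truth)
#' @export
generate_usaf_phantom <- function(groups, elements = 1:6, pixel_um = 0.2,
                                  amplitude_contrast = 1, phase_contrast = 0,
                                  orientations = c("vertical", "horizontal"),
                                  shape = NULL, supersample = 4) {
  stopifnot(length(groups) >= 1, pixel_um > 0,
            amplitude_contrast >= 0, amplitude_contrast <= 1,
            supersample >= 1, supersample == round(supersample))
  orientations <- match.arg(orientations, several.ok = TRUE)
  elements <- sort(unique(as.integer(elements)))
  if (any(elements < 1 | elements > 6)) stop("elements must be in 1..6")

  spec <- expand.grid(element = elements, group = sort(unique(as.integer(groups))))
  spec$lp_per_mm <- usaf_frequency(spec$group, spec$element)
  spec$period_um <- 1000 / spec$lp_per_mm
  # Nyquist guard: >= 2 samples per half-pitch
  bad <- spec$period_um / 2 < 2 * pixel_um
  if (any(bad)) {
    b <- spec[bad, ][1, ]
    stop(sprintf(paste0("pixel_um = %g gives fewer than 2 samples per half-pitch ",
                        "for group %d element %d (%.1f lp/mm); use a finer pixel"),
                 pixel_um, b$group, b$element, b$lp_per_mm))
  }

  # one cell per (element, orientation): 5w x 5w block + 1 period margin
  cells <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    do.call(rbind, lapply(orientations, function(o) {
      w <- spec$period_um[i] / 2
      data.frame(group = spec$group[i], element = spec$element[i],
                 orientation = o, bar_w_um = w, block_um = 5 * w,
                 margin_um = w, lp_per_mm = spec$lp_per_mm[i],
                 period_um = spec$period_um[i])
    }))
  }))
  cells$cell_um <- cells$block_um + 2 * cells$margin_um
  cells <- cells[order(-cells$cell_um), ]

  # shelf layout
  total_area <- sum(cells$cell_um^2)
  target_w <- if (is.null(shape)) sqrt(total_area) * 1.25 else shape[2] * pixel_um
  x_cur <- 0; y_cur <- 0; shelf_h <- 0; x_max <- 0
  cells$x0 <- NA_real_; cells$y0 <- NA_real_
  for (i in seq_len(nrow(cells))) {
    cu <- cells$cell_um[i]
    if (x_cur + cu > target_w * (1 + 1e-9) && x_cur > 0) {
      x_cur <- 0; y_cur <- y_cur + shelf_h; shelf_h <- 0
    }
    cells$x0[i] <- x_cur + cells$margin_um[i]
    cells$y0[i] <- y_cur + cells$margin_um[i]
    x_cur <- x_cur + cu
    x_max <- max(x_max, x_cur)
    shelf_h <- max(shelf_h, cu)
  }
  content_w <- x_max; content_h <- y_cur + shelf_h
  need <- ceiling(c(content_h, content_w) / pixel_um - 1e-9)
  if (is.null(shape)) shape <- need
  shape <- as.integer(shape)
  if (any(shape < need)) {
    stop(sprintf("requested canvas %dx%d px cannot hold the layout (needs %dx%d)",
                 shape[1], shape[2], need[1], need[2]))
  }
  # center the content block on the canvas
  off_um <- (shape * pixel_um - c(content_h, content_w)) / 2
  cells$x0 <- cells$x0 + off_um[2]
  cells$y0 <- cells$y0 + off_um[1]

  ss <- as.integer(supersample)
  fine <- pixel_um / ss
  nfr <- shape[1] * ss; nfc <- shape[2] * ss
  amp_f <- matrix(1, nfr, nfc)
  pha_f <- matrix(0, nfr, nfc)
  px_range <- function(a_um, len_um, n) {
    lo <- max(1L, as.integer(floor(a_um / fine)) + 1L)
    hi <- min(n, as.integer(ceiling((a_um + len_um) / fine)))
    if (hi < lo) integer(0) else lo:hi
  }
  bar_amp <- 1 - amplitude_contrast
  for (i in seq_len(nrow(cells))) {
    w <- cells$bar_w_um[i]
    for (b in 0:2) {
      if (cells$orientation[i] == "vertical") {
        cols <- px_range(cells$x0[i] + 2 * b * w, w, nfc)
        rows <- px_range(cells$y0[i], 5 * w, nfr)
      } else {
        rows <- px_range(cells$y0[i] + 2 * b * w, w, nfr)
        cols <- px_range(cells$x0[i], 5 * w, nfc)
      }
      amp_f[rows, cols] <- bar_amp
      pha_f[rows, cols] <- phase_contrast
    }
  }
  amp <- box_downsample(amp_f, ss)
  pha <- box_downsample(pha_f, ss)

  # tight rectangles on the object grid
  idx <- cells
  idx$row0 <- as.integer(floor(idx$y0 / pixel_um)) + 1L
  idx$col0 <- as.integer(floor(idx$x0 / pixel_um)) + 1L
  idx$n_row <- pmax(1L, as.integer(round(ifelse(idx$orientation == "vertical",
                                                5 * idx$bar_w_um,
                                                5 * idx$bar_w_um) / pixel_um)))
  idx$n_col <- idx$n_row  # three-bar block is 5w x 5w
  index <- idx[order(idx$lp_per_mm, idx$orientation),
               c("group", "element", "orientation", "row0", "col0",
                 "n_row", "n_col", "period_um", "lp_per_mm")]
  rownames(index) <- NULL

  complex_object(amp, pha, pixel_um, truth = index)
}
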