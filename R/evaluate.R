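# Resolving-power evaluation from bar targets: per-element contrast
# C = (Imax - Imin) / (Imax + Imin), MTF assembly across elements, monotone
# curve fitting with cutoff / threshold-frequency accessors, the
# smallest-resolved-element readout, and phase-image display preparation.

# Plateau-aware local extrema of a 1-D profile. Runs of equal values are
# collapsed; boundary runs are not extrema. Returns positions (run middles)
# and values for maxima and minima.
#' @noRd
profile_extrema <- function(p) {
  r <- rle(p)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mid <- (starts + ends) / 2
  n <- length(v)
  if (n < 3) {
    return(list(max_pos = numeric(0), max_val = numeric(0),
                min_pos = numeric(0), min_val = numeric(0)))
  }
  i <- 2:(n - 1)
  is_max <- v[i] > v[i - 1] & v[i] > v[i + 1]
  is_min <- v[i] < v[i - 1] & v[i] < v[i + 1]
  list(max_pos = mid[i][is_max], max_val = v[i][is_max],
       min_pos = mid[i][is_min], min_val = v[i][is_min])
}

#' Bar-pattern contrast of a three-bar element
#'
#' Measures the contrast `C = (Imax - Imin) / (Imax + Imin)` of one USAF
#' three-bar element in an intensity image. The image rows (or columns) of
#' the element are averaged along the bar length to a single profile
#' perpendicular to the bars; `Imin` is the mean of the three deepest
#' valleys (the dark bars) and `Imax` the mean of the two ridges between
#' them. The element counts as resolved only when three valleys and the two
#' intervening ridges are actually detectable.
#'
#' @param image Non-negative intensity matrix.
#' @param roi One row of a bar-pattern index (as produced by
#'   [generate_usaf_phantom()]), or any list/data frame with `row0`, `col0`,
#'   `n_row`, `n_col`, `orientation` and `period_um`.
#' @param pixel_um Pixel size of `image` in micrometres (used to pad the
#'   rectangle by half a bar period so the flanking ridges are visible).
#' @param n_bars Number of bars in the element (3 for USAF).
#' @return List with `contrast` (in [0, 1]; 0 when unresolved), `resolved`
#'   (logical), `imax`, `imin` and the extracted `profile`.
#' @examples
#' ph <- generate_usaf_phantom(groups = 8, elements = 2, pixel_um = 0.2)
#' bar_contrast(ph$amplitude^2, ph$truth[1, ], ph$pixel_um)$contrast  # ~1
#' @export
bar_contrast <- function(image, roi, pixel_um, n_bars = 3) {
  stopifnot(is.matrix(image), n_bars >= 2)
  roi <- as.list(roi)
  pad <- max(1L, as.integer(round(roi$period_um / 2 / pixel_um)))
  # pad by half a period across the bars (so flanking ridges are visible) and
  # trim 10% off each end along the bars (away from antialiased bar ends)
  trim_r <- ifelse(roi$orientation == "vertical",
                   as.integer(floor(0.1 * roi$n_row)), -pad)
  trim_c <- ifelse(roi$orientation == "horizontal",
                   as.integer(floor(0.1 * roi$n_col)), -pad)
  r0 <- max(1L, roi$row0 + trim_r)
  c0 <- max(1L, roi$col0 + trim_c)
  r1 <- min(nrow(image), roi$row0 + roi$n_row - 1L - trim_r)
  c1 <- min(ncol(image), roi$col0 + roi$n_col - 1L - trim_c)
  sub <- image[r0:r1, c0:c1, drop = FALSE]
  profile <- if (roi$orientation == "vertical") colMeans(sub) else rowMeans(sub)

  ex <- profile_extrema(profile)
  unresolved <- list(contrast = 0, resolved = FALSE,
                     imax = NA_real_, imin = NA_real_, profile = profile)
  if (length(ex$min_val) < n_bars) return(unresolved)
  valley_idx <- order(ex$min_val)[seq_len(n_bars)]
  vpos <- sort(ex$min_pos[valley_idx])
  imin <- mean(ex$min_val[valley_idx])
  ridge_keep <- ex$max_pos > vpos[1] & ex$max_pos < vpos[n_bars]
  if (sum(ridge_keep) < n_bars - 1) return(unresolved)
  rv <- ex$max_val[ridge_keep]
  imax <- mean(sort(rv, decreasing = TRUE)[seq_len(n_bars - 1)])
  if (!(imax > imin)) return(unresolved)
  ctr <- (imax - imin) / (imax + imin)
  list(contrast = min(max(ctr, 0), 1), resolved = TRUE,
       imax = imax, imin = imin, profile = profile)
}

#' Assemble MTF samples from a bar-pattern index
#'
#' Measures [bar_contrast()] for every indexed element and orientation, and
#' (by default) averages the two orientations into one sample per element.
#' Samples are normalized by the contrast of the lowest-frequency element,
#' anchoring the curve to 1 near zero frequency.
#'
#' @param image Intensity matrix.
#' @param index Bar-pattern index data frame (`truth` of
#'   [generate_usaf_phantom()]); entries must lie inside the image.
#' @param pixel_um Pixel size of `image` in micrometres.
#' @param average_orientations Average vertical/horizontal contrasts
#'   (default `TRUE`).
#' @param normalize Normalize by the lowest-frequency sample (default
#'   `TRUE`).
#' @return Data frame of class `"mtf_samples"` with columns `group`,
#'   `element`, `lp_per_mm`, `contrast`, `resolved` (and `orientation` when
#'   not averaging); attribute `normalization` stores the anchor contrast.
#' @export
build_mtf <- function(image, index, pixel_um, average_orientations = TRUE,
                      normalize = TRUE) {
  stopifnot(is.data.frame(index))
  if (nrow(index) == 0) stop("empty bar-pattern index")
  res <- lapply(seq_len(nrow(index)), function(i) {
    bc <- bar_contrast(image, index[i, ], pixel_um)
    data.frame(group = index$group[i], element = index$element[i],
               orientation = index$orientation[i],
               lp_per_mm = index$lp_per_mm[i],
               contrast = bc$contrast, resolved = bc$resolved)
  })
  out <- do.call(rbind, res)
  if (average_orientations) {
    key <- interaction(out$group, out$element, drop = TRUE)
    agg <- do.call(rbind, lapply(split(out, key), function(d) {
      data.frame(group = d$group[1], element = d$element[1],
                 lp_per_mm = d$lp_per_mm[1],
                 contrast = mean(d$contrast),
                 resolved = all(d$resolved))
    }))
    out <- agg[order(agg$lp_per_mm), ]
  } else {
    out <- out[order(out$lp_per_mm, out$orientation), ]
  }
  rownames(out) <- NULL
  anchor <- 1
  if (normalize) {
    anchor <- out$contrast[which.min(out$lp_per_mm)]
    if (anchor <= 0) stop("lowest-frequency element has zero contrast; cannot normalize")
    out$contrast <- pmin(out$contrast / anchor, 1)
  }
  structure(out, normalization = anchor,
            class = c("mtf_samples", "data.frame"))
}

#' Fit a monotone MTF curve
#'
#' Fits a smooth monotone non-increasing curve through measured contrast
#' samples: the samples are isotonic-regressed (pool-adjacent-violators,
#' non-increasing) and interpolated by a monotone piecewise-cubic (Hyman
#' filtered) spline anchored at contrast 1 for frequency 0. The cutoff is
#' the smallest frequency at which the fitted curve falls to
#' `cutoff_level`.
#'
#' @param samples An `"mtf_samples"` data frame (or any data frame with
#'   `lp_per_mm` and `contrast`), at least 4 samples.
#' @param cutoff_level Contrast level defining the cutoff (default 0.02;
#'   fitted curves approach zero asymptotically, so an exact zero crossing
#'   is not well defined).
#' @return An object of class `"mtf_curve"`: list with `samples`, `fitted`
#'   (a function of frequency), `cutoff_lp_mm` (`NA` if the curve never
#'   falls to the level inside the sampled range), `cutoff_level`,
#'   `f_max` and `fit_method`.
#' @export
fit_mtf_curve <- function(samples, cutoff_level = 0.02) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 4)
  s <- samples[order(samples$lp_per_mm), ]
  if (all(s$contrast <= 0)) stop("all contrast samples are zero; degenerate MTF")
  f <- c(0, s$lp_per_mm)
  y <- c(1, pmin(pmax(s$contrast, 0), 1))
  # isotonic regression for a non-increasing fit
  iso <- stats::isoreg(f, -y)
  yi <- pmin(pmax(-iso$yf, 0), 1)
  yi[1] <- 1
  yi <- cummin(yi)                       # guard: strictly enforce monotone
  ux <- !duplicated(f)
  fit_method <- "isotonic+hyman-spline"
  fitted_fun <- tryCatch(
    stats::splinefun(f[ux], yi[ux], method = "hyman"),
    error = function(e) {
      fit_method <<- "isotonic+linear"
      stats::approxfun(f[ux], yi[ux], rule = 2)
    })
  f_max <- max(f)
  fitted <- function(freq) {
    v <- fitted_fun(pmin(pmax(freq, 0), f_max))
    pmin(pmax(v, 0), 1)
  }
  cutoff <- NA_real_
  if (min(yi) <= cutoff_level) {
    grid <- seq(0, f_max, length.out = 4096)
    under <- which(fitted(grid) <= cutoff_level)
    if (length(under)) {
      i <- under[1]
      cutoff <- if (i == 1) 0 else
        stats::uniroot(function(x) fitted(x) - cutoff_level,
                       c(grid[i - 1], grid[i]))$root
    }
  }
  structure(list(samples = s, fitted = fitted, cutoff_lp_mm = cutoff,
                 cutoff_level = cutoff_level, f_max = f_max,
                 fit_method = fit_method),
            class = "mtf_curve")
}

#' Frequency at a given contrast level
#'
#' Inverse lookup on a fitted MTF curve: the smallest frequency at which the
#' fitted contrast falls to `contrast`. `frequency_at_contrast(curve, 1)` is
#' 0 by the normalization anchor.
#'
#' @param curve An `"mtf_curve"`.
#' @param contrast Contrast level in (0, 1].
#' @return Frequency in lp/mm (`NA` if the curve stays above the level).
#' @export
frequency_at_contrast <- function(curve, contrast) {
  stopifnot(inherits(curve, "mtf_curve"), contrast > 0, contrast <= 1)
  if (contrast >= 1) return(0)
  grid <- seq(0, curve$f_max, length.out = 4096)
  under <- which(curve$fitted(grid) <= contrast)
  if (!length(under)) return(NA_real_)
  i <- under[1]
  if (i == 1) return(0)
  stats::uniroot(function(x) curve$fitted(x) - contrast,
                 c(grid[i - 1], grid[i]))$root
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf("MTF curve: %d samples, %.4g-%.4g lp/mm (%s)\n",
              nrow(x$samples), min(x$samples$lp_per_mm),
              max(x$samples$lp_per_mm), x$fit_method))
  cat(sprintf("  cutoff (contrast <= %.3g): %s lp/mm\n", x$cutoff_level,
              if (is.na(x$cutoff_lp_mm)) "not reached" else
                sprintf("%.1f", x$cutoff_lp_mm)))
  invisible(x)
}

#' @export
plot.mtf_curve <- function(x, ...) {
  grid <- seq(0, x$f_max, length.out = 400)
  plot(grid, x$fitted(grid), type = "l", xlab = "spatial frequency (lp/mm)",
       ylab = "normalized contrast", ylim = c(0, 1), ...)
  points(x$samples$lp_per_mm, pmin(x$samples$contrast, 1), pch = 19)
  if (!is.na(x$cutoff_lp_mm)) abline(v = x$cutoff_lp_mm, lty = 2)
  invisible(x)
}

#' Smallest resolved USAF element in an image
#'
#' The finest (highest-frequency) indexed element whose every rendered
#' orientation passes the ridge/valley detection of [bar_contrast()] with
#' contrast above `contrast_threshold`.
#'
#' @param image Intensity matrix.
#' @param index Bar-pattern index data frame.
#' @param pixel_um Pixel size of `image` in micrometres.
#' @param contrast_threshold Minimum contrast to count as resolved
#'   (default 0.1).
#' @return A one-row data frame with `group`, `element` and `lp_per_mm`, or
#'   a zero-row data frame when nothing is resolved.
#' @export
smallest_resolved_element <- function(image, index, pixel_um,
                                      contrast_threshold = 0.1) {
  m <- build_mtf(image, index, pixel_um, average_orientations = FALSE,
                 normalize = FALSE)
  key <- interaction(m$group, m$element, drop = TRUE)
  per_el <- do.call(rbind, lapply(split(m, key), function(d) {
    data.frame(group = d$group[1], element = d$element[1],
               lp_per_mm = d$lp_per_mm[1],
               ok = all(d$resolved & d$contrast > contrast_threshold))
  }))
  hit <- per_el[per_el$ok, , drop = FALSE]
  if (nrow(hit) == 0) {
    return(data.frame(group = integer(0), element = integer(0),
                      lp_per_mm = numeric(0)))
  }
  best <- hit[which.max(hit$lp_per_mm), c("group", "element", "lp_per_mm")]
  rownames(best) <- NULL
  best
}

#' Prepare a phase image for display
#'
#' Affinely rescales the phase range to [0, 255] and inverts
#' (`v -> 255 - v`), so that the zero-phase background renders bright. A
#' constant phase image maps to all 255.
#'
#' @param phase Finite numeric matrix of phases (radians).
#' @return Integer matrix with values in 0..255.
#' @export
prepare_phase_display <- function(phase) {
  stopifnot(is.matrix(phase))
  if (any(!is.finite(phase))) stop("phase image contains non-finite values")
  rng <- range(phase)
  if (rng[1] == rng[2]) {
    out <- matrix(255L, nrow(phase), ncol(phase))
  } else {
    v <- round(255 * (phase - rng[1]) / (rng[2] - rng[1]))
    out <- matrix(as.integer(255 - v), nrow(phase), ncol(phase))
  }
  out
}
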