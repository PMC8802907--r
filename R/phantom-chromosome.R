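# Giemsa-banded metaphase-chromosome phantom. Chromosomes are rendered as
# elongated, slightly curved rods carrying alternating dark/bright bands
# perpendicular to the centerline. Giemsa-stained chromatin absorbs and also
# retards the wavefront, so the bands carry a phase component correlated
# with their absorption. Rendering is done by stamping disks along a finely
# sampled centerline on a supersampled grid, then box-downsampling.

#' Generate a synthetic banded-chromosome phantom
#'
#' Produces a complex-valued object emulating a metaphase spread of
#' Giemsa-banded chromosomes on a clear background, plus a ground-truth
#' annotation (centerlines, band boundaries, polarities and band spatial
#' frequencies) for downstream evaluation.
#'
#' @param n_chromosomes Number of chromosomes to place (0 gives a uniform
#'   background object with empty truth).
#' @param shape Canvas size c(rows, cols) in object pixels.
#' @param pixel_um Object pixel size in micrometres.
#' @param band_freq_range_lp_mm Interval of band spatial frequencies in
#'   lp/mm (one line pair = one dark + one bright band). Chromosome band
#'   patterns live below roughly 1000 lp/mm; the default 300-900 lp/mm
#'   gives band periods of 1.1-3.3 um.
#' @param length_range_um,width_range_um Chromosome length and width ranges
#'   in micrometres.
#' @param min_transmission Amplitude transmission of the dark bands
#'   (default 0.35, a visually Giemsa-like contrast; an arbitrary rendering
#'   choice, not a measured optical density).
#' @param light_transmission Amplitude transmission of the bright bands.
#' @param phase_amplitude Peak phase retardation in radians, reached on the
#'   dark bands; bright bands carry a proportionally smaller phase.
#' @param seed Integer seed; the phantom is bit-reproducible for a fixed
#'   seed and leaves the caller's RNG untouched.
#' @param supersample Integer antialiasing factor (default 4).
#' @param max_retries Placement retries per chromosome before giving up.
#' @return A [complex_object()] whose `truth` is a list with one entry per
#'   chromosome: `centerline` (data frame of `s_um`, `row`, `col` in object
#'   pixels), `band_boundaries_um`, `band_polarity`, `band_lp_mm`,
#'   `length_um`, `width_um`.
#' @examples
#' ph <- generate_chromosome_phantom(n_chromosomes = 3, shape = c(128, 128),
#'                                   seed = 7)
#' length(ph$truth)
#' @export
generate_chromosome_phantom <- function(n_chromosomes = 8,
                                        shape = c(256, 256),
                                        pixel_um = 0.2,
                                        band_freq_range_lp_mm = c(300, 900),
                                        length_range_um = c(5, 10),
                                        width_range_um = c(1.2, 1.8),
                                        min_transmission = 0.35,
                                        light_transmission = 0.85,
                                        phase_amplitude = 1,
                                        seed = 1,
                                        supersample = 4,
                                        max_retries = 200) {
  stopifnot(n_chromosomes >= 0, length(shape) == 2, all(shape >= 8),
            pixel_um > 0, length(band_freq_range_lp_mm) == 2,
            all(band_freq_range_lp_mm > 0),
            min_transmission >= 0, min_transmission < light_transmission,
            light_transmission <= 1, supersample >= 1)
  if (band_freq_range_lp_mm[2] > 1000) {
    warning("band frequencies above 1000 lp/mm exceed the typical chromosome band range")
  }
  shape <- as.integer(shape)
  ss <- as.integer(supersample)
  fine <- pixel_um / ss
  nfr <- shape[1] * ss; nfc <- shape[2] * ss
  H_um <- shape[1] * pixel_um; W_um <- shape[2] * pixel_um

  amp_f <- matrix(1, nfr, nfc)
  pha_f <- matrix(0, nfr, nfc)
  truth <- list()
  if (n_chromosomes == 0) {
    return(complex_object(amp_f[seq(1, nfr, ss), seq(1, nfc, ss), drop = FALSE] * 0 + 1,
                          matrix(0, shape[1], shape[2]), pixel_um, truth = list()))
  }

  with_seed(seed, {
    placed <- data.frame(cy = numeric(0), cx = numeric(0), R = numeric(0))
    for (ci in seq_len(n_chromosomes)) {
      L <- stats::runif(1, length_range_um[1], length_range_um[2])
      wd <- stats::runif(1, width_range_um[1], width_range_um[2])
      R <- L / 2 + wd
      if (2 * R > min(H_um, W_um)) {
        stop(sprintf("canvas (%.1f x %.1f um) too small for a %.1f um chromosome",
                     H_um, W_um, L))
      }
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cy <- stats::runif(1, R, H_um - R)
        cx <- stats::runif(1, R, W_um - R)
        if (nrow(placed) == 0 ||
            all(sqrt((placed$cy - cy)^2 + (placed$cx - cx)^2) >
                0.8 * (placed$R + R))) { ok <- TRUE; break }
      }
      if (!ok) stop(sprintf("could not place chromosome %d after %d retries; use a larger canvas or fewer chromosomes",
                            ci, max_retries))
      placed <- rbind(placed, data.frame(cy = cy, cx = cx, R = R))

      theta <- stats::runif(1, 0, pi)
      u <- c(cos(theta), sin(theta))        # (dy, dx) along the rod
      v <- c(-u[2], u[1])                   # perpendicular
      bend <- stats::runif(1, -0.15, 0.15)  # relative centerline bow

      # fine centerline samples
      tt <- seq(-L / 2, L / 2, by = fine / 2)
      off <- bend * L * ((tt / (L / 2))^2 - 1 / 3)  # zero-mean quadratic bow
      py <- cy + tt * u[1] + off * v[1]
      px <- cx + tt * u[2] + off * v[2]
      s_um <- c(0, cumsum(sqrt(diff(py)^2 + diff(px)^2)))
      arclen <- s_um[length(s_um)]

      # band structure along arclength
      f_band <- stats::runif(1, band_freq_range_lp_mm[1], band_freq_range_lp_mm[2])
      half_um <- 1000 / f_band / 2           # length of one band (half period)
      boundaries <- seq(half_um, arclen, by = half_um)
      start_dark <- stats::runif(1) < 0.5
      band_of <- function(s) pmin(floor(s / half_um), length(boundaries))
      n_bands <- band_of(arclen - 1e-9) + 1
      first_two <- if (start_dark) c("dark", "bright") else c("bright", "dark")
      polarity <- rep(first_two, length.out = n_bands)
      trans_of_band <- ifelse(polarity == "dark", min_transmission, light_transmission)

      # stamp disks along the centerline; each pixel takes the band value of
      # its nearest centerline sample, so bands stay perpendicular to the
      # centerline instead of being smeared by overlapping stamps
      r_px <- max(1L, as.integer(round(wd / 2 / fine)))
      dy <- rep(-r_px:r_px, times = 2 * r_px + 1)
      dx <- rep(-r_px:r_px, each = 2 * r_px + 1)
      keep <- dy^2 + dx^2 <= r_px^2
      dy <- dy[keep]; dx <- dx[keep]
      dd <- dy^2 + dx^2

      band_id <- band_of(s_um) + 1
      tr <- trans_of_band[band_id]
      ph <- phase_amplitude * (1 - tr) / (1 - min_transmission)
      iy <- as.integer(round(py / fine)) + 1L
      ix <- as.integer(round(px / fine)) + 1L
      dist_f <- matrix(Inf, nfr, nfc)
      for (si in seq_along(tt)) {
        yy <- iy[si] + dy; xx <- ix[si] + dx
        inb <- yy >= 1L & yy <= nfr & xx >= 1L & xx <= nfc
        lin <- (xx[inb] - 1L) * nfr + yy[inb]
        upd <- dd[inb] < dist_f[lin]
        lu <- lin[upd]
        dist_f[lu] <- dd[inb][upd]
        amp_f[lu] <- tr[si]
        pha_f[lu] <- ph[si]
      }

      truth[[ci]] <- list(
        centerline = data.frame(s_um = s_um,
                                row = py / pixel_um + 0.5,
                                col = px / pixel_um + 0.5),
        band_boundaries_um = boundaries,
        band_polarity = polarity,
        band_lp_mm = rep(f_band, n_bands),
        length_um = arclen, width_um = wd
      )
    }
  })

  amp <- box_downsample(amp_f, ss)
  pha <- box_downsample(pha_f, ss)
  complex_object(amp, pha, pixel_um, truth = truth)
}
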