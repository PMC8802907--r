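# Shared fixture builders. Everything is generated in code at test time.

# optical_system whose camera pitch matches an object pixel p and camera
# downsampling factor f (avoids the consistency warning in simulations)
matched_config <- function(na, mag, pixel_um, f) {
  optical_system(na, mag, 150, 180, 0.53,
                 camera_pixel_um = pixel_um * f *
                   effective_magnification(mag, 150, 180))
}

# random complex object whose spectrum is confined to a centered disk of
# radius `radius_px` (so a pupil at least that large acts as the identity)
make_bandlimited_object <- function(n, pixel_um, radius_px, seed = 1) {
  set.seed(seed)
  S <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  q <- seq_len(n) - (floor(n / 2) + 1)
  k2 <- outer(q^2, q^2, `+`)
  S[k2 > radius_px^2] <- 0
  s <- fpmicro:::cifft2(S)
  # affine map keeps the field band-limited (only adds a DC term)
  s <- 0.5 + 0.2 * s / max(Mod(s))
  complex_object(Mod(s), Arg(s), pixel_um)
}

# single-entry plan holding only the on-axis LED
on_axis_plan <- function(plan) plan[plan$row == 0 & plan$col == 0, , drop = FALSE]

# relative RMS error between a reconstructed and a true complex field after
# global-phase alignment
aligned_rel_rms <- function(rec_field, true_field) {
  g <- sum(Conj(rec_field) * true_field)
  g <- g / Mod(g)
  sqrt(sum(Mod(rec_field * g - true_field)^2) / sum(Mod(true_field)^2))
}

# circular shift helper (independent of the package's internal one)
circ_shift <- function(m, dy, dx) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[((seq_len(n1) - 1 - dy) %% n1) + 1, ((seq_len(n2) - 1 - dx) %% n2) + 1]
}
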