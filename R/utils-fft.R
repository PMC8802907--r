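# Internal FFT plumbing. All spectra in this package live on "centered"
# grids: the DC bin sits at index floor(n/2) + 1 along each dimension, so a
# spatial frequency offset of q pixels is an index offset of q from that bin.

#' @noRd
fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  x[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

#' @noRd
ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- ceiling(n1 / 2); s2 <- ceiling(n2 / 2)
  x[c((s1 + 1):n1, seq_len(s1)), c((s2 + 1):n2, seq_len(s2)), drop = FALSE]
}

# Centered unnormalized 2-D DFT and its (1/N-normalized) inverse.
#' @noRd
cfft2 <- function(x) fftshift2(stats::fft(ifftshift2(x)))

#' @noRd
cifft2 <- function(x) fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / length(x)

# Centered frequency indices for an n-point grid: 0 at floor(n/2)+1.
#' @noRd
centered_freqs <- function(n) seq_len(n) - (floor(n / 2) + 1)

# Index of the DC bin.
#' @noRd
dc_index <- function(n) floor(n / 2) + 1

# Box-average downsampling by an integer factor (models camera pixel
# integration). `f` must divide both dimensions.
#' @noRd
box_downsample <- function(x, f) {
  stopifnot(f >= 1, nrow(x) %% f == 0, ncol(x) %% f == 0)
  if (f == 1) return(x)
  n1 <- nrow(x) %/% f; n2 <- ncol(x) %/% f
  dim(x) <- c(f, n1, f, n2)
  out <- apply(x, c(2, 4), mean)
  matrix(out, n1, n2)
}

# Bilinear upsampling of a matrix by an integer factor, treating samples as
# pixel centers on a periodic (circular) domain — periodicity keeps the
# whole simulate/reconstruct pipeline exactly shift-equivariant.
#' @noRd
bilinear_upsample <- function(x, f) {
  stopifnot(f >= 1)
  if (f == 1) return(x)
  n1 <- nrow(x); n2 <- ncol(x)
  src <- function(n) (seq_len(n * f) - 0.5) / f + 0.5
  interp_axis <- function(m, pos, n) {
    lo <- floor(pos)
    w <- pos - lo
    loi <- ((lo - 1) %% n) + 1
    hii <- (lo %% n) + 1
    m[loi, , drop = FALSE] * (1 - w) + m[hii, , drop = FALSE] * w
  }
  y <- interp_axis(x, src(n1), n1)
  t(interp_axis(t(y), src(n2), n2))
}

# Restore-on-exit scoped RNG: run `expr` under set.seed(seed) without
# disturbing the caller's RNG stream. seed = NULL runs expr as-is.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
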