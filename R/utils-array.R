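# Internal array helpers shared by the hypercomplex processing machinery.
# All grids are real arrays whose first D axes are component axes (length 2,
# one per dimension) and whose last D axes are time/frequency axes.

# Extract a slice along one axis, keeping the number of dimensions.
slice_axis <- function(x, axis, idx) {
  ix <- lapply(dim(x), seq_len)
  ix[[axis]] <- idx
  do.call(`[`, c(list(x), ix, list(drop = FALSE)))
}

# Assign into a slice along one axis.
set_slice_axis <- function(x, axis, idx, value) {
  ix <- lapply(dim(x), seq_len)
  ix[[axis]] <- idx
  do.call(`[<-`, c(list(x), ix, list(value = value)))
}

# Zero-pad an array along one axis up to n_new points.
pad_axis <- function(x, axis, n_new) {
  dm <- dim(x)
  if (n_new < dm[axis]) stop("pad_axis: cannot shrink an axis")
  if (n_new == dm[axis]) return(x)
  dm2 <- dm
  dm2[axis] <- n_new
  out <- array(0, dim = dm2)
  set_slice_axis(out, axis, seq_len(dm[axis]), x)
}

# Multiply along one axis by a vector (e.g. an apodization window or a
# (-1)^k alternation).
scale_axis <- function(x, axis, w) {
  dm <- dim(x)
  stopifnot(length(w) == dm[axis])
  perm <- c(axis, seq_along(dm)[-axis])
  y <- aperm(x, perm)
  y <- y * w                       # axis is now fastest-varying
  aperm(y, order(perm))
}

# Complex Fourier transform of one dimension of a hypercomplex array:
# the two entries of `comp_axis` are treated as real/imaginary parts of a
# complex signal along `time_axis`. Forward transform matches stats::fft
# (negative exponent), so a modulation exp(+i*Omega*t) appears at the
# positive-frequency bin. The inverse divides by the axis length, making
# ft_pair(ft_pair(x), inverse = TRUE) the identity.
ft_pair <- function(x, comp_axis, time_axis, inverse = FALSE) {
  dm <- dim(x)
  stopifnot(dm[comp_axis] == 2L)
  rest <- setdiff(seq_along(dm), c(comp_axis, time_axis))
  perm <- c(comp_axis, time_axis, rest)
  y <- aperm(x, perm)
  n <- dm[time_axis]
  m <- length(y) / (2L * n)
  y <- array(y, dim = c(2L, n, m))
  z <- matrix(complex(real = y[1L, , ], imaginary = y[2L, , ]), nrow = n)
  z <- stats::mvfft(z, inverse = inverse)
  if (inverse) z <- z / n
  y[1L, , ] <- Re(z)
  y[2L, , ] <- Im(z)
  y <- array(y, dim = dm[perm])
  aperm(y, order(perm))
}

# Reorder one frequency axis from fft bin order (0 .. N-1) to centred order
# (-floor(N/2) .. ceiling(N/2)-1), i.e. the usual fftshift.
fftshift_axis <- function(x, axis) {
  n <- dim(x)[axis]
  idx <- c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))
  slice_axis(x, axis, idx)
}

# Centred frequency offsets (Hz) for an N-point axis of spectral width sw,
# matching fftshift_axis ordering.
freq_axis_hz <- function(n, sw) {
  (seq_len(n) - 1L - floor(n / 2)) * sw / n
}

# Restore the RNG state on exit; used so seeded helpers do not disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
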