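#' Describe one dimension of a multidimensional NMR experiment
#'
#' A dimension is either the directly detected axis (`role = "direct"`,
#' quadrature `"simple"`, i.e. ordinary complex detection) or an indirectly
#' incremented axis whose frequency discrimination uses one of the
#' phase-sensitive quadrature schemes: `"states"` (cosine/sine component
#' pairs), `"states_tppi"` (States with per-increment sign alternation,
#' shifting apparent frequencies by half the spectral width) or
#' `"echo_antiecho"` (p-/n-type pathway selection, the encoding produced by
#' preserved-pathway transfers, to be recombined Rance-Kay style before
#' Fourier processing).
#'
#' @param label Short axis name, e.g. `"N"` or `"Hdet"`. Must be unique
#'   within an experiment.
#' @param nucleus Nucleus observed on this axis, e.g. `"1H"`, `"15N"`, `"13C"`.
#' @param role `"direct"` or `"indirect"`.
#' @param quadrature One of `"simple"`, `"states"`, `"states_tppi"`,
#'   `"echo_antiecho"`. Direct dimensions must be `"simple"`; indirect
#'   dimensions must not be.
#' @param n_complex_points Number of complex points (time increments) on the
#'   axis; positive integer.
#' @param spectral_width Spectral width in Hz (> 0); the dwell time is its
#'   reciprocal.
#' @param observe_frequency Larmor frequency in MHz, used for Hz-to-ppm
#'   conversion (> 0).
#' @param carrier Carrier position in ppm; a resonance with zero frequency
#'   offset appears here.
#'
#' @return An object of class `"nmr_dim"`.
#' @examples
#' dim_spec("N", "15N", "indirect", "echo_antiecho", 16, 2000, 81.1, 118)
#' @export
dim_spec <- function(label, nucleus, role = c("direct", "indirect"),
                     quadrature = c("simple", "states", "states_tppi",
                                    "echo_antiecho"),
                     n_complex_points, spectral_width, observe_frequency,
                     carrier = 0) {
  role <- match.arg(role)
  quadrature <- match.arg(quadrature)
  if (role == "direct" && quadrature != "simple") {
    stop("a direct dimension must use simple (complex) quadrature")
  }
  if (role == "indirect" && quadrature == "simple") {
    stop("an indirect dimension needs a phase-sensitive quadrature scheme")
  }
  n_complex_points <- as.integer(n_complex_points)
  if (n_complex_points < 1L) stop("n_complex_points must be >= 1")
  if (spectral_width <= 0) stop("spectral_width must be positive")
  if (observe_frequency <= 0) stop("observe_frequency must be positive")
  structure(
    list(label = as.character(label), nucleus = as.character(nucleus),
         role = role, quadrature = quadrature,
         n_complex_points = n_complex_points,
         spectral_width = as.numeric(spectral_width),
         observe_frequency = as.numeric(observe_frequency),
         carrier = as.numeric(carrier),
         domain = "time"),
    class = "nmr_dim")
}

#' @export
print.nmr_dim <- function(x, ...) {
  cat(sprintf("<nmr_dim> %s (%s, %s, %s): %d pts, sw %.1f Hz, %.1f MHz, carrier %.2f ppm, %s domain\n",
              x$label, x$nucleus, x$role, x$quadrature, x$n_complex_points,
              x$spectral_width, x$observe_frequency, x$carrier, x$domain))
  invisible(x)
}

# Internal accessors ---------------------------------------------------------

n_dims <- function(grid) length(grid$dims)
dim_labels <- function(grid) vapply(grid$dims, `[[`, "", "label")

dim_index <- function(grid, label) {
  i <- match(label, dim_labels(grid))
  if (is.na(i)) stop(sprintf("unknown dimension label '%s'", label))
  i
}

comp_axis <- function(grid, i) i
time_axis <- function(grid, i) n_dims(grid) + i

indirect_indices <- function(grid) {
  which(vapply(grid$dims, function(d) d$role == "indirect", TRUE))
}

direct_index <- function(grid) {
  which(vapply(grid$dims, function(d) d$role == "direct", TRUE))
}

#' Hypercomplex time-domain data grid
#'
#' Container for raw multidimensional NMR data. Each of the D dimensions
#' carries two components: for the direct dimension the real/imaginary parts
#' of the detected complex FID; for a States(-TPPI) dimension the cosine- and
#' sine-modulated FIDs; for an echo-antiecho dimension the echo (+Omega
#' evolution) and antiecho (-Omega) FIDs. The 2^D component FIDs are stored
#' in a single real array whose first D axes are the component axes (length
#' 2, one per dimension, in dimension order) followed by the D time axes.
#'
#' @param dims List of [dim_spec()] objects, indirect dimensions first in
#'   acquisition order (outermost incremented loop first), the single direct
#'   dimension last.
#' @param data Real array of dimension `c(rep(2, D), n_1, ..., n_D)`. If
#'   `NULL`, an all-zero grid is created.
#' @param meta Named list of provenance information (transfer scheme, noise
#'   sigma, seed, applied processing); carried through all operations.
#'
#' @return An object of class `"hc_grid"`.
#' @export
hc_grid <- function(dims, data = NULL, meta = list()) {
  if (!length(dims) || !all(vapply(dims, inherits, TRUE, "nmr_dim"))) {
    stop("dims must be a non-empty list of dim_spec() objects")
  }
  labs <- vapply(dims, `[[`, "", "label")
  if (anyDuplicated(labs)) stop("dimension labels must be unique")
  roles <- vapply(dims, `[[`, "", "role")
  if (sum(roles == "direct") != 1L) {
    stop("exactly one direct dimension is required")
  }
  if (roles[length(roles)] != "direct") {
    stop("the direct dimension must be listed last")
  }
  D <- length(dims)
  np <- vapply(dims, function(d) as.integer(d$n_complex_points), 1L)
  want <- c(rep(2L, D), np)
  if (is.null(data)) {
    data <- array(0, dim = want)
  } else {
    if (!is.numeric(data) || !identical(as.integer(dim(data)), want)) {
      stop(sprintf("data must be a real array of dimension (%s)",
                   paste(want, collapse = ", ")))
    }
  }
  structure(list(dims = dims, data = data, meta = meta), class = "hc_grid")
}

#' @export
print.hc_grid <- function(x, ...) {
  cat(sprintf("<hc_grid> %dD hypercomplex data (%d component FIDs per increment)\n",
              n_dims(x), 2^length(indirect_indices(x))))
  for (d in x$dims) print(d)
  invisible(x)
}

# Time vector (s) for one dimension.
time_points <- function(d) (seq_len(d$n_complex_points) - 1L) / d$spectral_width

#' Recombine an echo-antiecho dimension to States quadrature (Rance-Kay)
#'
#' Applies the fixed linear recombination that converts the two
#' pathway-selected FIDs of an echo-antiecho dimension into the cosine/sine
#' pair of an equivalent States acquisition. The convention is: echo
#' `E(t) = a exp(+i Omega t - R t)`, antiecho `A(t) = a exp(-i Omega t - R t)`,
#' cosine component `(E + A)/2`, sine component `(E - A)/(2i)` (the division
#' by `i` is the 90-degree zero-order phase that makes the pair directly
#' States-processable). With this scaling a noiseless echo-antiecho data set
#' recombines to exactly the States encoding of the same resonances, and two
#' components carrying independent noise of standard deviation `sigma` yield
#' recombined components with noise `sigma/sqrt(2)` each -- the origin of the
#' sqrt(2) sensitivity gain per preserved-pathway dimension.
#'
#' Recombination acts per time increment, so it commutes with sampling masks
#' and with Fourier transforms of other dimensions; it must however precede
#' any Fourier transform (or reconstruction) of its own dimension.
#'
#' @param grid A [hc_grid()].
#' @param dim Label of an `echo_antiecho` dimension.
#' @return The grid with that dimension converted to `states` quadrature.
#' @export
recombine_echo_antiecho <- function(grid, dim) {
  stopifnot(inherits(grid, "hc_grid"))
  i <- dim_index(grid, dim)
  d <- grid$dims[[i]]
  if (d$quadrature != "echo_antiecho") {
    stop(sprintf("dimension '%s' is not echo-antiecho encoded", dim))
  }
  if (d$domain != "time") {
    stop("recombination must be applied in the time domain")
  }
  D <- n_dims(grid)
  idir <- direct_index(grid)
  x <- grid$data
  # Complex FID values live on the direct dimension's component pair.
  e_re <- slice_axis(slice_axis(x, i, 1L), idir, 1L)
  e_im <- slice_axis(slice_axis(x, i, 1L), idir, 2L)
  a_re <- slice_axis(slice_axis(x, i, 2L), idir, 1L)
  a_im <- slice_axis(slice_axis(x, i, 2L), idir, 2L)
  # cos = (E + A)/2 ; sin = (E - A)/(2i) = -i (E - A)/2
  cos_re <- (e_re + a_re) / 2
  cos_im <- (e_im + a_im) / 2
  sin_re <- (e_im - a_im) / 2
  sin_im <- -(e_re - a_re) / 2
  x <- set_slice_axis(x, i, 1L, set_slice_axis(
    set_slice_axis(slice_axis(x, i, 1L), idir, 1L, cos_re), idir, 2L, cos_im))
  x <- set_slice_axis(x, i, 2L, set_slice_axis(
    set_slice_axis(slice_axis(x, i, 2L), idir, 1L, sin_re), idir, 2L, sin_im))
  grid$data <- x
  grid$dims[[i]]$quadrature <- "states"
  grid$meta$recombined <- c(grid$meta$recombined, dim)
  grid$meta$rance_kay_convention <- "cos=(E+A)/2, sin=(E-A)/(2i), echo=+Omega"
  grid
}

#' Convert a States-TPPI dimension to plain States quadrature
#'
#' States-TPPI alternates the receiver reference so that the recorded
#' components carry an extra factor `(-1)^k` per increment `k`, equivalent to
#' shifting every apparent frequency by half the spectral width. Multiplying
#' increment `k` by `(-1)^k` removes the alternation (undoing the
#' half-spectral-width origin shift), after which Fourier processing places
#' each resonance at its true offset from the carrier.
#'
#' @param grid A [hc_grid()].
#' @param dim Label of a `states_tppi` dimension.
#' @return The grid with that dimension in `states` quadrature.
#' @export
states_tppi_to_states <- function(grid, dim) {
  stopifnot(inherits(grid, "hc_grid"))
  i <- dim_index(grid, dim)
  d <- grid$dims[[i]]
  if (d$quadrature != "states_tppi") {
    stop(sprintf("dimension '%s' is not States-TPPI encoded", dim))
  }
  if (d$domain != "time") stop("TPPI conversion must precede Fourier processing")
  alt <- (-1)^(seq_len(d$n_complex_points) - 1L)
  grid$data <- scale_axis(grid$data, time_axis(grid, i), alt)
  grid$dims[[i]]$quadrature <- "states"
  grid$meta$tppi_converted <- c(grid$meta$tppi_converted, dim)
  grid
}

# Apodization window for one dimension. `spec` is NULL (none) or a list with
# type "exp" (lb = line broadening in Hz) or "cosine" (half-cosine bell).
apod_window <- function(d, spec) {
  t <- time_points(d)
  if (is.null(spec) || identical(spec$type, "none")) return(rep(1, length(t)))
  switch(spec$type,
         exp = exp(-pi * (spec$lb %||% 1) * t),
         cosine = cos(pi * seq(0, 0.5, length.out = length(t) + 1L)[seq_along(t)]),
         stop(sprintf("unknown apodization type '%s'", spec$type)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fourier transform a single dimension of a hypercomplex grid
#'
#' Applies (optional) apodization, zero filling and the complex Fourier
#' transform that pairs the dimension's two components as real/imaginary
#' parts. Indirect dimensions must already be in `states` quadrature
#' (echo-antiecho data must be recombined first, States-TPPI converted
#' first); after the transform the dimension's components hold the real and
#' imaginary parts of its spectrum and its `domain` is `"frequency"`.
#' Exposed separately so that mixed States / echo-antiecho data can be
#' processed dimension by dimension in any order.
#'
#' @param grid A [hc_grid()].
#' @param dim Dimension label.
#' @param zero_fill Integer zero-filling factor (1 = none, 2 = double the
#'   number of points, ...).
#' @param apodization `NULL`, or a list such as `list(type = "exp", lb = 10)`
#'   or `list(type = "cosine")`.
#' @return The grid with that dimension transformed.
#' @export
ft_dimension <- function(grid, dim, zero_fill = 1, apodization = NULL) {
  stopifnot(inherits(grid, "hc_grid"))
  i <- dim_index(grid, dim)
  d <- grid$dims[[i]]
  if (d$domain != "time") stop(sprintf("dimension '%s' is already transformed", dim))
  if (d$role == "indirect" && d$quadrature == "echo_antiecho") {
    stop(sprintf(paste0("dimension '%s' is echo-antiecho encoded and must be ",
                        "recombined (recombine_echo_antiecho) before Fourier ",
                        "processing"), dim))
  }
  if (d$role == "indirect" && d$quadrature == "states_tppi") {
    stop(sprintf("dimension '%s' is States-TPPI encoded; convert it first (states_tppi_to_states)",
                 dim))
  }
  zero_fill <- as.integer(zero_fill)
  if (zero_fill < 1L) stop("zero_fill must be a positive integer factor")
  ta <- time_axis(grid, i)
  x <- grid$data
  if (!is.null(apodization)) {
    x <- scale_axis(x, ta, apod_window(d, apodization))
  }
  n_new <- d$n_complex_points * zero_fill
  x <- pad_axis(x, ta, n_new)
  x <- ft_pair(x, comp_axis(grid, i), ta)
  grid$data <- x
  grid$dims[[i]]$n_complex_points <- n_new
  grid$dims[[i]]$domain <- "frequency"
  grid$meta$processing[[d$label]] <- list(zero_fill = zero_fill,
                                          apodization = apodization)
  grid
}

#' Convert every indirect dimension to States quadrature
#'
#' Convenience wrapper applying [recombine_echo_antiecho()] to every
#' echo-antiecho dimension and [states_tppi_to_states()] to every
#' States-TPPI dimension, the preprocessing required before Fourier
#' processing or reconstruction.
#'
#' @param grid A time-domain [hc_grid()].
#' @return The grid with all indirect dimensions in `states` quadrature.
#' @export
to_states <- function(grid) {
  stopifnot(inherits(grid, "hc_grid"))
  for (i in indirect_indices(grid)) {
    q <- grid$dims[[i]]$quadrature
    lab <- grid$dims[[i]]$label
    if (q == "echo_antiecho") grid <- recombine_echo_antiecho(grid, lab)
    if (q == "states_tppi") grid <- states_tppi_to_states(grid, lab)
  }
  grid
}

#' Processed frequency-domain spectrum
#'
#' Real (absorptive) amplitudes on a rectangular ppm grid, one strictly
#' monotone ppm axis per retained dimension, plus processing provenance.
#' Usually produced by [hypercomplex_ft()], [nuft()] or [ist_reconstruct()].
#'
#' @param axes Named list of strictly monotone numeric ppm axes.
#' @param values Real array; `dim(values)` must match the axis lengths.
#' @param meta Named provenance list.
#' @return An object of class `"nmr_spectrum"`.
#' @export
spectrum_grid <- function(axes, values, meta = list()) {
  if (is.null(dim(values))) dim(values) <- length(values)
  if (length(axes) != length(dim(values))) {
    stop("one axis per dimension of values is required")
  }
  for (a in axes) {
    if (length(a) > 1L && !(all(diff(a) > 0) || all(diff(a) < 0))) {
      stop("spectrum axes must be strictly monotone")
    }
  }
  if (!identical(as.integer(lengths(axes)), as.integer(dim(values)))) {
    stop("axis lengths must match the value array")
  }
  structure(list(axes = axes, values = values, meta = meta),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s points (%s)\n",
              paste(dim(x$values), collapse = " x "),
              paste(names(x$axes), collapse = ", ")))
  invisible(x)
}

# ppm axis of a fully transformed dimension, centred (fftshift order),
# strictly increasing.
ppm_axis <- function(d) {
  f <- freq_axis_hz(d$n_complex_points, d$spectral_width)
  d$carrier + f / d$observe_frequency
}

#' Index of the axis point nearest a ppm value
#' @param axis Monotone numeric ppm axis.
#' @param ppm Target position.
#' @return Integer index.
#' @export
ppm_to_index <- function(axis, ppm) which.min(abs(axis - ppm))

# Extract the absorptive spectrum from a grid whose dimensions have all been
# Fourier transformed: take the all-real component and fftshift every
# frequency axis so that the carrier sits at the centre.
as_spectrum <- function(grid) {
  D <- n_dims(grid)
  if (!all(vapply(grid$dims, function(d) d$domain == "frequency", TRUE))) {
    stop("all dimensions must be Fourier transformed first")
  }
  x <- grid$data
  for (i in seq_len(D)) x <- slice_axis(x, i, 1L)   # all-real component
  dim(x) <- vapply(grid$dims, function(d) as.integer(d$n_complex_points), 1L)
  for (i in seq_len(D)) x <- fftshift_axis(x, i)
  axes <- lapply(grid$dims, ppm_axis)
  names(axes) <- dim_labels(grid)
  spectrum_grid(axes, x, meta = grid$meta)
}

#' Hypercomplex Fourier transform to an absorptive spectrum
#'
#' Processes every dimension of a hypercomplex grid: complex FT of the
#' directly detected dimension and, per indirect dimension, the States FT in
#' which the cosine/sine components supply the real/imaginary interferogram
#' parts. All indirect dimensions must be in `states` quadrature on entry --
#' echo-antiecho dimensions must be recombined first (this ordering is the
#' key workflow constraint of preserved-pathway processing) and States-TPPI
#' dimensions converted first; violations raise an error. The operation is
#' linear in the input. Returns the purely absorptive real spectrum (valid
#' for the zero-phase signals produced by [simulate_experiment()]); the
#' processing parameters are recorded in the spectrum's `meta`.
#'
#' @param grid A [hc_grid()].
#' @param zero_fill Zero-filling factor, a single integer or one per
#'   dimension (default 2).
#' @param apodization `NULL`, a single window spec applied to all dimensions,
#'   or a named list of per-dimension window specs (see [ft_dimension()]).
#' @return An [spectrum_grid()] object.
#' @export
hypercomplex_ft <- function(grid, zero_fill = 2, apodization = NULL) {
  stopifnot(inherits(grid, "hc_grid"))
  D <- n_dims(grid)
  labs <- dim_labels(grid)
  zf <- if (length(zero_fill) == 1L) rep(zero_fill, D) else zero_fill
  if (length(zf) != D) stop("zero_fill must have length 1 or one per dimension")
  per_dim_apod <- !is.null(apodization) && is.null(apodization$type)
  for (i in seq_len(D)) {
    if (grid$dims[[i]]$domain == "frequency") next
    ap <- if (per_dim_apod) apodization[[labs[i]]] else apodization
    grid <- ft_dimension(grid, labs[i], zero_fill = zf[i], apodization = ap)
  }
  as_spectrum(grid)
}
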