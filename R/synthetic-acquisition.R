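#' Resonance (peak) in the multidimensional signal model
#'
#' A resonance contributes, per dimension, an exponentially decaying
#' oscillation: the direct dimension contributes
#' `a * exp(i 2 pi Omega t - R t)`; an indirect dimension contributes the
#' component-dependent modulation dictated by the transfer scheme (see
#' [simulate_experiment()]).
#'
#' @param offsets Named numeric vector of frequency offsets Omega from the
#'   carrier, in Hz, one entry per dimension label.
#' @param amplitude Signal amplitude `a` (arbitrary units).
#' @param decays Named numeric vector of decay rates R in 1/s (>= 0); missing
#'   labels default to 0 (no decay).
#' @return An object of class `"resonance"`.
#' @export
resonance <- function(offsets, amplitude = 1, decays = NULL) {
  if (is.null(names(offsets)) || any(!nzchar(names(offsets)))) {
    stop("offsets must be named by dimension label")
  }
  if (is.null(decays)) decays <- setNames(numeric(length(offsets)), names(offsets))
  if (any(decays < 0)) stop("decay rates must be >= 0")
  structure(list(offsets = offsets, amplitude = as.numeric(amplitude),
                 decays = decays), class = "resonance")
}

#' Per-dimension magnetization transfer scheme
#'
#' Describes how each indirect dimension of an experiment is encoded:
#' `"cp_states"` / `"cp_states_tppi"` model a conventional cross-polarization
#' transfer that retains a single transverse component (unit relative
#' amplitude, States or States-TPPI frequency discrimination), while
#' `"trop_echo_antiecho"` models a preserved-pathway (transverse-mixing
#' optimal-control) transfer that retains both components at bulk efficiency
#' `b` each, encoded echo-antiecho. `b` is the per-component amplitude
#' relative to the CP transfer; it is fixed at 1 for the cp modes by
#' definition.
#'
#' @param modes Named character vector, one mode per indirect dimension
#'   label; values in `c("cp_states", "cp_states_tppi", "trop_echo_antiecho")`.
#' @param bulk Bulk efficiency `b` (> 0): a single value or a named vector
#'   per enhanced dimension. Ignored (forced to 1) for cp modes.
#' @return An object of class `"transfer_scheme"`.
#' @examples
#' transfer_scheme(c(N = "trop_echo_antiecho", CO = "cp_states"), bulk = 0.85)
#' @export
transfer_scheme <- function(modes, bulk = 1) {
  valid <- c("cp_states", "cp_states_tppi", "trop_echo_antiecho")
  if (is.null(names(modes)) || any(!nzchar(names(modes)))) {
    stop("modes must be named by indirect dimension label")
  }
  if (!all(modes %in% valid)) {
    stop("modes must be one of: ", paste(valid, collapse = ", "))
  }
  if (any(bulk <= 0)) stop("bulk efficiency b must be positive")
  b <- if (length(bulk) == 1L) setNames(rep(as.numeric(bulk), length(modes)),
                                        names(modes)) else bulk[names(modes)]
  b[modes != "trop_echo_antiecho"] <- 1
  structure(list(modes = modes, bulk = b), class = "transfer_scheme")
}

#' Conventional (all-CP) counterpart of a transfer scheme
#'
#' Replaces every preserved-pathway transfer by a plain CP/States transfer at
#' unit amplitude, giving the reference experiment against which enhancement
#' is measured.
#'
#' @param scheme A [transfer_scheme()].
#' @return A [transfer_scheme()] with all modes `"cp_states"` (States-TPPI
#'   dimensions are kept as such).
#' @export
conventional_scheme <- function(scheme) {
  modes <- scheme$modes
  modes[modes == "trop_echo_antiecho"] <- "cp_states"
  transfer_scheme(modes, bulk = 1)
}

#' Thermal noise model
#'
#' Independent complex Gaussian noise added to every recorded point of every
#' component FID: real and imaginary detector channels each receive
#' `N(0, sigma^2)` noise. Thermal noise is receiver-determined, so the same
#' `sigma` applies to conventional and preserved-pathway acquisitions of
#' equal duration.
#'
#' @param sigma Per-point standard deviation (>= 0).
#' @param seed Integer seed making the realization reproducible, or `NULL`.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sigma = 0, seed = NULL) {
  if (sigma < 0) stop("noise sigma must be >= 0")
  structure(list(sigma = as.numeric(sigma), seed = seed),
            class = "noise_model")
}

mode_quadrature <- function(mode) {
  switch(mode,
         cp_states = "states",
         cp_states_tppi = "states_tppi",
         trop_echo_antiecho = "echo_antiecho")
}

# Component modulation factors for one indirect dimension and one resonance:
# a complex 2 x n matrix (rows = the two hypercomplex components).
transfer_factors <- function(mode, b, omega, r, t) {
  dec <- exp(-r * t)
  ph <- 2 * pi * omega * t
  switch(mode,
         cp_states = rbind(cos(ph) * dec, sin(ph) * dec) + 0i,
         cp_states_tppi = {
           alt <- (-1)^(seq_along(t) - 1L)
           rbind(cos(ph) * dec * alt, sin(ph) * dec * alt) + 0i
         },
         trop_echo_antiecho = rbind(b * exp(1i * ph) * dec,
                                    b * exp(-1i * ph) * dec),
         stop("unknown transfer mode"))
}

#' Simulate a multidimensional acquisition
#'
#' Generates the full hypercomplex data set of a synthetic experiment: for
#' each hypercomplex component vector, the FID is the sum over resonances of
#' a separable product over dimensions. The direct dimension contributes
#' `a exp(i 2 pi Omega t - R t)`; a `cp_states` dimension contributes
#' `cos(2 pi Omega t) exp(-R t)` or `sin(...) exp(-R t)` (the single
#' transferred component, unit relative amplitude; `cp_states_tppi`
#' additionally alternates the sign per increment); a `trop_echo_antiecho`
#' dimension contributes `b exp(+/- i 2 pi Omega t - R t)` for the
#' echo/antiecho component. Independent complex Gaussian noise of standard
#' deviation `sigma` is added to every recorded point of every component
#' FID. Identical inputs and seed give bit-identical output.
#'
#' @param resonances List of [resonance()] objects (possibly empty).
#' @param dims List of [dim_spec()] objects, indirect first, one direct last.
#'   Indirect quadratures are set from the transfer scheme.
#' @param scheme A [transfer_scheme()] covering every indirect dimension.
#' @param noise A [noise_model()].
#' @return A [hc_grid()] with provenance (`scheme`, `sigma`, `seed`) in `meta`.
#' @export
simulate_experiment <- function(resonances, dims, scheme,
                                noise = noise_model(0)) {
  stopifnot(inherits(scheme, "transfer_scheme"), inherits(noise, "noise_model"))
  if (inherits(resonances, "resonance")) resonances <- list(resonances)
  labs <- vapply(dims, `[[`, "", "label")
  roles <- vapply(dims, `[[`, "", "role")
  ind <- which(roles == "indirect")
  if (!setequal(names(scheme$modes), labs[ind])) {
    stop("transfer scheme must cover exactly the indirect dimensions")
  }
  # stamp quadratures dictated by the scheme
  for (i in ind) {
    dims[[i]]$quadrature <- mode_quadrature(scheme$modes[[labs[i]]])
  }
  grid <- hc_grid(dims)
  D <- n_dims(grid)
  m <- length(ind)
  idir <- direct_index(grid)
  ddir <- dims[[idir]]
  tdir <- time_points(ddir)
  np_ind <- vapply(dims[ind], `[[`, 1L, "n_complex_points")

  # per-resonance, per-indirect-dim 2 x n modulation matrices
  comp_vectors <- if (m > 0L) {
    as.matrix(expand.grid(rep(list(1:2), m), KEEP.OUT.ATTRS = FALSE))
  } else matrix(integer(0), nrow = 1L, ncol = 0L)

  for (cv in seq_len(nrow(comp_vectors))) {
    total <- array(0 + 0i, dim = c(np_ind, ddir$n_complex_points))
    for (res in resonances) {
      miss <- setdiff(labs, names(res$offsets))
      if (length(miss)) {
        stop("resonance lacks offsets for dimension(s): ",
             paste(miss, collapse = ", "))
      }
      facs <- vector("list", m + 1L)
      for (k in seq_len(m)) {
        i <- ind[k]
        d <- dims[[i]]
        om <- res$offsets[[d$label]]
        if (abs(om) > d$spectral_width / 2) {
          stop(sprintf("resonance offset %.1f Hz exceeds half the spectral width of '%s'",
                       om, d$label))
        }
        rk <- res$decays[d$label]
        if (is.na(rk)) rk <- 0
        g <- transfer_factors(scheme$modes[[d$label]], scheme$bulk[[d$label]],
                              om, rk, time_points(d))
        facs[[k]] <- g[comp_vectors[cv, k], ]
      }
      om_d <- res$offsets[[ddir$label]]
      if (abs(om_d) > ddir$spectral_width / 2) {
        stop(sprintf("resonance offset %.1f Hz exceeds half the spectral width of '%s'",
                     om_d, ddir$label))
      }
      rd <- res$decays[ddir$label]
      if (is.na(rd)) rd <- 0
      facs[[m + 1L]] <- res$amplitude *
        exp((2i * pi * om_d - rd) * tdir)
      fid <- Reduce(outer, facs)
      total <- total + array(fid, dim = dim(total))
    }
    # place Re/Im on the direct component pair
    for (cd in 1:2) {
      part <- if (cd == 1L) Re(total) else Im(total)
      ix <- lapply(dim(grid$data), seq_len)
      for (k in seq_len(m)) ix[[ind[k]]] <- comp_vectors[cv, k]
      ix[[idir]] <- cd
      grid$data <- do.call(`[<-`, c(list(grid$data), ix, list(value = part)))
    }
  }

  if (noise$sigma > 0) {
    grid$data <- with_seed(noise$seed, {
      grid$data + array(stats::rnorm(length(grid$data), sd = noise$sigma),
                        dim = dim(grid$data))
    })
  }
  grid$meta$scheme <- scheme
  grid$meta$sigma <- noise$sigma
  grid$meta$seed <- noise$seed
  grid
}

#' First FID of an experiment
#'
#' Returns the directly detected complex FID at all-zero indirect time
#' increments for the first hypercomplex component vector. The first FID is
#' the standard probe for bulk-signal comparisons between a
#' preserved-pathway experiment and its conventional counterpart, since at
#' `t_indirect = 0` the indirect modulations reduce to the pure transfer
#' amplitudes.
#'
#' @param grid A [hc_grid()] in the time domain.
#' @return Complex vector of length `n_complex_points` of the direct
#'   dimension.
#' @export
first_fid <- function(grid) {
  stopifnot(inherits(grid, "hc_grid"))
  D <- n_dims(grid)
  idir <- direct_index(grid)
  x <- grid$data
  for (i in indirect_indices(grid)) {
    x <- slice_axis(x, i, 1L)                 # first component
    x <- slice_axis(x, time_axis(grid, i), 1L)  # t = 0
  }
  re <- as.vector(slice_axis(x, idir, 1L))
  im <- as.vector(slice_axis(x, idir, 2L))
  complex(real = re, imaginary = im)
}

# Deterministic peak set drawn inside +/- 0.35 sw with moderate decays.
fixture_peaks <- function(dims, n_peaks, seed, amplitudes) {
  labs <- vapply(dims, `[[`, "", "label")
  with_seed(seed, {
    lapply(seq_len(n_peaks), function(p) {
      off <- vapply(dims, function(d) {
        stats::runif(1, -0.35, 0.35) * d$spectral_width
      }, 1)
      dec <- vapply(dims, function(d) stats::runif(1, 10, 30), 1)
      resonance(setNames(off, labs), amplitude = amplitudes[p],
                decays = setNames(dec, labs))
    })
  })
}

#' Built-in synthetic fixtures
#'
#' Deterministic, documented peak/dimension/scheme bundles sized to run
#' end-to-end in seconds. Available fixtures:
#' \describe{
#'   \item{`toy2d`}{One enhanced (echo-antiecho) 15N dimension (16 points)
#'     plus 1H detection (64 points); 3 peaks.}
#'   \item{`toy3d_mixed_encoding`}{One States 13C' and one echo-antiecho 15N
#'     indirect dimension (12 points each) plus detection (48 points),
#'     exercising mixed-order processing; 3 peaks.}
#'   \item{`toy3d_2enh`}{Two echo-antiecho indirect dimensions (12 points
#'     each) plus detection (48 points); 2 peaks.}
#'   \item{`toy4d_3enh`}{Three echo-antiecho indirect dimensions (8 points
#'     each) plus detection (32 points); 2 peaks.}
#'   \item{`toy5d_3enh_smallgrid`}{Four indirect dimensions, one States-TPPI
#'     and three echo-antiecho (6 points each), plus detection (24 points);
#'     2 peaks.}
#' }
#'
#' @param name Fixture name.
#' @param seed Integer seed controlling the (deterministic) peak placement.
#' @param bulk Bulk efficiency `b` of the enhanced transfers.
#' @return List with elements `name`, `resonances`, `dims`, `scheme`, and
#'   `peaks` (a data frame of peak labels and ppm positions per dimension).
#' @export
fixture_library <- function(name, seed = 1, bulk = 1) {
  hdet <- function(np) dim_spec("Hdet", "1H", "direct", "simple", np,
                                4000, 800, 8.3)
  nd <- function(lab, np, quad = "echo_antiecho")
    dim_spec(lab, "15N", "indirect", quad, np, 2000, 81.1, 118)
  cd <- function(lab, np, quad = "states")
    dim_spec(lab, "13C", "indirect", quad, np, 3000, 201.2, 175)
  fx <- switch(
    name,
    toy2d = {
      dims <- list(nd("N", 16L), hdet(64L))
      list(dims = dims,
           scheme = transfer_scheme(c(N = "trop_echo_antiecho"), bulk),
           resonances = fixture_peaks(dims, 3L, seed, c(1, 0.6, 0.35)))
    },
    toy3d_mixed_encoding = {
      dims <- list(cd("CO", 12L), nd("N", 12L), hdet(48L))
      list(dims = dims,
           scheme = transfer_scheme(c(CO = "cp_states",
                                      N = "trop_echo_antiecho"), bulk),
           resonances = fixture_peaks(dims, 3L, seed, c(1, 0.6, 0.35)))
    },
    toy3d_2enh = {
      dims <- list(cd("CO", 12L, "echo_antiecho"), nd("N", 12L), hdet(48L))
      list(dims = dims,
           scheme = transfer_scheme(c(CO = "trop_echo_antiecho",
                                      N = "trop_echo_antiecho"), bulk),
           resonances = fixture_peaks(dims, 2L, seed, c(1, 0.5)))
    },
    toy4d_3enh = {
      dims <- list(cd("CO", 8L, "echo_antiecho"), cd("CA", 8L, "echo_antiecho"),
                   nd("N", 8L), hdet(32L))
      list(dims = dims,
           scheme = transfer_scheme(c(CO = "trop_echo_antiecho",
                                      CA = "trop_echo_antiecho",
                                      N = "trop_echo_antiecho"), bulk),
           resonances = fixture_peaks(dims, 2L, seed, c(1, 0.5)))
    },
    toy5d_3enh_smallgrid = {
      dims <- list(nd("N1", 6L, "states_tppi"),
                   cd("CO", 6L, "echo_antiecho"), cd("CA", 6L, "echo_antiecho"),
                   nd("N2", 6L), hdet(24L))
      list(dims = dims,
           scheme = transfer_scheme(c(N1 = "cp_states_tppi",
                                      CO = "trop_echo_antiecho",
                                      CA = "trop_echo_antiecho",
                                      N2 = "trop_echo_antiecho"), bulk),
           resonances = fixture_peaks(dims, 2L, seed, c(1, 0.5)))
    },
    stop(sprintf("unknown fixture '%s'", name))
  )
  labs <- vapply(fx$dims, `[[`, "", "label")
  pos <- t(vapply(fx$resonances, function(r) {
    vapply(seq_along(fx$dims), function(i) {
      d <- fx$dims[[i]]
      d$carrier + r$offsets[[d$label]] / d$observe_frequency
    }, 1)
  }, numeric(length(fx$dims))))
  peaks <- as.data.frame(pos)
  names(peaks) <- labs
  peaks <- cbind(label = sprintf("P%d", seq_len(nrow(peaks))), peaks,
                 stringsAsFactors = FALSE)
  c(list(name = name, seed = seed), fx, list(peaks = peaks))
}
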