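#' Generate a non-uniform sampling schedule
#'
#' Selects a subset of the indirect-dimension time grid to be recorded. One
#' schedule "point" means all 2^n hypercomplex components of that time
#' increment. The all-zero increment (origin) is always included, since it
#' anchors the bulk signal. `"uniform_random"` samples without replacement
#' with equal weights; `"exponential_biased"` weights point `(k_1..k_n)` by
#' `exp(-sum(bias_decay_i * k_i / N_i))` before sampling, concentrating
#' samples at early evolution times where decaying signals are strongest;
#' `"full"` keeps the whole grid.
#'
#' @param shape Integer vector: indirect grid dimensions `(N_1, ..., N_n)`.
#' @param fraction Sampled fraction, `0 < fraction <= 1`.
#' @param mode `"uniform_random"`, `"exponential_biased"` or `"full"`.
#' @param seed Integer seed; identical inputs and seed give the identical
#'   schedule.
#' @param bias_decay Per-dimension decay rate of the exponential bias
#'   (recycled; default 2).
#' @return An object of class `"nus_schedule"`: list with `shape`, `points`
#'   (matrix of 0-based multi-indices, one row per sampled increment, in
#'   lexicographic order), `fraction` (realized `|points| / grid size`),
#'   `mode`, `seed`.
#' @export
generate_schedule <- function(shape, fraction = 1,
                              mode = c("uniform_random", "exponential_biased",
                                       "full"),
                              seed = 1, bias_decay = 2) {
  mode <- match.arg(mode)
  shape <- as.integer(shape)
  if (!length(shape) || any(shape < 1L)) stop("empty sampling grid")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  total <- prod(shape)
  grid <- as.matrix(expand.grid(lapply(shape, function(n) 0:(n - 1L)),
                                KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  if (mode == "full" || fraction == 1) {
    pts <- grid
  } else {
    npts <- max(1L, as.integer(round(fraction * total)))
    keep <- with_seed(seed, {
      w <- if (mode == "exponential_biased") {
        bd <- rep_len(bias_decay, length(shape))
        exp(-as.vector(grid %*% (bd / shape)))
      } else rep(1, total)
      origin <- which(rowSums(grid) == 0L)
      w[origin] <- 0          # origin forced in, sample the rest
      extra <- if (npts > 1L) {
        sample(seq_len(total), npts - 1L, prob = w / sum(w))
      } else integer(0)
      sort(unique(c(origin, extra)))
    })
    pts <- grid[keep, , drop = FALSE]
  }
  structure(list(shape = shape, points = pts,
                 fraction = nrow(pts) / total, mode = mode, seed = seed),
            class = "nus_schedule")
}

#' @export
print.nus_schedule <- function(x, ...) {
  cat(sprintf("<nus_schedule> %d / %d points (%.1f%%, %s) on grid (%s)\n",
              nrow(x$points), prod(x$shape), 100 * x$fraction, x$mode,
              paste(x$shape, collapse = " x ")))
  invisible(x)
}

#' Write / read a sampling schedule as plain text
#'
#' Interchange format: one sampled increment per line as space-separated
#' 0-based indices; lines starting with `#` are comments.
#'
#' @param schedule A `"nus_schedule"` object.
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns a `"nus_schedule"` (the `shape` is taken from the header
#'   comment written by `write_schedule`, or from the `shape` argument).
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "nus_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nus schedule: shape %s, mode %s, seed %s",
                     paste(schedule$shape, collapse = " "),
                     schedule$mode, schedule$seed), con)
  writeLines(apply(schedule$points, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_schedule
#' @param shape Grid shape, required if the file has no shape header.
#' @export
read_schedule <- function(path, shape = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#.*shape", lines, value = TRUE)
  if (is.null(shape) && length(hdr)) {
    m <- regmatches(hdr[1], regexpr("shape[ :]+[0-9 ]+", hdr[1]))
    shape <- as.integer(strsplit(sub("shape[ :]+", "", m), " +")[[1]])
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  pts <- do.call(rbind, lapply(strsplit(lines, "[[:space:]]+"), as.integer))
  if (is.null(shape)) stop("grid shape not found in file; pass `shape`")
  if (ncol(pts) != length(shape)) stop("index width does not match shape")
  if (any(pts < 0L) || any(t(pts) >= shape)) stop("indices outside the grid")
  if (anyDuplicated(pts)) stop("duplicate schedule points")
  structure(list(shape = as.integer(shape), points = pts,
                 fraction = nrow(pts) / prod(shape), mode = "from_file",
                 seed = NA_integer_),
            class = "nus_schedule")
}

# Logical mask array over the indirect grid.
schedule_mask <- function(schedule) {
  mask <- array(FALSE, dim = schedule$shape)
  mask[schedule$points + 1L] <- TRUE
  mask
}

#' Apply a sampling schedule to a hypercomplex grid
#'
#' Zeroes every time increment not in the schedule, for all hypercomplex
#' components of that increment (one NUS point = all quadrature components)
#' and all direct-dimension points. The mask is stored in the grid's `meta`
#' for use by [nuft()] and [ist_reconstruct()].
#'
#' @param grid A time-domain [hc_grid()].
#' @param schedule A `"nus_schedule"` whose `shape` matches the indirect
#'   grid.
#' @return The masked grid.
#' @export
apply_schedule <- function(grid, schedule) {
  stopifnot(inherits(grid, "hc_grid"), inherits(schedule, "nus_schedule"))
  ind <- indirect_indices(grid)
  np <- vapply(grid$dims[ind], `[[`, 1L, "n_complex_points")
  if (!identical(as.integer(schedule$shape), as.integer(np))) {
    stop("schedule shape does not match the indirect time grid")
  }
  mask <- schedule_mask(schedule)
  D <- n_dims(grid)
  dm <- dim(grid$data)
  # broadcast: component axes first (fastest), then indirect times, then
  # the direct time axis (slowest)
  ncomp <- 2L^D
  full <- rep(rep(as.numeric(mask), each = ncomp),
              times = grid$dims[[direct_index(grid)]]$n_complex_points)
  grid$data <- grid$data * array(full, dim = dm)
  grid$meta$schedule <- schedule
  grid$meta$mask <- mask
  grid
}

#' Direct Fourier transform of non-uniformly sampled data (nuFT)
#'
#' Zero-filled hypercomplex Fourier transform of the masked data: unsampled
#' increments enter as zeros, so each resonance appears at its correct
#' position convolved with the point-spread function of the schedule.
#' Echo-antiecho dimensions must be recombined first (recombination is a
#' per-increment operation, so it commutes with the sampling mask). With a
#' full schedule the result equals [hypercomplex_ft()] exactly.
#'
#' @param grid A time-domain [hc_grid()], already masked by
#'   [apply_schedule()] or accompanied by `schedule`.
#' @param schedule Optional `"nus_schedule"` to apply first.
#' @param zero_fill,apodization As in [hypercomplex_ft()].
#' @return An [spectrum_grid()]; `meta$schedule` records the sampling.
#' @export
nuft <- function(grid, schedule = NULL, zero_fill = 1, apodization = NULL) {
  stopifnot(inherits(grid, "hc_grid"))
  if (!is.null(schedule)) grid <- apply_schedule(grid, schedule)
  if (is.null(grid$meta$mask)) {
    stop("no sampling mask: pass `schedule` or use apply_schedule() first")
  }
  hypercomplex_ft(grid, zero_fill = zero_fill, apodization = apodization)
}

#' Point-spread function of a sampling schedule
#'
#' The Fourier transform of the schedule's indicator mask over the indirect
#' grid, normalized so the central (zero-frequency) value is 1, with the
#' real (absorptive) part retained to match the real-part processing chain.
#' By the convolution theorem, the nuFT spectrum of a noiseless on-grid
#' resonance equals its height times the PSF circularly shifted to the peak
#' position, so the PSF side-lobe level is exactly the relative artifact
#' level that non-uniform sampling imprints on every signal.
#'
#' @param schedule A `"nus_schedule"`.
#' @param zero_fill Zero-filling factor applied to the mask before the
#'   transform (match the processing of the data it is compared against).
#' @return An [spectrum_grid()] whose axes are dimensionless frequency
#'   bins (cycles per grid length), centred at zero.
#' @export
point_spread_function <- function(schedule, zero_fill = 1) {
  stopifnot(inherits(schedule, "nus_schedule"))
  mask <- schedule_mask(schedule)
  zf <- as.integer(zero_fill)
  dm <- dim(mask) * zf
  big <- array(0, dim = dm)
  ix <- lapply(dim(mask), seq_len)
  big <- do.call(`[<-`, c(list(big), ix, list(value = as.numeric(mask))))
  ft <- stats::fft(big) / sum(mask)
  psf <- Re(ft)
  for (i in seq_along(dm)) psf <- fftshift_axis(psf, i)
  axes <- lapply(dm, function(n) (seq_len(n) - 1L - floor(n / 2)) / zf)
  names(axes) <- sprintf("k%d", seq_along(axes))
  spectrum_grid(axes, psf,
                meta = list(schedule = schedule, zero_fill = zf,
                            part = "real"))
}
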