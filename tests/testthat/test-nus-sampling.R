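test_that("schedules are counted, seeded and anchored at the origin", {
  s <- generate_schedule(c(8, 8), 0.25, "uniform_random", seed = 7)
  expect_identical(nrow(s$points), 16L)
  expect_false(anyDuplicated(s$points) > 0)
  expect_true(any(rowSums(s$points) == 0))
  expect_identical(s$points,
                   generate_schedule(c(8, 8), 0.25, seed = 7)$points)
  expect_equal(s$fraction, 0.25)
  full <- generate_schedule(c(4, 4), 1, "uniform_random")
  expect_identical(nrow(full$points), 16L)
  expect_error(generate_schedule(c(8, 8), 0), "fraction")
  expect_error(generate_schedule(integer(0), 0.5), "empty")
})

test_that("exponential bias concentrates samples at early increments", {
  means <- vapply(c("uniform_random", "exponential_biased"), function(md) {
    mean(vapply(1:300, function(k) {
      mean(generate_schedule(32, 0.25, md, seed = k, bias_decay = 4)$points)
    }, 1))
  }, 1)
  expect_lt(means[["exponential_biased"]], means[["uniform_random"]])
})

test_that("schedule text files round-trip, with comments and validation", {
  s <- generate_schedule(c(6, 5), 0.4, seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_schedule(s, path)
  s2 <- read_schedule(path)
  expect_identical(s2$points, s$points)
  expect_identical(s2$shape, s$shape)
  writeLines(c("# comment", "0 0", "1 2", "1 2"), path)
  expect_error(read_schedule(path, shape = c(4, 4)), "duplicate")
  writeLines(c("0 0", "9 0"), path)
  expect_error(read_schedule(path, shape = c(4, 4)), "outside")
})

test_that("masking zeroes whole increments across all components", {
  g <- sim_2d(list(on_grid_res(3, 5)), "cp_states", sigma = 0.1, seed = 2)
  full <- generate_schedule(16, 1, "full")
  expect_equal(apply_schedule(g, full)$data, g$data)
  origin <- generate_schedule(16, 1 / 16, seed = 1)
  go <- apply_schedule(g, origin)
  expect_true(all(go$data[, , 2:16, ] == 0))
  expect_false(all(go$data[, , 1, ] == 0))
  half <- generate_schedule(16, 0.5, seed = 4)
  gh <- apply_schedule(g, half)
  expect_identical(sum(gh$meta$mask), nrow(half$points))
  bad <- generate_schedule(8, 0.5, seed = 1)
  expect_error(apply_schedule(g, bad), "shape")
})

test_that("nuFT of a full schedule is exactly the hypercomplex FT", {
  g <- sim_2d(list(on_grid_res(4, 8), on_grid_res(-3, 5, 0.6)), "cp_states",
              sigma = 0.05, seed = 9)
  full <- generate_schedule(16, 1, "full")
  expect_identical(nuft(g, full, zero_fill = 2)$values,
                   hypercomplex_ft(g, zero_fill = 2)$values)
  expect_error(nuft(g), "mask")
  gz <- apply_schedule(sim_2d(list(), "cp_states"),
                       generate_schedule(16, 0.5, seed = 2))
  expect_true(all(nuft(gz)$values == 0))
})

test_that("nuFT agrees with a brute-force DFT over the sampled points", {
  n_ind <- 16L
  g <- sim_2d(list(on_grid_res(4, 8)), "cp_states")
  sch <- generate_schedule(n_ind, 0.25, seed = 13)
  sp <- nuft(g, sch, zero_fill = 1)
  # oracle: direct-dimension spectrum is a delta at bin kH = 8; along the
  # indirect dimension the masked interferogram exp(2i pi kN t) is Fourier
  # transformed by explicit summation
  kN <- 4L
  sampled <- sch$points[, 1]
  oracle <- vapply(0:(n_ind - 1L), function(bin) {
    Re(sum(exp(2i * pi * kN * sampled / n_ind) *
             exp(-2i * pi * bin * sampled / n_ind)))
  }, 1) * 32       # direct-dimension delta height (n_dir points)
  hcol <- ppm_to_index(sp$axes$Hdet, 8.3 + 8 * 4000 / 32 / 800)
  got <- sp$values[, hcol]
  shift_ord <- c((floor(n_ind / 2) + 1L):n_ind, seq_len(floor(n_ind / 2)))
  expect_equal(got, oracle[shift_ord], tolerance = 1e-10)
})

test_that("the PSF of full and origin-only schedules is degenerate as expected", {
  full <- point_spread_function(generate_schedule(c(8, 8), 1, "full"))
  centre <- which(full$values == max(full$values), arr.ind = TRUE)
  expect_equal(max(full$values), 1)
  expect_lt(sort(abs(full$values), decreasing = TRUE)[2], 1e-12)
  expect_equal(unname(centre[1, ]), c(5, 5))  # zero-frequency bin
  origin <- point_spread_function(generate_schedule(8, 1 / 8, seed = 1))
  expect_true(all(abs(origin$values - origin$values[1]) < 1e-12))
})

test_that("a masked on-grid peak is exactly the shifted PSF times its height", {
  g <- sim_2d(list(on_grid_res(4, 8)), "cp_states")
  sch <- generate_schedule(16, 0.5, seed = 11)
  sp <- nuft(g, sch, zero_fill = 1)
  psf <- point_spread_function(sch)
  hcol <- ppm_to_index(sp$axes$Hdet, 8.3 + 8 * 4000 / 32 / 800)
  nrow_pk <- ppm_to_index(sp$axes$N, 118 + 4 * 2000 / 16 / 81.1)
  col <- sp$values[, hcol]
  zero_bin <- floor(16 / 2) + 1L
  expected <- col[nrow_pk] * circshift(as.vector(psf$values),
                                       nrow_pk - zero_bin)
  expect_equal(as.vector(col), expected, tolerance = 1e-10)
})

test_that("nuFT spectra superpose linearly", {
  sch <- generate_schedule(16, 0.4, seed = 5)
  g1 <- sim_2d(list(on_grid_res(4, 8)), "cp_states")
  g2 <- sim_2d(list(on_grid_res(-5, 3, 0.5)), "cp_states")
  g12 <- sim_2d(list(on_grid_res(4, 8), on_grid_res(-5, 3, 0.5)), "cp_states")
  expect_equal(nuft(g12, sch)$values,
               nuft(g1, sch)$values + nuft(g2, sch)$values,
               tolerance = 1e-12)
})

test_that("PSF side-lobe level falls as the sampled fraction grows", {
  rms_at <- function(fr) {
    mean(vapply(1:60, function(k) {
      p <- point_spread_function(generate_schedule(32, fr, seed = k))
      v <- p$values
      v[which.max(v)] <- NA
      sqrt(mean(v^2, na.rm = TRUE))
    }, 1))
  }
  levels <- vapply(c(0.1, 0.25, 0.5, 1), rms_at, 1)
  expect_true(all(diff(levels) < 0))
})
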