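noise_plane <- function(sigma = 1, seed = 1, n1 = 48L, n2 = 48L, offset = 0) {
  set.seed(seed)
  vals <- matrix(rnorm(n1 * n2, mean = offset, sd = sigma), n1, n2)
  spectrum_grid(list(N = seq(100, 130, length.out = n1),
                     Hdet = seq(6, 11, length.out = n2)), vals)
}

centre_peak <- function() peak_record("X", c(N = 115, Hdet = 8.5))

test_that("the noise level of a pure Gaussian plane recovers sigma", {
  ests <- vapply(1:40, function(k) {
    plane_snr(noise_plane(seed = k), centre_peak(), n_points = 100,
              exclusion = c(2.5, 1.0), seed = k)$noise_level
  }, 1)
  # sd of a 100-point sample std is about 7 %; each estimate within the
  # sampling band and the ensemble mean much tighter
  expect_true(all(abs(ests - 1) < 0.25))
  expect_equal(mean(ests), 1, tolerance = 0.03)
  r <- plane_snr(noise_plane(seed = 2), centre_peak(), seed = 2,
                 exclusion = c(2.5, 1.0))
  expect_lt(abs(r$snr), 4)
})

test_that("the estimate is invariant under a constant plane offset and seeded", {
  p0 <- noise_plane(seed = 6)
  p7 <- noise_plane(seed = 6, offset = 7)
  r0 <- plane_snr(p0, centre_peak(), seed = 3, exclusion = c(2.5, 1.0))
  r7 <- plane_snr(p7, centre_peak(), seed = 3, exclusion = c(2.5, 1.0))
  expect_equal(r0$snr, r7$snr, tolerance = 1e-10)
  expect_equal(r0$noise_level, r7$noise_level, tolerance = 1e-12)
  expect_identical(r0$snr,
                   plane_snr(p0, centre_peak(), seed = 3,
                             exclusion = c(2.5, 1.0))$snr)
})

test_that("degenerate and infeasible planes raise errors", {
  const <- spectrum_grid(list(N = seq(100, 130, length.out = 20),
                              Hdet = seq(6, 11, length.out = 20)),
                         matrix(3, 20, 20))
  expect_error(plane_snr(const, centre_peak(), n_points = 50,
                         exclusion = c(2.5, 1.0)), "zero variance")
  expect_error(plane_snr(noise_plane(), centre_peak(), n_points = 1e6,
                         exclusion = c(2.5, 1.0)), "available")
  expect_error(plane_snr(noise_plane(), centre_peak(),
                         exclusion = c(100, 100)), "whole plane")
})

test_that("a constructed peak of height 10 over unit noise reads SNR near 10", {
  p <- noise_plane(seed = 9)
  i <- hdnmr:::peak_indices(p, c(N = 115, Hdet = 8.5))
  p$values[i[1], i[2]] <- 10
  r <- plane_snr(p, centre_peak(), n_points = 100, exclusion = c(2.5, 1.0),
                 seed = 4)
  expect_equal(r$snr, 10, tolerance = 0.3 * 10)
})

test_that("bulk signal ratios handle identity and degenerate input", {
  fid <- complex(real = rnorm(16), imaginary = rnorm(16))
  expect_equal(as.numeric(bulk_signal_ratio(fid, fid)), 1)
  expect_equal(as.numeric(bulk_signal_ratio(fid, fid, method = "max")), 1)
  expect_error(bulk_signal_ratio(fid, fid[1:8]), "length")
  expect_error(bulk_signal_ratio(fid, 0 * fid), "zero signal")
})

test_that("enhancement tables flag peaks missing conventionally", {
  re <- data.frame(label = c("A", "B", "C"), snr = c(10, 8, 6),
                   detected_in_conventional = c(TRUE, TRUE, FALSE))
  rc <- data.frame(label = c("A", "B"), snr = c(5, 8))
  out <- per_peak_enhancement(re, rc)
  expect_identical(out$table$excluded, c(FALSE, FALSE, TRUE))
  expect_equal(out$table$enhancement[1:2], c(2, 1))
  expect_equal(out$mean_enhancement, 1.5)
  ident <- per_peak_enhancement(re[1:2, ], rc)
  expect_equal(ident$table$enhancement, c(2, 1))
  doubled <- rc
  doubled$snr <- rc$snr / 2
  expect_equal(per_peak_enhancement(re[1:2, ], doubled)$mean_enhancement,
               ((10 / 2.5) + (8 / 4)) / 2)
  expect_error(per_peak_enhancement(re[3, , drop = FALSE], rc), "shared")
})

test_that("noise comparisons report unity for identical spectra and flag degeneracy", {
  p <- noise_plane(seed = 12)
  pk <- data.frame(label = "X", N = 115, Hdet = 8.5)
  out <- noise_ratio_report(p, p, p, p, pk, exclusion = c(2.5, 1.0))
  expect_equal(out$table$ratio_pre, 1)
  expect_equal(out$table$ratio_post, 1)
  expect_identical(out$summary$n_degenerate, 0L)
  # noiseless fully sampled on-grid spectra: off-peak values identically
  # zero, noise undefined
  g <- sim_2d(list(on_grid_res(4, 8)), "cp_states")
  s <- hypercomplex_ft(g, zero_fill = 1)
  pk2 <- data.frame(label = "P", N = 118 + 4 * 2000 / 16 / 81.1,
                    Hdet = 8.3 + 8 * 4000 / 32 / 800)
  out2 <- noise_ratio_report(s, s, s, s, pk2, n_points = 50,
                             exclusion = c(2.5, 1.0))
  expect_true(out2$table$degenerate)
  expect_true(is.na(out2$table$ratio_pre))
  other <- noise_plane(seed = 12, n1 = 40L)
  expect_error(noise_ratio_report(p, p, p, other, pk), "matching axes")
})

test_that("plane extraction fixes the remaining coordinates at the peak", {
  fx <- fixture_library("toy3d_2enh", seed = 4)
  g <- simulate_experiment(fx$resonances, fx$dims, fx$scheme,
                           noise_model(0.1, 3))
  s <- hypercomplex_ft(to_states(g), zero_fill = 1)
  pk <- hdnmr:::as_peak_list(fx$peaks, names(s$axes))[[1]]
  pl <- peak_plane(s, pk)
  expect_identical(names(pl$axes), c("N", "Hdet"))
  ico <- ppm_to_index(s$axes$CO, pk$position[["CO"]])
  expect_equal(pl$values, s$values[ico, , ], tolerance = 1e-12)
})
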