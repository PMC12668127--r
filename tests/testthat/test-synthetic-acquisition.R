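test_that("simulation is seed-deterministic and validates inputs", {
  res <- list(on_grid_res(3, 5))
  g1 <- sim_2d(res, sigma = 0.3, seed = 11)
  g2 <- sim_2d(res, sigma = 0.3, seed = 11)
  g3 <- sim_2d(res, sigma = 0.3, seed = 12)
  expect_identical(g1$data, g2$data)
  expect_false(identical(g1$data, g3$data))
  expect_error(noise_model(-1), "sigma")
  # scheme must cover exactly the indirect dimensions
  expect_error(
    simulate_experiment(res, dims_2d(), transfer_scheme(c(Q = "cp_states"))),
    "indirect")
})

test_that("no resonances and no noise give an all-zero grid", {
  g <- sim_2d(list())
  expect_true(all(g$data == 0))
  expect_true(all(first_fid(g) == 0))
})

test_that("both preserved pathways add coherently on recombination", {
  # at b = 1 the recombined cosine component equals the CP cosine component:
  # two half-amplitude pathways add coherently to the full CP amplitude
  res <- list(resonance(c(N = 400, Hdet = 250), 1.5, c(N = 18, Hdet = 22)))
  r <- recombine_echo_antiecho(sim_2d(res, "trop_echo_antiecho"), "N")
  cp <- sim_2d(res, "cp_states")
  expect_equal(r$data, cp$data, tolerance = 1e-12)
})

test_that("signal is linear in amplitude and noise floor linear in sigma", {
  res <- function(a) list(resonance(c(N = 500, Hdet = 300), a,
                                    c(N = 20, Hdet = 25)))
  g1 <- sim_2d(res(1))
  g2 <- sim_2d(res(2.5))
  expect_equal(g2$data, 2.5 * g1$data, tolerance = 1e-12)
  n1 <- sim_2d(list(), sigma = 1, seed = 5)
  n2 <- sim_2d(list(), sigma = 2, seed = 5)
  expect_equal(n2$data, 2 * n1$data, tolerance = 1e-12)
})

test_that("the first FID probes the bulk transfer amplitudes", {
  # on-carrier resonance: first FID is a * exp(-R t) times the transfer
  # amplitude of the first component (echo at t = 0 contributes b)
  res <- list(resonance(c(N = 0, Hdet = 0), 1.2, c(N = 30, Hdet = 40)))
  g <- sim_2d(res, "trop_echo_antiecho", bulk = 0.85)
  td <- (0:31) / 4000
  expect_equal(first_fid(g), 0.85 * 1.2 * exp(-40 * td) + 0i,
               tolerance = 1e-12)
  gc <- sim_2d(res, "cp_states")
  expect_equal(as.numeric(bulk_signal_ratio(first_fid(g), first_fid(gc))),
               0.85, tolerance = 1e-12)
})

test_that("improved transfers can exceed the conventional bulk signal", {
  res <- list(resonance(c(N = 200, Hdet = 150), 1, c(N = 20, Hdet = 20)))
  g_new <- sim_2d(res, "trop_echo_antiecho", bulk = 1.1)
  g_cp <- sim_2d(res, "cp_states")
  expect_equal(as.numeric(bulk_signal_ratio(first_fid(g_new), first_fid(g_cp),
                                            method = "max")),
               1.1, tolerance = 1e-12)
})

test_that("fixture library is deterministic and matches its documentation", {
  f1 <- fixture_library("toy2d", seed = 1)
  f2 <- fixture_library("toy2d", seed = 1)
  expect_identical(f1$resonances, f2$resonances)
  f4 <- fixture_library("toy4d_3enh")
  expect_true(all(f4$scheme$modes == "trop_echo_antiecho"))
  expect_identical(length(f4$dims), 4L)
  f3 <- fixture_library("toy3d_mixed_encoding")
  expect_setequal(unname(f3$scheme$modes),
                  c("cp_states", "trop_echo_antiecho"))
  f5 <- fixture_library("toy5d_3enh_smallgrid")
  expect_true(all(vapply(f5$dims[1:4], `[[`, 1L, "n_complex_points") <= 8L))
  expect_error(fixture_library("nope"), "unknown fixture")
})

test_that("States and echo-antiecho processing commute across dimensions", {
  fx <- fixture_library("toy3d_mixed_encoding", seed = 2)
  g <- simulate_experiment(fx$resonances, fx$dims, fx$scheme,
                           noise_model(0.02, 7))
  a <- hypercomplex_ft(
    ft_dimension(recombine_echo_antiecho(g, "N"), "CO", zero_fill = 2),
    zero_fill = 2)
  b <- hypercomplex_ft(
    recombine_echo_antiecho(ft_dimension(g, "CO", zero_fill = 2), "N"),
    zero_fill = 2)
  expect_equal(a$values, b$values, tolerance = 1e-12)
  expect_equal(a$axes, b$axes)
})

test_that("measured SNR gain recovers b * sqrt(2) for one enhanced dimension", {
  fx <- fixture_library("toy2d", seed = 5, bulk = 0.8)
  ap <- list(type = "cosine")
  ratios <- vapply(1:80, function(k) {
    ge <- simulate_experiment(fx$resonances, fx$dims, fx$scheme,
                              noise_model(1, 300 + k))
    gc <- simulate_experiment(fx$resonances, fx$dims,
                              conventional_scheme(fx$scheme),
                              noise_model(1, 9000 + k))
    se <- hypercomplex_ft(to_states(ge), zero_fill = 2, apodization = ap)
    sc <- hypercomplex_ft(to_states(gc), zero_fill = 2, apodization = ap)
    re <- snr_report(se, fx$peaks, n_points = 300, seed = k,
                     exclusion = c(4, 1), exclude_other_peaks = TRUE)
    rc <- snr_report(sc, fx$peaks, n_points = 300, seed = k,
                     exclusion = c(4, 1), exclude_other_peaks = TRUE)
    re$snr[1] / rc$snr[1]
  }, 1)
  expect_equal(mean(ratios), 0.8 * sqrt(2), tolerance = 0.05)
})
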