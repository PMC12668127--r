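test_that("dimension specs enforce role/quadrature invariants", {
  expect_error(dim_spec("H", "1H", "direct", "states", 8, 1000, 600),
               "simple")
  expect_error(dim_spec("N", "15N", "indirect", "simple", 8, 1000, 60),
               "phase-sensitive")
  expect_error(dim_spec("N", "15N", "indirect", "states", 0, 1000, 60))
  expect_error(dim_spec("N", "15N", "indirect", "states", 8, -1, 60))
  d <- dim_spec("N", "15N", "indirect", "echo_antiecho", 8, 1000, 60, 118)
  expect_s3_class(d, "nmr_dim")
})

test_that("grids validate their layout", {
  dims <- dims_2d(8L, 16L)
  g <- hc_grid(dims)
  expect_identical(dim(g$data), c(2L, 2L, 8L, 16L))
  expect_true(all(g$data == 0))
  expect_error(hc_grid(rev(dims)), "direct dimension must be listed last")
  expect_error(hc_grid(dims, data = array(0, c(2, 2, 8, 8))), "dimension")
})

test_that("Rance-Kay recombination of a zero-offset resonance gives a pure cosine component", {
  res <- resonance(c(N = 0, Hdet = 500), amplitude = 2,
                   decays = c(N = 30, Hdet = 20))
  g <- sim_2d(list(res))
  r <- recombine_echo_antiecho(g, "N")
  # cos component: a * exp(-R t) modulation; sin component identically zero
  sin_comp <- r$data[2, , , ]
  expect_lt(max(abs(sin_comp)), 1e-12)
  dN <- r$dims[[1]]
  tN <- (0:15) / dN$spectral_width
  cos_mod <- r$data[1, 1, , 1]   # direct Re at t_direct = 0
  expect_equal(cos_mod, 2 * exp(-30 * tN), tolerance = 1e-12)
})

test_that("recombination converts all-zero and rejects wrong dimensions", {
  g <- sim_2d(list())
  r <- recombine_echo_antiecho(g, "N")
  expect_true(all(r$data == 0))
  expect_identical(r$dims[[1]]$quadrature, "states")
  expect_error(recombine_echo_antiecho(r, "N"), "not echo-antiecho")
  expect_error(recombine_echo_antiecho(g, "Q"), "unknown dimension")
})

test_that("noiseless echo-antiecho data recombines to the identical States encoding", {
  res <- list(resonance(c(N = 500, Hdet = 300), 2, c(N = 20, Hdet = 25)),
              resonance(c(N = -720, Hdet = -1100), 0.7, c(N = 35, Hdet = 15)))
  g_ea <- recombine_echo_antiecho(sim_2d(res, "trop_echo_antiecho"), "N")
  g_st <- sim_2d(res, "cp_states")
  expect_equal(g_ea$data, g_st$data, tolerance = 1e-12)
  s_ea <- hypercomplex_ft(g_ea, zero_fill = 2)
  s_st <- hypercomplex_ft(g_st, zero_fill = 2)
  expect_lt(max(abs(s_ea$values - s_st$values)) / max(abs(s_st$values)),
            1e-10)
})

test_that("States-TPPI conversion reproduces the States spectrum at the true offset", {
  # on-carrier resonance appears at the carrier after conversion
  res0 <- resonance(c(N = 0, Hdet = 0), 1, c(N = 10, Hdet = 10))
  g0 <- states_tppi_to_states(sim_2d(list(res0), "cp_states_tppi"), "N")
  s0 <- hypercomplex_ft(g0, zero_fill = 2)
  i <- which(s0$values == max(s0$values), arr.ind = TRUE)
  expect_equal(s0$axes$N[i[1]], 118, tolerance = 2000 / 32 / 81.1)
  # +0.25 sw resonance matches the plain States encoding point-wise
  res <- resonance(c(N = 0.25 * 2000, Hdet = 400), 1, c(N = 15, Hdet = 20))
  g_tp <- states_tppi_to_states(sim_2d(list(res), "cp_states_tppi"), "N")
  g_st <- sim_2d(list(res), "cp_states")
  expect_equal(g_tp$data, g_st$data, tolerance = 1e-12)
  expect_error(states_tppi_to_states(g_st, "N"), "not States-TPPI")
})

test_that("Fourier processing refuses unconverted quadratures", {
  g_ea <- sim_2d(list(on_grid_res(2, 3)))
  expect_error(hypercomplex_ft(g_ea), "recombine")
  g_tp <- sim_2d(list(on_grid_res(2, 3)), "cp_states_tppi")
  expect_error(hypercomplex_ft(g_tp), "States-TPPI")
})

test_that("hypercomplex FT is linear and places peaks at analytic positions", {
  r1 <- list(resonance(c(N = 430, Hdet = -700), 1.3, c(N = 22, Hdet = 18)))
  r2 <- list(resonance(c(N = -610, Hdet = 900), 0.8, c(N = 12, Hdet = 30)))
  gx <- sim_2d(r1, "cp_states")
  gy <- sim_2d(r2, "cp_states")
  gxy <- sim_2d(c(r1, r2), "cp_states")
  sx <- hypercomplex_ft(gx, zero_fill = 2)
  sy <- hypercomplex_ft(gy, zero_fill = 2)
  sxy <- hypercomplex_ft(gxy, zero_fill = 2)
  expect_equal(sxy$values, sx$values + sy$values, tolerance = 1e-12)
  # peak of sx within one zero-filled grid step of the ppm prediction
  i <- which(sx$values == max(sx$values), arr.ind = TRUE)
  expect_lt(abs(sx$axes$N[i[1]] - (118 + 430 / 81.1)), 2000 / 32 / 81.1 + 1e-9)
  expect_lt(abs(sx$axes$Hdet[i[2]] - (8.3 - 700 / 800)), 4000 / 64 / 800 + 1e-9)
})

test_that("total spectral power scales quadratically with input amplitude", {
  res <- function(a) list(resonance(c(N = 500, Hdet = 300), a,
                                    c(N = 20, Hdet = 25)))
  s1 <- hypercomplex_ft(sim_2d(res(1), "cp_states"))
  s3 <- hypercomplex_ft(sim_2d(res(3), "cp_states"))
  expect_equal(sum(s3$values^2), 9 * sum(s1$values^2), tolerance = 1e-10)
})

test_that("recombining iid-noise components yields sigma/sqrt(2) noise", {
  sds <- vapply(1:3, function(k) {
    g <- sim_2d(list(), sigma = 1, seed = k)
    r <- recombine_echo_antiecho(g, "N")
    sd(as.vector(r$data))
  }, 1)
  expect_equal(mean(sds), 1 / sqrt(2), tolerance = 0.05)
})

test_that("spectrum containers insist on monotone matching axes", {
  expect_error(spectrum_grid(list(a = c(1, 3, 2)), 1:3), "monotone")
  expect_error(spectrum_grid(list(a = 1:4), matrix(0, 2, 2)), "axis")
  s <- spectrum_grid(list(a = 1:2, b = c(5, 4)), matrix(0, 2, 2))
  expect_s3_class(s, "nmr_spectrum")
})
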