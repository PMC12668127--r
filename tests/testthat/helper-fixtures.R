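# Shared builders for small deterministic test systems.

dims_2d <- function(n_ind = 16L, n_dir = 32L, quad = "echo_antiecho") {
  list(dim_spec("N", "15N", "indirect", quad, n_ind, 2000, 81.1, 118),
       dim_spec("Hdet", "1H", "direct", "simple", n_dir, 4000, 800, 8.3))
}

# a resonance sitting exactly on frequency-grid points (no decay unless set)
on_grid_res <- function(kN, kH, a = 1, n_ind = 16L, n_dir = 32L,
                        rN = 0, rH = 0) {
  resonance(c(N = kN * 2000 / n_ind, Hdet = kH * 4000 / n_dir), amplitude = a,
            decays = c(N = rN, Hdet = rH))
}

sim_2d <- function(resonances, mode = "trop_echo_antiecho", bulk = 1,
                   sigma = 0, seed = NULL, n_ind = 16L, n_dir = 32L) {
  quad <- switch(mode, trop_echo_antiecho = "echo_antiecho",
                 cp_states = "states", cp_states_tppi = "states_tppi")
  simulate_experiment(resonances, dims_2d(n_ind, n_dir, quad),
                      transfer_scheme(c(N = mode), bulk),
                      noise_model(sigma, seed))
}

# circular shift of a vector by k positions (for PSF convolution checks)
circshift <- function(v, k) {
  n <- length(v)
  v[((seq_len(n) - 1L - k) %% n) + 1L]
}
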