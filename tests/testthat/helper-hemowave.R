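# shared fixtures: small parameter sets and grids used across tests

subj_foveal <- function(a_F = NA_real_) wave_params(2.3, 0.86, a_F = a_F)
subj_peripheral <- function(a_F = NA_real_) wave_params(1.8, 0.56, a_F = a_F)

# smooth space-time pulse, band-limited on the test grids
pulse_zfun <- function(x, t, sig_x = 1, sig_t = 0.4, t0 = 2)
  exp(-x^2 / (2 * sig_x^2)) * exp(-(t - t0)^2 / (2 * sig_t^2))

quiet_recover <- function(ds, ...) suppressMessages(recover_parameters(ds, ...))

quick_dataset <- function(v, Gamma, noise = no_noise(), ...) {
  make_flatmap_dataset(wave_params(v, Gamma), noise = noise,
                       y_extent = 12, ...)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
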