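# Shared fixtures: small grids and parameter sets used across test files.

syn0 <- synaptic_params()
conn0 <- connectivity_params()
sens0 <- sensor_model()
noise0 <- noise_params()

small_grid <- function(n_k = 16L)
  spectral_grid(seq(10, 90, by = 10), n_k = n_k)

fit_grid <- function(n = 16L, n_k = 16L)
  spectral_grid(seq(6, 90, length.out = n), n_k = n_k)

# random connectivity within a few prior standard deviations of the means
random_conn <- function(sd = 0.25) {
  connectivity_params(
    alpha = default_alpha() * exp(rnorm(10, 0, sd)),
    c_decay = default_c_decay() * exp(rnorm(10, 0, sd)),
    inv_speed = (1 / 300) * exp(rnorm(1, 0, sd / 2)))
}

random_syn <- function(sd = 0.125) {
  synaptic_params(kappa_ms = c(1 / 2, 1 / 35, 1 / 35, 1 / 2) *
                    exp(rnorm(4, 0, sd)))
}

# brute-force Fourier quadrature of the delayed exponential kernel
kernel_quadrature <- function(edge, k, omega, conn, half_width = 60) {
  al <- conn$alpha[[edge]]; cc <- conn$c_decay[[edge]]
  up <- conn$inv_speed
  re <- integrate(function(x) al / 2 * exp(-cc * abs(x)) *
                    cos(omega * up * abs(x) + k * x),
                  -half_width, half_width, rel.tol = 1e-10,
                  subdivisions = 4000L)$value
  im <- integrate(function(x) al / 2 * exp(-cc * abs(x)) *
                    sin(omega * up * abs(x) + k * x),
                  -half_width, half_width, rel.tol = 1e-10,
                  subdivisions = 4000L)$value
  complex(real = re, imaginary = -im)
}

# tiny noiseless dataset at the prior means (null generating model)
prior_mean_dataset <- function(freqs = seq(6, 90, length.out = 16L),
                               n_epochs = Inf, seed = 1L) {
  simulate_csd_dataset(truth = list(dev = numeric(0), beta = NULL),
                       model = model_space()[[8L]], freqs = freqs,
                       n_epochs = n_epochs, n_k = 16L, seed = seed)
}
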