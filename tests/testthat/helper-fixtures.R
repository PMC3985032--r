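# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so single tests run in well under a second.

tiny_acq <- function(...) {
  defaults <- list(n_tag = 12, n_control = 12, matrix_shape = c(12, 12),
                   n_slices = 2, noise_sd = 0, drift_slope = 0,
                   bold_amplitude = 0, seed = 11L)
  do.call(acquisition_config, utils::modifyList(defaults, list(...)))
}

tiny_cbf <- c(frontal_gray = 52, parietal_gray = 48,
              frontal_white = 22, parietal_white = 18)

# independent evaluation of the quantification formula, written against the
# printed equation rather than the package internals
oracle_cbf <- function(dm_over_m0, n = 1, lambda = 0.9, t1b = 1.68,
                       t2b = 0.275, w = 0.5, te = 0.044, t_slc = 0.06) {
  dm_over_m0 * 6000 / (lambda * t1b) *
    exp((w + t_slc * (n - 1)) / t1b) * exp(te / t2b)
}

# chain-structured triple (x -> m -> y plus direct path) for mediation tests
make_chain <- function(n, a, b, c_prime, sd_m = 1, sd_y = 1, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + rnorm(n, 0, sd_m)
  y <- b * m + c_prime * x + rnorm(n, 0, sd_y)
  list(x = x, m = m, y = y)
}
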