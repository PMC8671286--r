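# Reference parameter sets: unit rate constants, n = 5, cross-link
# breaking rate chosen in each of the three regimes, plus the
# cross-link-conserving case; shared initial state (2, 4, 3).
pars_finite <- rate_constants(5, 1, 1, 1, 1, 0.6)
pars_extinct <- rate_constants(5, 1, 1, 1, 1, 0.93)
pars_growth <- rate_constants(5, 1, 1, 1, 1, 0.2)
pars_kzero <- rate_constants(5, 1, 1, 1, 1, 0)
init_ref <- c(p = 2, q = 4, r = 3)

# log-uniform random rate constants used by property tests
random_params <- function(m, seed, n_choices = c(3L, 4L, 5L, 8L)) {
  set.seed(seed)
  purrr::map(seq_len(m), function(i) {
    k <- exp(stats::runif(5, log(0.05), log(5)))
    rate_constants(sample(n_choices, 1L), k[1], k[2], k[3], k[4], k[5])
  })
}
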