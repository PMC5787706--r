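# Shared fixtures, built in code.

# a parameter set with all feedback severed (delta_alpha = 0 everywhere);
# every gene is then an independent constitutive two-stage birth-death unit
constitutive_params <- function(alpha = c(0.4, 0.5, 0.6, 0.7),
                                gamma = c(0.5, 0.4, 0.3, 0.2),
                                beta = 0.05, mu = 0.02) {
  genes <- purrr::map2(c("GAL1", "GAL3", "GAL80", "REPORTER"),
                       seq_len(4), function(nm, i) {
    gene_kinetics(nm, alpha = alpha[i], delta_alpha = 0, beta = beta,
                  gamma = gamma[i], mu = mu, n_sites = 1L)
  })
  gal_params(genes, shared_constants(k0_on = 1e-5, k0_off = 0.01, K1 = 10,
                                     K3 = 1, K80 = 25, Kgal = 0.055,
                                     nu_mat = 1e-9))
}

# hand-built ensemble with prescribed monotone signals (for lag logic tests)
toy_ensemble <- function(signals, time = seq(0, 100, by = 10), gal = 0.5) {
  structure(list(time = time, signal = signals,
                 initial_inducers = seq_len(nrow(signals)),
                 final_state = NULL, seed = 1L,
                 params = default_params(), gal = gal, gain = 1),
            class = "gal_ensemble")
}

# small synthetic event sample: bivariate normal scatter + given FL1 values
toy_sample <- function(n, sample_id, fl1 = rnorm(n, 100, 10), plate = 1,
                       strain = "S", gal = 0.5, time_min = 0, replicate = 1) {
  tibble::tibble(
    fsc = round(rnorm(n, 450, 60)), ssc = round(rnorm(n, 380, 55)),
    fl1 = fl1, strain = strain, gal = gal, time_min = time_min,
    replicate = replicate, plate = plate, sample_id = sample_id)
}

# the two anchor parameter sets: gradual and binary induction at 0.5% galactose
GRADUAL_RHO <- 140
BINARY_RHO <- 40
ANCHOR_KGAL <- 0.055
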