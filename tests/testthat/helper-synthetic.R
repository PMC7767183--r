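# Shared helpers: randomized-but-seeded simulation configs and an
# independent one-expression oracle for the stoichiometric chain.

# Draw a random experiment configuration (seeded by the caller).
random_sim_config <- function(noise_sd_ph = 0, noise_sd_height_mm = 0) {
  simulation_config(
    concentration_pct = stats::runif(1, 0.5, 2.5),
    rate_k = stats::runif(1, 0.005, 0.05),
    max_reacted_fraction = stats::runif(1, 0.3, 0.97),
    water_binding_factor = stats::runif(1, 1, 3),
    noise_sd_ph = noise_sd_ph,
    noise_sd_height_mm = noise_sd_height_mm,
    duration_min = 120, dt_min = 5, n_replicates = 2
  )
}

# Independent single-expression form of the pH -> reacted volume chain
# (physical direction), used as the oracle against the composed functions.
oracle_chain_volume <- function(ph0, phn, pKw = 14, pKb = 5.24, Vr = 0.003,
                                M_acid = 284.48, f_stearic = 0.24,
                                d_mg_mm3 = 0.842) {
  (10^(2 * ph0 - 2 * pKw + pKb) - 10^(2 * phn - 2 * pKw + pKb)) *
    Vr * M_acid / (f_stearic * (d_mg_mm3 * 1e-3))
}
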