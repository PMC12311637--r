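# small in-code fixtures shared across test files

# six shared ASVs engineered to realize mean relative-abundance ratios
# (nano/pico) of 3, 0.4, 1, 2.0, 0.5 and Inf; every row sums to 100 so
# counts are relative abundances x 100
shared_asv_toy <- function() {
  pico_counts <- rbind(S1 = c(A1 = 10, A2 = 10, A3 = 10, A4 = 10, A5 = 10,
                              A6 = 0, pico_only = 50),
                       S2 = c(A1 = 10, A2 = 10, A3 = 10, A4 = 10, A5 = 10,
                              A6 = 0, pico_only = 50))
  nano_counts <- rbind(S1 = c(A1 = 30, A2 = 4, A3 = 10, A4 = 20, A5 = 5,
                              A6 = 10, nano_only = 21),
                       S2 = c(A1 = 30, A2 = 4, A3 = 10, A4 = 20, A5 = 5,
                              A6 = 10, nano_only = 21))
  list(pico = asv_table(pico_counts, "pico"),
       nano = asv_table(nano_counts, "nano"))
}

season_meta <- function(n_per_season, seasons = c("winter", "spring",
                                                  "summer", "autumn")) {
  data.frame(season = rep(seasons, each = n_per_season),
             layer = "surface", station = "ST1")
}

# quick latent-chain count data for network inference tests
chain_count_data <- function(p, n_per_season, seed, rho = 0.4,
                             zero_inflation = 0) {
  scen <- synthetic_scenario(
    n_eligible = c(bacteria = p, pico = 0, nano = 0),
    n_noise = c(bacteria = 0, pico = 0, nano = 0),
    true_precision = chain_precision(p, rho),
    samples_per_season = n_per_season, n_seasons = 4,
    zero_inflation = zero_inflation, composition_effect = 0, seed = seed)
  generate_counts(scen)
}
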