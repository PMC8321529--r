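# The fate a correct classifier should call for each generating scenario:
# conserved, pseudogenized and neofunctionalized families all leave the
# ancestral paralog as the best-correlated member; only subfunctionalized
# families make the summed profile win by the margin.
expected_call <- function(fate) {
  ifelse(fate == "subfunctionalized",
         "subfunctionalization_candidate", "ancestral_conserved")
}

fate_accuracy <- function(noise_sd, n_families = 200L, seed = 7L) {
  cfg <- sim_config(n_families = n_families,
                    expression_noise_sd = noise_sd, seed = seed)
  sim <- simulate_families(cfg)
  cors <- family_correlations(sim$human, sim$ortholog, sim$families)
  calls <- classify_families(cors, sim$families)
  m <- merge(calls, sim$truth$fates, by = "family")
  mean(m$call == expected_call(m$fate))
}

# tiny genome landscape reused by interval tests
small_landscape <- function(seed = 3L) {
  simulate_peak_landscape(sim_config(seed = seed, genome_length = 1e6,
                                     n_sd = 10L, sd_length = 2e4,
                                     n_peaks = 500L))
}
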