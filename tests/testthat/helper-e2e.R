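# Shared end-to-end mapping run used by the calibration checks: a 1 Mb
# random genome, 500 simulated kilobase reads at 15% error with the
# 10/62/28 substitution/insertion/deletion mix.  Computed once per session.
.e2e_cache <- new.env(parent = emptyenv())

e2e_mapping_run <- function() {
  if (!is.null(.e2e_cache$run)) return(.e2e_cache$run)
  genome <- random_genome(1e6, seed = 42)
  idx <- build_index(genome)
  sim <- simulate_reads(genome, sim_config(rho = 0.15,
                                           read_length = 1000,
                                           n_reads = 500, seed = 7))
  res <- map_reads(lapply(sim, `[[`, "record"), idx)
  .e2e_cache$run <- list(sim = sim, res = res)
  .e2e_cache$run
}
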