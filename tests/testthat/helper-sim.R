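# One seeded synthetic dataset shared across test files (built on first
# use; ~10 s once per suite).
.sim_cache <- new.env(parent = emptyenv())

get_sim <- function() {
  if (is.null(.sim_cache$sim)) .sim_cache$sim <- simulate_dataset(seed = 42)
  .sim_cache$sim
}
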