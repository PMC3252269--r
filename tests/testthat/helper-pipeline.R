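# One small simulated dataset and pipeline run, shared across test files
# (the full-scale seeded run lives in the acceptance suite).
.pipeline_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.pipeline_cache$sim)) {
    .pipeline_cache$sim <- generate_dataset(simulation_config(
      seed = 42, n_families = 10, transfer_fraction = 0.3,
      contaminant_fraction = 0.1, sequence_length = 180
    ))
  }
  .pipeline_cache$sim
}

small_run <- function() {
  if (is.null(.pipeline_cache$run)) {
    .pipeline_cache$run <- run_pipeline(pipeline_inputs(small_sim()),
                                        pipeline_config(seed = 42))
  }
  .pipeline_cache$run
}
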