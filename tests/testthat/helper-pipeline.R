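# The end-to-end study-condition run (default generator, seed 0) is
# expensive, so it is computed once per test session and shared by the
# tests that probe different stages of the same run.
.pipeline_cache <- new.env(parent = emptyenv())

study_run <- function() {
  if (!exists("run", envir = .pipeline_cache)) {
    dir <- file.path(tempdir(), "cellmark-study-run")
    cfg <- pipeline_config(seed = 0L)
    .pipeline_cache$run <- suppressWarnings(run_all(cfg, dir))
    .pipeline_cache$sim <- simulate_profiles(synth_config(seed = 0L))
  }
  list(run = .pipeline_cache$run, sim = .pipeline_cache$sim)
}
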