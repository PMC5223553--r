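# shared fixtures; the end-to-end pipeline run is cached because several
# test files interrogate different stages of the same run
fixture_env <- new.env()

cached_pipeline <- function() {
  if (is.null(fixture_env$run)) {
    out <- file.path(tempdir(), "mdinet-fixture-run")
    fixture_env$run <- suppressWarnings(run_pipeline(
      run_config(simulate = sim_config(seed = 101), out_dir = out)))
  }
  fixture_env$run
}

# tiny feature matrix builder
fm_of <- function(mz, mat, groups) {
  samples <- paste0(rep(names(groups), groups), "_",
                    unlist(lapply(groups, seq_len)))
  feature_matrix(mz, mat, samples, rep(names(groups), groups))
}

# simulate one dilution-series experiment under the single-hit model
rseries <- function(f, top = 1000, k = 8, wells = 24) {
  simulate_dilution_series(f, top_dose = top, n_dilutions = k, wells = wells)
}
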