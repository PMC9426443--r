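# Session-level cache for fixtures that are expensive to build, so that the
# scenario simulations are computed once and shared across test files.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

toy_fixture <- function() get_fixture("toy", function() build_toy_model())

scenario_fixture <- function(name) {
  get_fixture(paste0("sc_", name), function() diel_scenario(name))
}

scenario_sim <- function(name, hours = 24, dt = 0.1) {
  get_fixture(sprintf("sim_%s_%s_%s", name, hours, dt), function() {
    run_scenario(scenario_fixture(name), hours = hours, dt = dt)
  })
}

# a small fitted transcriptome shared by curve/similarity tests
small_fit_fixture <- function() {
  get_fixture("small_fits", function() {
    out <- generate_synthetic_transcriptome(
      synthetic_transcriptome_spec(n_genes = 12, noise_cv = 0.02, seed = 3))
    list(data = out,
         fits = fit_transcriptome(out$expression, n_restarts = 5, seed = 3))
  })
}

# three-point expression series builder
make_series <- function(times, values) {
  tibble::tibble(time = times, fpkm = values)
}
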