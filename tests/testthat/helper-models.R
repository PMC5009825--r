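# Shared fixtures for the test suite. Everything is built in code; the
# heavier artifacts (fits, datasets) are cached per test run.

quick_solver <- function() {
  solver_control(rtol = 1e-5, atol = 1, dense_dt = 21)
}

quick_ga <- function(pop = 24, gen = 12, ...) {
  ga_config(pop_size = pop, generations = gen, ...)
}

# one-pool toy: exponential decay with a constant source, analytically
# transparent and fast to fit
toy_pool_model <- function(k_death = 0.1, k_in = 0, x0 = 1000) {
  procs <- list(
    process_spec("Death", "BM.normal",
                 rate_form("first_order", k = k_death),
                 source = "BM.normal")
  )
  if (k_in > 0) {
    procs <- c(procs, list(
      process_spec("Import", "BM.normal", rate_form("zero_order", k = k_in),
                   sink = "BM.normal")
    ))
  }
  model_spec("toy_pool", init = c(BM.normal = x0), processes = procs,
             free = "BM.normal.Death.k", obs_days = c(0, 2, 4, 6, 8, 10))
}

toy_dataset <- function(spec, cv = 0, seed = 1) {
  scen <- leukodyn:::.scenario(spec, cv, 3, "toy")
  generate_kinetics(scen, seed)
}

# memoised per-session fixtures
.fixture_env <- new.env()

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

default_data_noisefree <- function() {
  fixture("default_cv0", function() {
    generate_kinetics(default_scenario(cv = 0), 1)
  })
}

default_data_noisy <- function(seed = 1) {
  fixture(paste0("default_cv15_", seed), function() {
    generate_kinetics(default_scenario(), seed)
  })
}

# a reference fitted tissue model (noise-free data, fast GA) reused by the
# decomposition / control tests
fitted_tissue <- function() {
  fixture("fitted_tissue", function() {
    fit_model(tissue_model(), default_data_noisefree(),
              ga = quick_ga(), seed = 7, solver = quick_solver())
  })
}
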