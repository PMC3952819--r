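# Shared small fixtures, built once per test run.

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(3, 5, seed = 101)
    cache
  }
})

# Univariate, intercept-only instance with one state and one county:
# the marginal likelihood reduces to a low-dimensional integral that a
# fine-grid oracle can evaluate.
tiny_instance <- function(seed = 3, pop = NULL, var_state = 0.4,
                          var_county = 0.3) {
  spec1 <- model_spec("ASD", covariates = character(0))
  pop_cfg <- if (is.null(pop)) list(meanlog = log(11000), sdlog = 1.3) else
    list(meanlog = log(pop), sdlog = 1e-9)
  geo <- generate_geography(1, 1, pop_distribution = pop_cfg, seed = seed)
  covars <- generate_covariates(geo, seed = seed)
  params <- parameter_set(setNames(log(0.001), "ASD"),
                          matrix(var_state), matrix(var_county))
  sim <- simulate_panel(geo, covars, params, spec1, seed = seed)
  list(design = sim$design, params = params, spec = spec1, panel = sim$panel)
}

expect_tibble <- function(x) {
  expect_s3_class(x, "tbl_df")
}
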