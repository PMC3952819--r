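#' Default simulation parameters at realistic magnitudes
#'
#' A `gp_parameter_set` whose fixed-effect weights and random-effect
#' covariances sit at the magnitudes reported for county-level claims data:
#' a strong positive weight on the male genital-malformation rate for the
#' first disease, moderate positive weights on non-genital malformations
#' and viral infections, a strongly male-biased gender effect, small
#' income/urbanization effects, and a large negative weight on the
#' strictest diagnostic-evaluation policy. Intercepts are set from the
#' descriptive *median* county rates (about 0.023% per male for the first
#' phenotype, a few thousandths of a percent for the second): under the
#' log link the centered-design intercept is the median log rate, and the
#' heavy upper tail implied by the log-scale random-effect variances then
#' reproduces the much larger mean and maximum county rates.
#' State- and county-level covariances imply cross-phenotype correlations
#' of about 0.97 and 0.96.
#'
#' @param spec A `gp_model_spec`; weights are named to its design columns.
#'   Unrecognised columns get weight 0.
#' @return A `gp_parameter_set`.
#' @export
default_parameters <- function(spec = model_spec()) {
  stopifnot(inherits(spec, "gp_model_spec"))
  base <- list(
    ASD = c("(Intercept)" = log(0.00023),
            Gender = -0.699, Income = 0.032, Urban = 0.036, Insured = -0.012,
            Poor = -0.035, AmInd = -0.131, Asian = -0.045, WHisp = -0.128,
            W = -0.122, BHisp = 0.085, B = -0.131, Pacific = -0.439,
            ConGenM = 1.345, CongMrepM = 0.277, Viral_M = 0.180,
            CFR = -0.100, DSM = 0.138, ASD = -0.175,
            Eval1 = -4.231, Eval2 = -0.213, `Eval-1` = 0.668),
    ID = c("(Intercept)" = log(0.00004),
           Gender = -0.114, Income = 0.027, Urban = 0.031, Insured = 0.005,
           Poor = -0.013, AmInd = -0.139, Asian = -0.066, WHisp = -0.130,
           W = -0.127, BHisp = 0.033, B = -0.130, Pacific = -0.374,
           ConGenM = 0.660, CongMrepM = 0.362, Viral_M = 0.211,
           CFR = 0.103, DSM = 0.149, ASD = -0.109,
           Eval1 = -4.536, Eval2 = -0.063, `Eval-1` = 0.418)
  )
  cn <- design_colnames(spec)
  b <- setNames(numeric(length(cn)), cn)
  for (k in seq_along(spec$diseases)) {
    dz <- spec$diseases[k]
    src <- base[[min(k, length(base))]]
    for (nm in names(b)) {
      if (nm == dz) b[nm] <- src[["(Intercept)"]]
      else if (startsWith(nm, paste0(dz, ":"))) {
        key <- sub(paste0("^", dz, ":"), "", nm)
        if (key %in% names(src)) b[nm] <- src[[key]]
      }
    }
  }
  d <- length(spec$diseases)
  Ss <- matrix(c(3.126, 2.666, 2.666, 2.398), 2)[seq_len(d), seq_len(d), drop = FALSE]
  Sc <- matrix(c(0.7699, 0.6960, 0.6960, 0.6796), 2)[seq_len(d), seq_len(d), drop = FALSE]
  parameter_set(b, Ss, Sc)
}

# Internal: design column names implied by a spec.
design_colnames <- function(spec) {
  unlist(lapply(spec$diseases, function(dz) {
    c(dz, paste0(dz, ":", expand_covariate_names(spec$covariates[[dz]],
                                                 spec$eval_reference)))
  }), use.names = FALSE)
}

#' Simulate an incidence panel under the multilevel Poisson model
#'
#' Draws state- and county-level random effects from their zero-mean
#' bivariate normals, evaluates the linear predictor on the centered design
#' built from `covars` and `geo`, and draws case counts
#' \eqn{y \sim \mathrm{Poisson}(N e^{\eta})} for every
#' (county, disease, gender) cell. The true random effects are returned so
#' recovery of simulation truth can be tested. Counts are capped at the
#' population offset so the panel invariant \eqn{y \le N} holds; at
#' realistic rate magnitudes the cap never binds. Zero-population cells get
#' a zero count.
#'
#' @param geo A `gp_geography`.
#' @param covars County covariate tibble matching `geo`.
#' @param params A `gp_parameter_set` (see [default_parameters()]).
#' @param spec A `gp_model_spec`.
#' @param seed Integer seed; bit-reproducible.
#' @return List with `panel` (tibble: `county_id`, `disease`, `gender`,
#'   `y`, `N`), `raneff` (the drawn `gp_random_effects`), and `design`
#'   (the `gp_design` used, for reuse).
#' @examples
#' geo <- generate_geography(3, 5, seed = 2)
#' cov <- generate_covariates(geo, seed = 2)
#' sim <- simulate_panel(geo, cov, default_parameters(), seed = 2)
#' head(sim$panel)
#' @export
simulate_panel <- function(geo, covars, params, spec = model_spec(), seed = 1L) {
  stopifnot(inherits(geo, "gp_geography"), inherits(params, "gp_parameter_set"))
  d <- length(spec$diseases)
  if (nrow(params$Sigma_state) != d) {
    abort("covariance dimension must equal the number of diseases.",
          class = "geopoisson_validation_error")
  }
  assert_psd(params$Sigma_state, "Sigma_state")
  assert_psd(params$Sigma_county, "Sigma_county")

  skeleton <- tidyr::expand_grid(
    disease = spec$diseases,
    county_id = geo$counties$county_id,
    gender = names(spec$gender_coding)
  ) %>%
    left_join(select(geo$counties, "county_id", "pop_male", "pop_female"),
              by = "county_id") %>%
    mutate(N = ifelse(.data$gender == "F", .data$pop_female, .data$pop_male),
           y = 0L) %>%
    select("county_id", "disease", "gender", "y", "N")

  with_seed(derive_seed(seed, "panel"), {
    vs <- mvn_draw(nrow(geo$states), params$Sigma_state)
    rownames(vs) <- geo$states$state_id
    vc <- mvn_draw(nrow(geo$counties), params$Sigma_county)
    rownames(vc) <- geo$counties$county_id
    raneff <- random_effects(vs, vc)

    design <- suppressWarnings(build_design(skeleton, covars, geo, spec))
    # align the drawn effects with the design's unit ordering
    re_aligned <- random_effects(
      vs[design$states$state_id, , drop = FALSE],
      vc[design$counties$county_id, , drop = FALSE])
    eta <- linear_predictor(design, params, re_aligned)
    lambda <- design$N * exp(eta)
    y <- pmin(rpois(length(lambda), lambda), design$N)

    key_design <- paste(design$rows$county_id, design$rows$disease,
                        design$rows$gender)
    key_skel <- paste(skeleton$county_id, skeleton$disease, skeleton$gender)
    panel <- skeleton
    panel$y[match(key_design, key_skel)] <- as.integer(y)
    # rebuild so the returned design carries the simulated counts
    design <- suppressWarnings(build_design(panel, covars, geo, spec))
    list(panel = panel, raneff = raneff, design = design)
  })
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper: geography, covariates, incidence panel and (
#' optionally) patient-level comorbidity records, all driven by one master
#' seed with one RNG stream per stage.
#'
#' @param n_states,counties_per_state Passed to [generate_geography()].
#' @param params `gp_parameter_set`; defaults to [default_parameters()].
#' @param spec `gp_model_spec`.
#' @param seed Master integer seed.
#' @param covariate_cfg Covariate configuration override.
#' @param patients If `TRUE`, also generate a patient table.
#' @param target_or Comorbidity odds ratio for the patient table.
#' @param n_per_county Patients sampled per county and gender.
#' @return List with `geo`, `covars`, `panel`, `raneff`, `design`, and
#'   optionally `patients`.
#' @export
simulate_study <- function(n_states = 10L, counties_per_state = 20L,
                           params = NULL, spec = model_spec(), seed = 1L,
                           covariate_cfg = covariate_config(),
                           patients = FALSE, target_or = 5.53,
                           n_per_county = 50L) {
  geo <- generate_geography(n_states, counties_per_state, seed = seed)
  covars <- generate_covariates(geo, covariate_cfg, seed = seed)
  params <- params %||% default_parameters(spec)
  sim <- simulate_panel(geo, covars, params, spec, seed = seed)
  out <- list(geo = geo, covars = covars, panel = sim$panel,
              raneff = sim$raneff, design = sim$design, params = params)
  if (patients) {
    out$patients <- generate_patients(sim$panel, covars, target_or = target_or,
                                      seed = seed, n_per_county = n_per_county)
  }
  out
}
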