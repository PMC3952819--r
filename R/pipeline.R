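#' Configure an end-to-end pipeline run
#'
#' Bundles everything a full run needs: the output directory, the master
#' seed (recorded in every output's sidecar), the simulation scale, the
#' model specification and the chain settings. The configuration is
#' serialisable to YAML/JSON, so runs are reproducible from a single file
#' plus a seed.
#'
#' @param out_dir Output directory.
#' @param seed Master integer seed for all stages.
#' @param scale `"desk"` (10 states / 200 counties) or `"national"`
#'   (51 states / 3,111 counties).
#' @param spec A `gp_model_spec`.
#' @param priors A `gp_prior_spec`.
#' @param chain A `gp_chain_config` (its own seed is overridden by the
#'   master seed).
#' @param method `"mcmc"` or `"laplace"` fitting path.
#' @param stages Stages to execute, in order, from
#'   `c("simulate", "fit", "summarize", "describe")`.
#' @param target_or Comorbidity odds ratio used when simulating patients.
#' @param n_per_county Patients per county and gender in the simulate
#'   stage.
#' @param verbose Emit per-stage log messages.
#' @return An object of class `gp_run_config`.
#' @export
run_config <- function(out_dir = tempfile("geopoisson_run_"),
                       seed = 1L,
                       scale = c("desk", "national"),
                       spec = model_spec(),
                       priors = prior_spec(),
                       chain = chain_config(n_iter = 2000L, burnin = 500L,
                                            thin = 1L, n_chains = 1L),
                       method = c("mcmc", "laplace"),
                       stages = c("simulate", "fit", "summarize", "describe"),
                       target_or = 5.53,
                       n_per_county = 50L,
                       verbose = TRUE) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = seed, scale = scale, spec = spec,
                 priors = priors, chain = chain, method = method,
                 stages = stages, target_or = target_or,
                 n_per_county = n_per_county, verbose = verbose),
            class = "gp_run_config")
}

#' Run the full pipeline: simulate, fit, summarize, describe
#'
#' Executes the requested stages in order against the configured output
#' directory. Stage inputs are read back from the files the earlier stages
#' wrote, so any stage can be re-run in isolation on existing outputs. A
#' `manifest.json` records the seed, the configuration, package version,
#' per-stage status with wall-clock seconds and row counts, and an MD5
#' checksum of every file written; warnings such as dropped rows or
#' non-convergence are captured there in machine-readable form.
#'
#' @param config A `gp_run_config`.
#' @return Invisibly, the exit status: `0L` if every stage succeeded,
#'   `1L` otherwise (partial outputs are retained and the manifest marks
#'   the failed stage).
#' @examples
#' cfg <- run_config(stages = "simulate", verbose = FALSE)
#' run_pipeline(cfg)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "gp_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    seed = config$seed,
    scale = config$scale,
    method = config$method,
    package_version = as.character(utils::packageVersion("geopoisson")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(), files = list(), warnings = list())
  status <- 0L

  say <- function(...) if (config$verbose) inform(sprintf(...))

  for (stage in config$stages) {
    t0 <- Sys.time()
    warns <- character(0)
    res <- withCallingHandlers(
      tryCatch({
        switch(stage,
               simulate = stage_simulate(config),
               fit = stage_fit(config),
               summarize = stage_summarize(config),
               describe = stage_describe(config))
        "ok"
      }, error = function(e) conditionMessage(e)),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ok <- identical(res, "ok")
    manifest$stages[[stage]] <- list(status = if (ok) "ok" else "failed",
                                     error = if (ok) NULL else res,
                                     seconds = round(secs, 3))
    if (length(warns) > 0) manifest$warnings[[stage]] <- warns
    say("stage %s: %s (%.2fs)", stage, if (ok) "ok" else "FAILED", secs)
    if (!ok) { status <- 1L; break }
  }

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$files <- lapply(setNames(files, basename(files)), function(f) {
    list(md5 = unname(tools::md5sum(f)), rows = count_rows(f))
  })
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(status)
}

count_rows <- function(f) {
  if (!grepl("\\.csv$", f)) return(NULL)
  length(readr::read_lines(f, progress = FALSE)) - 1L
}

stage_simulate <- function(config) {
  d <- config$out_dir
  geo <- geography_preset(config$scale, seed = config$seed)
  covars <- generate_covariates(geo, seed = config$seed)
  params <- default_parameters(config$spec)
  sim <- simulate_panel(geo, covars, params, config$spec, seed = config$seed)
  patients <- generate_patients(sim$panel, covars, target_or = config$target_or,
                                seed = config$seed,
                                n_per_county = config$n_per_county)
  write_geography(geo, d)
  write_covariates(covars, file.path(d, "covariates.csv"))
  write_panel(sim$panel, file.path(d, "panel.csv"))
  write_patients(patients, file.path(d, "patients.csv"))
  readr::write_csv(as_tibble(sim$raneff), file.path(d, "true_random_effects.csv"))
  jsonlite::write_json(list(seed = config$seed, scale = config$scale,
                            target_or = config$target_or,
                            n_per_county = config$n_per_county),
                       file.path(d, "simulate_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

stage_fit <- function(config) {
  d <- config$out_dir
  geo <- read_geography(d)
  covars <- read_covariates(file.path(d, "covariates.csv"))
  panel <- read_panel(file.path(d, "panel.csv"))
  design <- build_design(panel, covars, geo, config$spec)
  if (config$method == "mcmc") {
    chain <- config$chain
    chain$seed <- config$seed
    fit <- fit_mcmc(design, config$priors, chain)
    saveRDS_free_draws(fit, file.path(d, "draws.csv"))
    readr::write_csv(fit$summary$fixed, file.path(d, "fit_fixed.csv"))
    readr::write_csv(fit$summary$covariance, file.path(d, "fit_covariance.csv"))
    eb_state <- as_tibble(fit$re_mean$state, rownames = "state_id")
    eb_county <- as_tibble(fit$re_mean$county, rownames = "county_id")
  } else {
    fit <- fit_laplace(design)
    readr::write_csv(tidy(fit), file.path(d, "fit_fixed.csv"))
    eb <- empirical_bayes(design, parameter_set(fit$b, fit$Sigma_state,
                                                fit$Sigma_county))
    eb_state <- as_tibble(eb$state, rownames = "state_id")
    eb_county <- as_tibble(eb$county, rownames = "county_id")
  }
  readr::write_csv(eb_state, file.path(d, "random_effects_state.csv"))
  readr::write_csv(eb_county, file.path(d, "random_effects_county.csv"))
  invisible(NULL)
}

# Draws are written as plain CSV so every output stays a text format.
saveRDS_free_draws <- function(fit, path) {
  readr::write_csv(as_tibble(fit$draws), path)
}

stage_summarize <- function(config) {
  d <- config$out_dir
  fixed <- readr::read_csv(file.path(d, "fit_fixed.csv"),
                           show_col_types = FALSE)
  # Table layout: parameter, estimate, rate, estimate CI, rate CI, p
  cols <- intersect(c("term", "estimate", "rate", "conf.low", "conf.high",
                      "rate.conf.low", "rate.conf.high", "p.value"),
                    names(fixed))
  readr::write_csv(fixed[, cols], file.path(d, "summary_table.csv"))
  invisible(NULL)
}

stage_describe <- function(config) {
  d <- config$out_dir
  panel <- read_panel(file.path(d, "panel.csv"))
  covars <- read_covariates(file.path(d, "covariates.csv"))
  rates <- suppressWarnings(county_rates(panel))
  readr::write_csv(rate_summary(rates), file.path(d, "rate_summary.csv"))

  diseases <- unique(panel$disease)
  if (length(diseases) == 2) {
    wide <- rates %>%
      filter(.data$gender == "M") %>%
      select("county_id", "disease", "rate_pct") %>%
      tidyr::pivot_wider(names_from = "disease", values_from = "rate_pct")
    rc <- rate_correlation(wide[[diseases[1]]], wide[[diseases[2]]])
    readr::write_csv(rc, file.path(d, "rate_correlation.csv"))
  }

  male <- rates %>%
    filter(.data$disease == diseases[1], .data$gender == "M") %>%
    left_join(covars, by = "county_id")
  for (pred in intersect(c("ConGenM", "CongMrepM", "Viral_M", "spont_abort"),
                         names(covars))) {
    prof <- decile_profile(male, !!rlang::sym(pred), .data$rate_pct)
    readr::write_csv(prof, file.path(d, sprintf("decile_%s.csv", pred)))
  }

  pts_path <- file.path(d, "patients.csv")
  if (file.exists(pts_path)) {
    pts <- read_patients(pts_path)
    flag <- paste0("flag_", diseases[1])
    or <- comorbidity_or(pts, !!rlang::sym(flag), .data$flag_ConGen,
                         stratum = .data$gender == "M")
    readr::write_csv(or, file.path(d, "comorbidity_or.csv"))
  }
  invisible(NULL)
}
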