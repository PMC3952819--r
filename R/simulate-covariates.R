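#' Default county covariate configuration
#'
#' Sampling distributions for the synthetic county covariates. Each entry is
#' a list with a `dist` element (`"gamma"`, `"normal"`, `"beta"`, or
#' `"point"`) and distribution parameters. Gamma entries are parameterised
#' by `mean` and `shape` (percent scale); beta entries by `shape1`/`shape2`
#' and are rescaled to percent; normal entries by `mean`/`sd`. `"point"`
#' entries are degenerate (constant) columns, convenient for controlled
#' experiments.
#'
#' The environmental-rate defaults are right-skewed gamma distributions
#' whose medians and maxima bracket the descriptive summaries of the US
#' claims data this generator emulates: male genital-malformation rates
#' (`ConGenM`) average 0.27% of the male population with county maxima
#' around 2.4%, other malformation and viral-infection rates are a few
#' tenths of a percent to a few percent. Ethnic proportions are drawn
#' jointly from a scaled Dirichlet with an unreported remainder category so
#' row sums never exceed 100. Income is in thousands of dollars per capita.
#'
#' The concentrations are chosen so that, at realistic fixed-effect
#' magnitudes, the implied log-rates stay in the regime of rare events:
#' covariates with large per-percent weights get modest between-county
#' dispersion, keeping every Poisson mean well below its population
#' offset.
#'
#' @return Named list of distribution specifications, plus `ethnic_alpha`
#'   (Dirichlet concentrations, including a trailing remainder category).
#' @export
covariate_config <- function() {
  list(
    Income  = list(dist = "normal", mean = 24, sd = 6, min = 2, max = 100),
    Poor    = list(dist = "beta", shape1 = 8, shape2 = 40),
    Urban   = list(dist = "beta", shape1 = 14, shape2 = 21),
    Insured = list(dist = "beta", shape1 = 12, shape2 = 3),
    ConGenM = list(dist = "gamma", mean = 0.27, shape = 1.05),
    ConGenF = list(dist = "gamma", mean = 0.15, shape = 1.05),
    CongMrepM = list(dist = "gamma", mean = 1.0, shape = 2),
    CongMrepF = list(dist = "gamma", mean = 1.0, shape = 2),
    Viral_M = list(dist = "gamma", mean = 2.0, shape = 2),
    Viral_F = list(dist = "gamma", mean = 2.2, shape = 2),
    ect_pr  = list(dist = "gamma", mean = 0.5, shape = 2),
    abnormal_concept = list(dist = "gamma", mean = 0.3, shape = 1.5),
    spont_abort = list(dist = "gamma", mean = 1.0, shape = 2),
    mult_gest = list(dist = "gamma", mean = 0.8, shape = 2),
    ethnic_alpha = c(AmInd = 4.8, Asian = 9.6, WHisp = 19.2, W = 160,
                     BHisp = 6.4, B = 25.6, Pacific = 1.6, Other = 32)
  )
}

ethnic_columns <- function() c("AmInd", "Asian", "WHisp", "W", "BHisp", "B", "Pacific")

#' Generate synthetic county-level covariates
#'
#' Draws one row of fixed-effect covariates per county: per-capita income
#' (thousands), socioeconomic percentages (`Poor`, `Urban`, `Insured`),
#' ethnic-composition percentages (jointly Dirichlet so their sum stays at
#' or below 100), and population-normalised environmental rates (congenital
#' malformations of the genitals and otherwise, by gender; viral infections
#' by gender; pregnancy-related rates). All percent columns are kept inside
#' \[0, 100\] by rejection-and-resampling; resampling events are reported
#' via a message.
#'
#' @param geo A `gp_geography` object.
#' @param config Covariate configuration, see [covariate_config()]. Entries
#'   can be overridden individually.
#' @param seed Integer seed; deterministic for a fixed seed and config.
#' @return A tibble with `county_id` and one column per covariate.
#' @examples
#' geo <- generate_geography(2, 3, seed = 1)
#' generate_covariates(geo, seed = 1)
#' @export
generate_covariates <- function(geo, config = covariate_config(), seed = 1L) {
  stopifnot(inherits(geo, "gp_geography"))
  config <- modifyList(covariate_config(), config)
  n <- nrow(geo$counties)

  with_seed(derive_seed(seed, "covariates"), {
    alpha <- config$ethnic_alpha
    g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
                nrow = n)
    eth <- 100 * g / rowSums(g)
    colnames(eth) <- names(alpha)
    eth <- eth[, ethnic_columns(), drop = FALSE]  # remainder category dropped

    scalar <- setdiff(names(config), "ethnic_alpha")
    cols <- lapply(scalar, function(nm) draw_covariate(n, config[[nm]], nm))
    names(cols) <- scalar

    out <- tibble(county_id = geo$counties$county_id)
    out <- dplyr::bind_cols(out, as_tibble(cols), as_tibble(eth))
    out
  })
}

# Internal: draw one covariate column, resampling values outside [min, max].
draw_covariate <- function(n, cfg, name) {
  lo <- cfg$min %||% 0
  hi <- cfg$max %||% 100
  draw <- switch(cfg$dist,
    gamma  = function(m) rgamma(m, shape = cfg$shape, scale = cfg$mean / cfg$shape),
    normal = function(m) rnorm(m, cfg$mean, cfg$sd),
    beta   = function(m) 100 * rbeta(m, cfg$shape1, cfg$shape2),
    point  = function(m) rep(cfg$value, m),
    abort(sprintf("unknown distribution '%s' for covariate %s", cfg$dist, name),
          class = "geopoisson_config_error")
  )
  x <- draw(n)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) > 0 && tries < 100L) {
    x[bad] <- draw(length(bad))
    bad <- bad[x[bad] < lo | x[bad] > hi]
    tries <- tries + 1L
  }
  if (tries > 0L) {
    inform(sprintf("covariate %s: resampled out-of-range draws (%d rounds).",
                   name, tries))
  }
  if (length(bad) > 0) {
    abort(sprintf("covariate %s: distribution keeps producing out-of-range values.",
                  name), class = "geopoisson_config_error")
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
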