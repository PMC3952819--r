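#' Specify the bivariate multilevel Poisson model
#'
#' A model specification names the response diseases and, per disease, the
#' fixed-effect covariates entering that disease's block of the design
#' matrix. The default reproduces the 22-weights-per-disease layout of the
#' county incidence analysis: an intercept plus gender, income,
#' socioeconomic and ethnic-composition percentages, the three male
#' environmental rates (`ConGenM`, `CongMrepM`, `Viral_M`), the binary
#' state policy codes (`CFR`, `DSM`, `ASD`) and the four-level `Eval` code,
#' which is expanded into three indicator columns against a reference
#' level.
#'
#' Gender is coded as an indicator (male = 0, female = 1 by default), so
#' the exponentiated gender weight is the female-to-male rate ratio. All
#' predictors, including the policy dummies, are mean-centered when the
#' design is built.
#'
#' @param diseases Character vector of disease labels (the bivariate
#'   response); length 1 or 2.
#' @param covariates Either a character vector (same covariates for every
#'   disease) or a named list, one character vector per disease. Use
#'   `"Eval"` to request the categorical policy code; it expands to
#'   indicator columns. `character(0)` gives an intercept-only block.
#' @param gender_coding Named numeric vector giving the numeric code per
#'   gender level; default `c(M = 0, F = 1)`.
#' @param center Logical; mean-center all non-intercept columns (default
#'   `TRUE`).
#' @param eval_reference The `Eval` level absorbed into the reference
#'   (default `-2`); the remaining three levels get indicator columns. The
#'   mapping of levels to policy meanings is configurable because published
#'   codings differ.
#' @param offset_col Name of the offset (population) column in panels.
#' @return An object of class `gp_model_spec`.
#' @examples
#' model_spec()                                   # default 44-weight layout
#' model_spec("ASD", covariates = character(0))   # univariate, intercept-only
#' @export
model_spec <- function(diseases = c("ASD", "ID"),
                       covariates = default_covariates(),
                       gender_coding = c(M = 0, F = 1),
                       center = TRUE,
                       eval_reference = -2L,
                       offset_col = "N") {
  if (length(diseases) < 1 || length(diseases) > 2 || anyDuplicated(diseases)) {
    abort("`diseases` must be 1 or 2 distinct labels.",
          class = "geopoisson_validation_error")
  }
  if (!is.list(covariates)) covariates <- setNames(
    rep(list(covariates), length(diseases)), diseases)
  if (!setequal(names(covariates), diseases)) {
    abort("`covariates` must be named by disease.",
          class = "geopoisson_validation_error")
  }
  covariates <- covariates[diseases]
  if (!eval_reference %in% c(-2L, -1L, 1L, 2L)) {
    abort("`eval_reference` must be one of -2, -1, 1, 2.",
          class = "geopoisson_validation_error")
  }
  structure(list(diseases = diseases, covariates = covariates,
                 gender_coding = gender_coding, center = center,
                 eval_reference = as.integer(eval_reference),
                 offset_col = offset_col),
            class = "gp_model_spec")
}

#' Default per-disease covariate list
#'
#' The 21 named covariates (expanding to 21 design columns: `Eval` becomes
#' three indicators) that, with the intercept, give 22 fixed-effect weights
#' per disease.
#' @return Character vector of covariate names.
#' @export
default_covariates <- function() {
  c("Gender", "Income", "Urban", "Insured", "Poor",
    "AmInd", "Asian", "WHisp", "W", "BHisp", "B", "Pacific",
    "ConGenM", "CongMrepM", "Viral_M",
    "CFR", "DSM", "ASD", "Eval")
}

# Internal: expand a covariate name vector to design column names.
expand_covariate_names <- function(covs, eval_reference = -2L) {
  out <- character(0)
  eval_levels <- setdiff(c(1L, 2L, -1L, -2L), eval_reference)
  for (cv in covs) {
    if (cv == "Eval") {
      out <- c(out, paste0("Eval", ifelse(eval_levels < 0,
                                          as.character(eval_levels),
                                          as.character(eval_levels))))
    } else {
      out <- c(out, cv)
    }
  }
  out
}

# Internal: number of fixed-effect columns per disease (incl. intercept).
n_fixed_per_disease <- function(spec) {
  vapply(spec$covariates, function(cv) {
    1L + length(expand_covariate_names(cv, spec$eval_reference))
  }, integer(1))
}

#' Count the free parameters of a model specification
#'
#' Fixed-effect weights (including intercepts) across the disease blocks,
#' plus the free elements of the two random-effect covariance matrices —
#' \eqn{d(d+1)/2} per level for \eqn{d} diseases, so 3 per level in the
#' bivariate model. The default specification has 44 fixed effects and 6
#' covariance parameters: 50 in total.
#'
#' @param spec A `gp_model_spec`.
#' @return Integer count.
#' @examples
#' count_free_parameters(model_spec())  # 50
#' @export
count_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "gp_model_spec"))
  d <- length(spec$diseases)
  sum(n_fixed_per_disease(spec)) + 2L * (d * (d + 1L)) %/% 2L
}

#' @export
print.gp_model_spec <- function(x, ...) {
  cat(sprintf("<gp_model_spec> diseases: %s; %s fixed effects; %d free parameters\n",
              paste(x$diseases, collapse = ", "),
              paste(n_fixed_per_disease(x), collapse = " + "),
              count_free_parameters(x)))
  invisible(x)
}

#' Serialize / restore a model specification
#'
#' @param spec A `gp_model_spec`.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return `write_model_spec()` returns `path` invisibly;
#'   `read_model_spec()` returns a `gp_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "gp_model_spec"))
  lst <- unclass(spec)
  lst$gender_coding <- as.list(lst$gender_coding)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  model_spec(diseases = unlist(lst$diseases),
             covariates = lapply(lst$covariates, unlist),
             gender_coding = unlist(lst$gender_coding),
             center = lst$center,
             eval_reference = lst$eval_reference,
             offset_col = lst$offset_col)
}

#' Bundle model parameters
#'
#' Collects the fixed-effect weight vector and the two random-effect
#' covariance matrices (state and county level). For \eqn{d} diseases each
#' covariance is \eqn{d \times d}; in the bivariate case its off-diagonal
#' element is the cross-phenotype covariance whose implied correlation is
#' reported alongside the fit.
#'
#' @param b Named or unnamed numeric vector of fixed-effect weights, in
#'   design-column order.
#' @param Sigma_state,Sigma_county Symmetric positive semi-definite
#'   matrices, one per hierarchy level.
#' @return An object of class `gp_parameter_set`.
#' @export
parameter_set <- function(b, Sigma_state, Sigma_county) {
  Sigma_state <- as.matrix(Sigma_state); Sigma_county <- as.matrix(Sigma_county)
  assert_psd(Sigma_state, "Sigma_state")
  assert_psd(Sigma_county, "Sigma_county")
  if (!all(dim(Sigma_state) == dim(Sigma_county))) {
    abort("state and county covariances must have the same dimension.",
          class = "geopoisson_validation_error")
  }
  structure(list(b = b, Sigma_state = Sigma_state, Sigma_county = Sigma_county),
            class = "gp_parameter_set")
}

#' @export
print.gp_parameter_set <- function(x, ...) {
  cat(sprintf("<gp_parameter_set> %d fixed effects; %dx%d covariances per level\n",
              length(x$b), nrow(x$Sigma_state), ncol(x$Sigma_state)))
  invisible(x)
}

#' Random-effect values over a hierarchy
#'
#' Container for state- and county-level random-effect values: one row per
#' unit, one column per disease. Used both for simulation truth and for
#' empirical-Bayes estimates.
#'
#' @param state Numeric matrix, states x diseases (rownames = state ids).
#' @param county Numeric matrix, counties x diseases (rownames = county ids).
#' @return An object of class `gp_random_effects`.
#' @export
random_effects <- function(state, county) {
  state <- as.matrix(state); county <- as.matrix(county)
  if (anyNA(state) || anyNA(county) || any(!is.finite(state)) || any(!is.finite(county))) {
    abort("random effects must be finite and complete.",
          class = "geopoisson_validation_error")
  }
  structure(list(state = state, county = county), class = "gp_random_effects")
}

#' @method as_tibble gp_random_effects
#' @export
as_tibble.gp_random_effects <- function(x, ...) {
  st <- as_tibble(x$state, rownames = "unit_id") %>%
    tidyr::pivot_longer(-"unit_id", names_to = "disease", values_to = "value") %>%
    mutate(level = "state")
  ct <- as_tibble(x$county, rownames = "unit_id") %>%
    tidyr::pivot_longer(-"unit_id", names_to = "disease", values_to = "value") %>%
    mutate(level = "county")
  bind_rows(st, ct) %>% select("level", "unit_id", "disease", "value")
}
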