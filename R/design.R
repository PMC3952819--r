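#' Build the regression design from panel, covariates and geography
#'
#' Assembles the level-1 response and design objects of the bivariate
#' three-level Poisson model: one row per (county, disease, gender) with
#' its case count `y` and population offset `N`; a fixed-effect matrix `X`
#' that is block-diagonal across the disease blocks (each disease carries
#' its own weights); and the random-effect incidence map giving each row's
#' state, county and disease index.
#'
#' County covariates and state policy codes are joined onto the rows; the
#' categorical `Eval` code is expanded to indicator columns against the
#' reference level; gender enters as a level-1 indicator. All non-intercept
#' columns are then mean-centered (within their disease block) so the
#' intercept is the log rate at average covariate values. Rows with a zero
#' population offset are dropped with a warning, since a log-link rate is
#' undefined for them; their counts are necessarily zero.
#'
#' @param panel An incidence panel: tibble with `county_id`, `disease`,
#'   `gender`, `y`, `N`.
#' @param covars County covariate tibble (from [generate_covariates()] or
#'   [read_covariates()]).
#' @param geo A `gp_geography`.
#' @param spec A `gp_model_spec`.
#' @return An object of class `gp_design`: list with `y`, `N`, `X`
#'   (dense matrix, named columns `"<disease>"` for the intercept and
#'   `"<disease>:<covariate>"` otherwise), integer maps `state_idx`,
#'   `county_idx`, `disease_idx`, lookup tibbles `states` and `counties`,
#'   the row metadata `rows`, and the `spec`.
#' @examples
#' geo <- generate_geography(2, 2, seed = 1)
#' cov <- generate_covariates(geo, seed = 1)
#' sim <- simulate_panel(geo, cov, default_parameters(), seed = 1)
#' d <- build_design(sim$panel, cov, geo)
#' dim(d$X)
#' @export
build_design <- function(panel, covars, geo, spec = model_spec()) {
  stopifnot(inherits(geo, "gp_geography"), inherits(spec, "gp_model_spec"))
  validate_panel(panel)

  needed <- setdiff(unique(unlist(spec$covariates)),
                    c("Gender", "CFR", "DSM", "ASD", "Eval"))
  missing_cols <- setdiff(needed, names(covars))
  if (length(missing_cols) > 0) {
    abort(sprintf("covariate table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "geopoisson_schema_error")
  }
  if (!all(panel$county_id %in% geo$counties$county_id) ||
      !all(panel$county_id %in% covars$county_id)) {
    abort("every panel county must appear in both `covars` and `geo`.",
          class = "geopoisson_schema_error")
  }

  rows <- panel %>%
    left_join(select(geo$counties, "county_id", "state_id"), by = "county_id") %>%
    left_join(covars, by = "county_id") %>%
    left_join(geo$states, by = "state_id")

  n_zero <- sum(rows$N == 0)
  if (n_zero > 0) {
    warn(sprintf("dropping %d row(s) with zero population offset.", n_zero))
    rows <- filter(rows, .data$N > 0)
  }

  # Canonical row order: disease block, then county (covariate-table order),
  # then gender.
  rows <- rows %>%
    mutate(ord_d = match(.data$disease, spec$diseases),
           ord_c = match(.data$county_id, covars$county_id),
           ord_g = match(.data$gender, names(spec$gender_coding))) %>%
    arrange(.data$ord_d, .data$ord_c, .data$ord_g)
  if (anyNA(rows$ord_d) || anyNA(rows$ord_g)) {
    abort("panel contains disease or gender labels not covered by the spec.",
          class = "geopoisson_schema_error")
  }

  counties <- tibble(county_id = unique(rows$county_id))
  counties$state_idx <- match(
    geo$counties$state_id[match(counties$county_id, geo$counties$county_id)],
    geo$states$state_id)
  states <- tibble(state_id = geo$states$state_id)

  disease_idx <- rows$ord_d
  county_idx <- match(rows$county_id, counties$county_id)
  state_idx <- counties$state_idx[county_idx]

  blocks <- lapply(seq_along(spec$diseases), function(k) {
    in_block <- which(disease_idx == k)
    Xk <- design_block(rows[in_block, , drop = FALSE], spec, k)
    list(rows = in_block, X = Xk)
  })
  p <- sum(vapply(blocks, function(b) ncol(b$X), integer(1)))
  X <- matrix(0, nrow(rows), p)
  cn <- character(p); at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(ncol(b$X))
    X[b$rows, idx] <- b$X
    cn[idx] <- colnames(b$X)
    at <- at + ncol(b$X)
  }
  colnames(X) <- cn

  structure(list(
    y = as.integer(rows$y), N = as.numeric(rows$N), X = X,
    state_idx = state_idx, county_idx = county_idx, disease_idx = disease_idx,
    states = states, counties = counties,
    rows = select(rows, "county_id", "state_id", "disease", "gender", "y", "N"),
    spec = spec
  ), class = "gp_design")
}

# Internal: one disease block of the fixed-effect matrix, mean-centered.
design_block <- function(rows, spec, k) {
  disease <- spec$diseases[k]
  covs <- spec$covariates[[disease]]
  cols <- list(rep(1, nrow(rows)))
  nms <- disease
  eval_levels <- setdiff(c(1L, 2L, -1L, -2L), spec$eval_reference)
  for (cv in covs) {
    if (cv == "Gender") {
      cols <- c(cols, list(unname(spec$gender_coding[rows$gender])))
      nms <- c(nms, paste0(disease, ":Gender"))
    } else if (cv == "Eval") {
      for (lv in eval_levels) {
        cols <- c(cols, list(as.numeric(rows$Eval == lv)))
        nms <- c(nms, paste0(disease, ":Eval", lv))
      }
    } else {
      cols <- c(cols, list(as.numeric(rows[[cv]])))
      nms <- c(nms, paste0(disease, ":", cv))
    }
  }
  Xk <- do.call(cbind, cols)
  colnames(Xk) <- nms
  if (spec$center && ncol(Xk) > 1) {
    Xk[, -1] <- scale(Xk[, -1, drop = FALSE], center = TRUE, scale = FALSE)
  }
  Xk
}

validate_panel <- function(panel) {
  req <- c("county_id", "disease", "gender", "y", "N")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols) > 0) {
    abort(sprintf("panel lacks column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "geopoisson_schema_error")
  }
  bad <- which(panel$y < 0 | panel$y > panel$N)
  if (length(bad) > 0) {
    abort(sprintf("panel rows with y < 0 or y > N: row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "geopoisson_validation_error")
  }
  key <- paste(panel$county_id, panel$disease, panel$gender)
  if (anyDuplicated(key)) {
    abort("panel has duplicate (county, disease, gender) rows.",
          class = "geopoisson_validation_error")
  }
  invisible(panel)
}

#' @export
print.gp_design <- function(x, ...) {
  cat(sprintf("<gp_design> %d rows x %d fixed effects; %d counties in %d states\n",
              length(x$y), ncol(x$X), nrow(x$counties), nrow(x$states)))
  invisible(x)
}

#' Export a design bundle as plain tables
#'
#' Writes the response/offset/index table and the centered fixed-effect
#' matrix as comma-separated files, for cross-checking the likelihood in
#' other environments.
#'
#' @param design A `gp_design`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows_path <- file.path(dir, "design_rows.csv")
  x_path <- file.path(dir, "design_X.csv")
  readr::write_csv(mutate(design$rows,
                          state_idx = design$state_idx,
                          county_idx = design$county_idx,
                          disease_idx = design$disease_idx), rows_path)
  readr::write_csv(as_tibble(design$X), x_path)
  invisible(c(rows_path, x_path))
}
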