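#' Solve 2x2 joint probabilities from margins and an odds ratio
#'
#' Given marginal probabilities \eqn{p_1, p_2} of two binary flags and a
#' target odds ratio \eqn{\psi}, returns the joint cell probability
#' \eqn{p_{11}} of the (Plackett) 2x2 distribution with those margins and
#' cross-product ratio. Errors if the requested odds ratio is infeasible
#' for the given margins, reporting the attainable range.
#'
#' @param p1,p2 Marginal probabilities in \[0, 1\].
#' @param psi Target odds ratio, positive.
#' @return The joint probability \eqn{P(\mathrm{both})}.
#' @export
joint_prob_from_or <- function(p1, p2, psi) {
  if (psi <= 0 || !is.finite(psi)) {
    abort(sprintf(
      "odds ratio %g infeasible; attainable range is (0, Inf) for interior margins.",
      psi), class = "geopoisson_feasibility_error")
  }
  if (p1 == 0 || p2 == 0) return(0)
  if (p1 == 1) return(p2)
  if (p2 == 1) return(p1)
  if (abs(psi - 1) < 1e-12) return(p1 * p2)
  s <- 1 + (p1 + p2) * (psi - 1)
  p11 <- (s - sqrt(s^2 - 4 * psi * (psi - 1) * p1 * p2)) / (2 * (psi - 1))
  lo <- max(0, p1 + p2 - 1); hi <- min(p1, p2)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    abort(sprintf("odds ratio %g infeasible for margins (%g, %g); p11 must lie in [%g, %g].",
                  psi, p1, p2, lo, hi), class = "geopoisson_feasibility_error")
  }
  min(max(p11, lo), hi)
}

#' Generate patient-level comorbidity records
#'
#' Builds a synthetic patient table consistent with a county incidence
#' panel: for each county and gender, `n_per_county` patients are drawn
#' whose disease flags match the county's empirical rates in expectation
#' and whose joint distribution with the congenital-malformation flag has
#' the requested odds ratio. The malformation flag is drawn first from the
#' county's genital-malformation rate (`ConGenM` for males, `ConGenF` for
#' females); each disease flag is then drawn from its conditional
#' probability given the malformation flag, derived from the pairwise 2x2
#' solve. Counties with zero prevalence contribute no flagged patients.
#'
#' @param panel Incidence panel tibble (`county_id`, `disease`, `gender`,
#'   `y`, `N`).
#' @param covars County covariates with `ConGenM` (and `ConGenF` if female
#'   strata are generated), in percent.
#' @param target_or Odds ratio between the first disease's flag and the
#'   malformation flag; positive.
#' @param seed Integer seed.
#' @param n_per_county Patients per county and gender (capped by the
#'   population offset).
#' @param or_second Optional odds ratio between the second disease and the
#'   malformation flag; by default the second disease is independent of it.
#' @param genders Gender strata to generate (default `"M"`).
#' @return Tibble with `patient_id`, `county_id`, `gender`, one logical
#'   `flag_<disease>` column per disease, and `flag_ConGen`.
#' @examples
#' s <- simulate_study(2, 5, seed = 3)
#' pts <- generate_patients(s$panel, s$covars, target_or = 5.53, seed = 3)
#' head(pts)
#' @export
generate_patients <- function(panel, covars, target_or, seed = 1L,
                              n_per_county = 50L, or_second = NULL,
                              genders = "M") {
  if (target_or <= 0) {
    abort("`target_or` must be positive.", class = "geopoisson_feasibility_error")
  }
  validate_panel(panel)
  diseases <- unique(panel$disease)

  rates <- panel %>%
    mutate(rate = ifelse(.data$N > 0, .data$y / .data$N, 0)) %>%
    select("county_id", "disease", "gender", "rate", "N") %>%
    tidyr::pivot_wider(names_from = "disease", values_from = "rate")

  with_seed(derive_seed(seed, "patients"), {
    out <- vector("list", 0L)
    for (g in genders) {
      cg_col <- if (g == "F") "ConGenF" else "ConGenM"
      if (!cg_col %in% names(covars)) {
        abort(sprintf("covariate table lacks %s.", cg_col),
              class = "geopoisson_schema_error")
      }
      rg <- filter(rates, .data$gender == g)
      p_cg <- covars[[cg_col]][match(rg$county_id, covars$county_id)] / 100
      n_i <- pmin(n_per_county, rg$N)
      for (i in seq_len(nrow(rg))) {
        n <- n_i[i]
        if (n <= 0) next
        cg <- runif(n) < p_cg[i]
        flags <- list()
        for (j in seq_along(diseases)) {
          p_dis <- rg[[diseases[j]]][i]
          psi <- if (j == 1L) target_or else (or_second %||% 1)
          if (p_dis <= 0) { flags[[j]] <- rep(FALSE, n); next }
          if (p_cg[i] <= 0 || p_cg[i] >= 1 || p_dis >= 1) {
            flags[[j]] <- runif(n) < p_dis; next
          }
          p11 <- joint_prob_from_or(p_dis, p_cg[i], psi)
          p_given_cg <- p11 / p_cg[i]
          p_given_no <- (p_dis - p11) / (1 - p_cg[i])
          flags[[j]] <- runif(n) < ifelse(cg, p_given_cg, p_given_no)
        }
        tb <- tibble(
          patient_id = sprintf("%s_%s_%06d", rg$county_id[i], g, seq_len(n)),
          county_id = rg$county_id[i], gender = g)
        for (j in seq_along(diseases)) tb[[paste0("flag_", diseases[j])]] <- flags[[j]]
        tb$flag_ConGen <- cg
        out[[length(out) + 1L]] <- tb
      }
    }
    bind_rows(out)
  })
}
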