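#' Empirical-Bayes random-effect estimates
#'
#' Point predictions of the state- and county-level random effects given
#' the data and a set of model parameters — the quantities mapped when
#' color-coding states or counties by their residual disease-rate
#' deviation after all fixed effects are accounted for.
#'
#' With `method = "mode"` (the Laplace path) the estimate is the joint
#' posterior mode of each state's block of effects, found by Newton
#' iteration, with uncertainty from the inverse curvature at the mode.
#' With a fitted MCMC object, use its `re_mean`/`re_sd` fields instead
#' (posterior means of the sampled effects). Counties whose counts sit
#' exactly at the fixed-effect prediction shrink to zero, and the
#' estimates shrink entirely to zero as the variances vanish.
#'
#' @param design A `gp_design`.
#' @param params A `gp_parameter_set` (from either fitter or simulation
#'   truth).
#' @return A `gp_random_effects` whose matrices carry `sd` attributes;
#'   [as_tibble()] turns it into a keyed long table for mapping.
#' @examples
#' s <- simulate_study(3, 5, seed = 7)
#' eb <- empirical_bayes(s$design, s$params)
#' head(as_tibble(eb))
#' @export
empirical_bayes <- function(design, params) {
  stopifnot(inherits(design, "gp_design"), inherits(params, "gp_parameter_set"))
  d <- length(design$spec$diseases)
  Qs <- solve(params$Sigma_state); Qc <- solve(params$Sigma_county)
  slices <- state_slices(design, params$b)
  S <- nrow(design$states); C <- nrow(design$counties)
  vs <- matrix(0, S, d); vc <- matrix(0, C, d)
  vs_sd <- matrix(0, S, d); vc_sd <- matrix(0, C, d)
  for (sl in slices) {
    md <- state_mode(sl, Qs, Qc, d)
    m <- length(sl$counties)
    se <- sqrt(diag(solve(md$negH)))
    vs[sl$state, ] <- md$u[seq_len(d)]
    vs_sd[sl$state, ] <- se[seq_len(d)]
    if (m > 0) {
      vc[sl$counties, ] <- matrix(md$u[-seq_len(d)], m, d, byrow = TRUE)
      vc_sd[sl$counties, ] <- matrix(se[-seq_len(d)], m, d, byrow = TRUE)
    }
  }
  dimnames(vs) <- dimnames(vs_sd) <- list(design$states$state_id,
                                          design$spec$diseases)
  dimnames(vc) <- dimnames(vc_sd) <- list(design$counties$county_id,
                                          design$spec$diseases)
  out <- random_effects(vs, vc)
  attr(out$state, "sd") <- vs_sd
  attr(out$county, "sd") <- vc_sd
  out
}
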