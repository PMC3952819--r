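#' Event rate ratio of a regression weight
#'
#' Under the log link, the exponential of a regression weight is the
#' multiplicative change in incidence rate per unit increase of the
#' covariate (for a credible-interval bound, the transform applies
#' elementwise).
#'
#' @param b_j Regression weight(s), finite numeric.
#' @return `exp(b_j)`.
#' @examples
#' event_rate_ratio(1.344962)  # 3.838041
#' @export
event_rate_ratio <- function(b_j) {
  stopifnot(is.numeric(b_j), all(is.finite(b_j)))
  exp(b_j)
}

#' Percent change in incidence rate
#'
#' Expresses a regression weight as the percent change in rate per unit
#' covariate increase: \eqn{100(\exp(b) - 1)}.
#'
#' @inheritParams event_rate_ratio
#' @return Percent change (numeric, percent units).
#' @examples
#' percent_change(1.344962)  # 283.8% rate increase
#' @export
percent_change <- function(b_j) {
  100 * (event_rate_ratio(b_j) - 1)
}

#' Correlation implied by a covariance
#'
#' Converts a random-effect covariance and the two variances into the
#' correlation coefficient \eqn{r = \mathrm{cov}/\sqrt{v_1 v_2}}.
#'
#' @param cov Covariance between the two diseases' random effects.
#' @param var1,var2 Positive variances.
#' @return Correlation in \[-1, 1\].
#' @examples
#' random_effect_correlation(2.666, 3.126, 2.398)  # 0.974
#' @export
random_effect_correlation <- function(cov, var1, var2) {
  if (any(var1 <= 0) || any(var2 <= 0)) {
    abort("variances must be positive.", class = "geopoisson_domain_error")
  }
  r <- cov / sqrt(var1 * var2)
  if (any(abs(r) > 1 + 1e-9)) {
    abort("implied correlation exceeds 1 in magnitude.",
          class = "geopoisson_domain_error")
  }
  pmin(pmax(r, -1), 1)
}
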