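#' Forest plot of event rate ratios
#'
#' Rate ratios (log scale) with 95% intervals for every fixed-effect
#' weight of a fitted model, split by disease block. The vertical line at
#' 1 marks "no effect".
#'
#' @param object A `gp_mcmc_fit` or `gp_laplace_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gp_mcmc_fit
#' @export
autoplot.gp_mcmc_fit <- function(object, ...) {
  plot_rate_forest(tidy(object), object$design$spec)
}

#' @rdname autoplot.gp_mcmc_fit
#' @method autoplot gp_laplace_fit
#' @export
autoplot.gp_laplace_fit <- function(object, ...) {
  plot_rate_forest(tidy(object), object$design$spec)
}

plot_rate_forest <- function(td, spec) {
  td <- td %>%
    mutate(disease = sub(":.*$", "", .data$term),
           covariate = ifelse(grepl(":", .data$term),
                              sub("^[^:]*:", "", .data$term), "(Intercept)"))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$rate,
                                   y = stats::reorder(.data$covariate,
                                                      .data$rate))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$rate.conf.low,
                                          xmax = .data$rate.conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~disease) +
    ggplot2::labs(x = "event rate ratio (95% interval)", y = NULL)
}

#' Plot a decile profile
#'
#' Mean outcome rate per predictor decile, the raw-data dose-response
#' view.
#'
#' @param object A `gp_decile_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gp_decile_profile
#' @export
autoplot.gp_decile_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$bin),
                                       y = .data$mean_outcome)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = sprintf("decile of %s", attr(object, "predictor") %||% "predictor"),
                  y = sprintf("mean %s", attr(object, "outcome") %||% "outcome"))
}

#' Histogram of county rates
#'
#' Percent incidence rates across counties, faceted by disease and
#' gender; the distributions are typically strongly right-skewed.
#'
#' @param object A `gp_rates` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gp_rates
#' @export
autoplot.gp_rates <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$rate_pct)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue") +
    ggplot2::facet_grid(gender ~ disease, scales = "free_y") +
    ggplot2::labs(x = "county rate (% of population)", y = "counties")
}

#' Bar chart of random-effect estimates by unit
#'
#' Map-ready view of empirical-Bayes (or true simulated) random effects:
#' one bar per state or county, per disease.
#'
#' @param raneff A `gp_random_effects`.
#' @param level `"state"` or `"county"`.
#' @return A ggplot object.
#' @export
plot_random_effects <- function(raneff, level = c("state", "county")) {
  level <- match.arg(level)
  td <- as_tibble(raneff) %>% filter(.data$level == !!level)
  ggplot2::ggplot(td, ggplot2::aes(x = stats::reorder(.data$unit_id, .data$value),
                                   y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~disease) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("%s-level random effect (log rate)", level))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
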