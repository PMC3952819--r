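#' Summarise posterior draws
#'
#' Per-parameter posterior mean, standard deviation, equal-tailed 95%
#' credible interval, the event-rate-ratio transform of the estimate and of
#' the interval endpoints (rate CI = exp of the estimate CI, elementwise),
#' and a two-sided MCMC p-value: twice the smaller tail fraction of draws
#' on either side of zero, floored at \eqn{2/M} for \eqn{M} retained draws.
#' When a tail is empty the p-value equals the floor and `p.censored` is
#' `TRUE`, to be read as "p below the resolution of the chain".
#'
#' @param draws Numeric matrix of retained draws (columns = parameters),
#'   with at least 100 rows.
#' @param conf_level Credible-interval mass (default 0.95).
#' @param rate If `TRUE`, add the exponential-transform columns.
#' @return A tibble, one row per parameter.
#' @export
summarize_posterior <- function(draws, conf_level = 0.95, rate = TRUE) {
  draws <- as.matrix(draws)
  M <- nrow(draws)
  if (M < 100) {
    abort("need at least 100 retained draws to summarise.",
          class = "geopoisson_validation_error")
  }
  a <- (1 - conf_level) / 2
  qs <- apply(draws, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  frac_pos <- colMeans(draws > 0)
  p_raw <- 2 * pmin(frac_pos, 1 - frac_pos)
  out <- tibble(
    term = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
    estimate = unname(colMeans(draws)),
    std.error = unname(apply(draws, 2, sd)),
    conf.low = unname(qs[1, ]), conf.high = unname(qs[2, ]),
    p.value = unname(pmax(p_raw, 2 / M)),
    p.censored = unname(p_raw < 2 / M)
  )
  if (rate) {
    out <- mutate(out,
                  rate = exp(.data$estimate),
                  rate.conf.low = exp(.data$conf.low),
                  rate.conf.high = exp(.data$conf.high))
  }
  out
}

#' Summaries of an MCMC fit
#'
#' Produces the two standard tables of the county-incidence analysis: the
#' fixed-effect table (posterior mean, credible interval, event rate ratio
#' with transformed interval, MCMC p-value) and the random-effect
#' covariance table (state- and county-level variances and the
#' cross-phenotype covariance with its credible interval, plus the implied
#' correlation computed from the covariance draws).
#'
#' @param object A `gp_mcmc_fit`.
#' @param conf_level Credible-interval mass.
#' @param ... Unused.
#' @return List with tibbles `fixed` and `covariance`.
#' @export
summary.gp_mcmc_fit <- function(object, conf_level = 0.95, ...) {
  d <- length(object$design$spec$diseases)
  p <- ncol(object$design$X)
  fixed <- summarize_posterior(object$draws[, seq_len(p), drop = FALSE],
                               conf_level = conf_level)
  cov_draws <- object$draws[, -seq_len(p), drop = FALSE]
  cov_tbl <- summarize_posterior(cov_draws, conf_level = conf_level,
                                 rate = FALSE) %>%
    mutate(level = ifelse(grepl("state", .data$term), "state", "county"))
  if (d == 2) {
    cors <- lapply(c("state", "county"), function(lv) {
      v1 <- cov_draws[, sprintf("Sigma_%s[1,1]", lv)]
      cv <- cov_draws[, sprintf("Sigma_%s[1,2]", lv)]
      v2 <- cov_draws[, sprintf("Sigma_%s[2,2]", lv)]
      r <- random_effect_correlation(cv, v1, v2)
      summarize_posterior(matrix(r, ncol = 1,
                                 dimnames = list(NULL, sprintf("r_%s", lv))),
                          conf_level = conf_level, rate = FALSE) %>%
        mutate(level = lv)
    })
    cov_tbl <- bind_rows(cov_tbl, bind_rows(cors))
  }
  list(fixed = fixed, covariance = cov_tbl)
}

#' @export
print.gp_mcmc_fit <- function(x, ...) {
  cat(sprintf("<gp_mcmc_fit> %d parameters, %d retained draws, %d chain(s); max split-Rhat %.3f%s\n",
              x$n_params, nrow(x$draws), x$chain$n_chains,
              max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else " (not converged)"))
  print(x$summary$fixed, n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed-effect table of a fit
#'
#' @param x A `gp_mcmc_fit` or `gp_laplace_fit`.
#' @param ... Passed to the summary.
#' @return Tibble with one row per fixed-effect weight: estimate,
#'   uncertainty, interval, event rate ratio with transformed interval,
#'   p-value.
#' @method tidy gp_mcmc_fit
#' @export
tidy.gp_mcmc_fit <- function(x, ...) x$summary$fixed

#' @rdname tidy.gp_mcmc_fit
#' @method tidy gp_laplace_fit
#' @export
tidy.gp_laplace_fit <- function(x, ...) {
  z <- qnorm(0.975)
  tibble(term = names(x$b), estimate = unname(x$b),
         std.error = unname(x$se_b),
         conf.low = unname(x$b - z * x$se_b),
         conf.high = unname(x$b + z * x$se_b)) %>%
    mutate(rate = exp(.data$estimate),
           rate.conf.low = exp(.data$conf.low),
           rate.conf.high = exp(.data$conf.high),
           p.value = 2 * stats::pnorm(-abs(.data$estimate / .data$std.error)))
}

#' One-line model overview
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return One-row tibble of fit-level facts.
#' @method glance gp_mcmc_fit
#' @export
glance.gp_mcmc_fit <- function(x, ...) {
  tibble(n_obs = length(x$design$y), n_params = x$n_params,
         n_draws = nrow(x$draws), n_chains = x$chain$n_chains,
         max_rhat = max(x$rhat, na.rm = TRUE), converged = x$converged)
}

#' @rdname glance.gp_mcmc_fit
#' @method glance gp_laplace_fit
#' @export
glance.gp_laplace_fit <- function(x, ...) {
  tibble(n_obs = length(x$design$y), logLik = x$loglik,
         n_params = length(x$b) + length(x$psi), converged = x$converged,
         iterations = x$outer_iterations)
}
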