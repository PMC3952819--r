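#' Per-capita county incidence rates
#'
#' Exact case-over-population ratios per (county, disease, gender) cell,
#' with the rate also expressed in percent. Rows with a zero population
#' offset are excluded with a warning.
#'
#' @param panel Incidence panel tibble.
#' @return Tibble of class `gp_rates` with `county_id`, `disease`,
#'   `gender`, `y`, `N`, `rate` (proportion), `rate_pct`.
#' @examples
#' s <- simulate_study(2, 5, seed = 1)
#' r <- county_rates(s$panel)
#' rate_summary(r)
#' @export
county_rates <- function(panel) {
  validate_panel(panel)
  n_zero <- sum(panel$N == 0)
  if (n_zero > 0) {
    warn(sprintf("excluding %d zero-offset row(s) from the rate table.", n_zero))
    panel <- filter(panel, .data$N > 0)
  }
  out <- panel %>%
    mutate(rate = .data$y / .data$N, rate_pct = 100 * .data$y / .data$N) %>%
    select("county_id", "disease", "gender", "y", "N", "rate", "rate_pct")
  class(out) <- c("gp_rates", class(out))
  out
}

#' Summarise county rates per disease and gender
#'
#' Unweighted mean, median and maximum of the per-county percent rates —
#' county-level summaries, every county counting once regardless of its
#' population.
#'
#' @param rates A `gp_rates` table from [county_rates()].
#' @return Tibble with one row per (disease, gender).
#' @export
rate_summary <- function(rates) {
  rates %>%
    as_tibble() %>%
    group_by(.data$disease, .data$gender) %>%
    summarise(n_counties = dplyr::n(),
              mean_pct = mean(.data$rate_pct),
              median_pct = median(.data$rate_pct),
              max_pct = max(.data$rate_pct), .groups = "drop")
}

#' Pearson correlation between two county rate vectors
#'
#' Product-moment correlation with its two-sided t-test, used for the
#' cross-phenotype county-rate association.
#'
#' @param rates_a,rates_b Numeric vectors of equal length (>= 3).
#' @return One-row tibble: `estimate`, `statistic`, `df`, `p.value`,
#'   `conf.low`, `conf.high`, `n`.
#' @export
rate_correlation <- function(rates_a, rates_b) {
  if (length(rates_a) != length(rates_b) || length(rates_a) < 3) {
    abort("need two equal-length vectors with n >= 3.",
          class = "geopoisson_validation_error")
  }
  if (sd(rates_a) == 0 || sd(rates_b) == 0) {
    abort("correlation undefined: a rate vector has zero variance.",
          class = "geopoisson_domain_error")
  }
  ct <- cor.test(rates_a, rates_b)
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         df = unname(ct$parameter), p.value = ct$p.value,
         conf.low = ct$conf.int[1], conf.high = ct$conf.int[2],
         n = length(rates_a))
}

#' Decile profile of an outcome over a predictor
#'
#' Ranks counties by a predictor, splits them into ten equal-count bins at
#' the empirical decile cut-points (inverted-CDF quantiles; ties broken by
#' stable input order, so the profile is invariant to any order-preserving
#' transform of the predictor) and reports the mean outcome per bin — the
#' raw-data view of a dose-response trend before any model adjustment.
#'
#' @param data A data frame with one row per county.
#' @param predictor,outcome Unquoted column names.
#' @param n_bins Number of quantile bins (default 10).
#' @return Tibble of class `gp_decile_profile`: `bin`, `pred_min`,
#'   `pred_max`, `mean_outcome`, `n`.
#' @examples
#' s <- simulate_study(3, 20, seed = 2)
#' r <- county_rates(s$panel) %>%
#'   dplyr::filter(disease == "ASD", gender == "M") %>%
#'   dplyr::left_join(s$covars, by = "county_id")
#' decile_profile(r, ConGenM, rate_pct)
#' @export
decile_profile <- function(data, predictor, outcome, n_bins = 10L) {
  pv <- eval_tidy(enquo(predictor), data)
  ov <- eval_tidy(enquo(outcome), data)
  n <- length(pv)
  if (n < n_bins) {
    abort(sprintf("need at least %d rows for %d bins.", n_bins, n_bins),
          class = "geopoisson_validation_error")
  }
  ord <- order(pv)                       # stable: ties keep input order
  bin_of_sorted <- ceiling(seq_len(n) * n_bins / n)
  bin <- integer(n); bin[ord] <- bin_of_sorted
  out <- tibble(bin = bin, pred = pv, outcome = ov) %>%
    group_by(.data$bin) %>%
    summarise(pred_min = min(.data$pred), pred_max = max(.data$pred),
              mean_outcome = mean(.data$outcome), n = dplyr::n(),
              .groups = "drop") %>%
    arrange(.data$bin)
  attr(out, "predictor") <- rlang::as_label(enquo(predictor))
  attr(out, "outcome") <- rlang::as_label(enquo(outcome))
  class(out) <- c("gp_decile_profile", class(out))
  out
}

#' Comorbidity odds ratio from patient-level flags
#'
#' Cross-tabulates two boolean patient flags (optionally within a stratum)
#' and reports the sample (cross-product) odds ratio, the two-sided
#' Fisher exact p-value, and a confidence interval — by default the normal
#' approximation on the log odds ratio; `ci_method = "exact"` gives the
#' conditional maximum-likelihood interval instead. If any cell is zero
#' the odds ratio is computed with the Haldane-Anscombe 0.5 continuity
#' correction and flagged in the `note` column.
#'
#' @param patients Patient-level data frame.
#' @param exposure,outcome Unquoted logical column names.
#' @param stratum Optional unquoted filtering expression (e.g.
#'   `gender == "M"`).
#' @param ci_method `"wald"` (log-OR normal approximation) or `"exact"`.
#' @param conf_level Confidence level.
#' @return One-row tibble: cell counts, `odds_ratio`, `conf.low`,
#'   `conf.high`, `p.value`, `ci_method`, `note`.
#' @examples
#' s <- simulate_study(2, 10, seed = 4, patients = TRUE, n_per_county = 200)
#' comorbidity_or(s$patients, flag_ASD, flag_ConGen, stratum = gender == "M")
#' @export
comorbidity_or <- function(patients, exposure, outcome, stratum = NULL,
                           ci_method = c("wald", "exact"), conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  sq <- enquo(stratum)
  if (!quo_is_null(sq)) {
    patients <- filter(patients, !!sq)
  }
  e <- eval_tidy(enquo(exposure), patients)
  o <- eval_tidy(enquo(outcome), patients)
  stopifnot(is.logical(e), is.logical(o))
  n11 <- sum(e & o); n10 <- sum(e & !o); n01 <- sum(!e & o); n00 <- sum(!e & !o)
  tab <- matrix(c(n11, n01, n10, n00), 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("a margin of the 2x2 table is empty; odds ratio undefined.",
          class = "geopoisson_validation_error")
  }
  note <- NA_character_
  cells <- c(n11, n10, n01, n00)
  if (any(cells == 0)) {
    cells <- cells + 0.5
    note <- "zero cell: Haldane-Anscombe 0.5 continuity correction applied"
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  ft <- fisher.test(tab, conf.level = conf_level)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (ci_method == "wald") {
    se <- sqrt(sum(1 / cells))
    ci <- exp(log(or) + c(-1, 1) * z * se)
  } else {
    ci <- ft$conf.int
  }
  tibble(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
         odds_ratio = or, conf.low = ci[1], conf.high = ci[2],
         p.value = ft$p.value, ci_method = ci_method, note = note)
}
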