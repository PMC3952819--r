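#' Generate a synthetic state/county hierarchy
#'
#' Builds a two-level geography — counties nested within states — with
#' gender-stratified county populations and per-state special-education
#' policy codes. The populations are the Poisson offsets \eqn{N_{ijkl}} of
#' the incidence model; the policy codes (`CFR`, `DSM`, `ASD`, `Eval`) are
#' categorical state-level covariates.
#'
#' County populations are drawn per gender from a log-normal distribution,
#' whose heavy right tail mimics the extreme size dispersion of US counties
#' (a few metropolitan counties holding millions next to thousands of small
#' rural ones). Policy codes are drawn i.i.d. per state from configurable
#' frequencies; they are a simulation fixture, not a claim about any actual
#' state statute.
#'
#' @param n_states Number of states (level-3 units). Must be >= 1.
#' @param counties_per_state Either a single count (every state gets the
#'   same number of counties), a length-2 integer range `c(lo, hi)` (each
#'   state draws uniformly from it), or a length-`n_states` vector of
#'   explicit counts. See [partition_counties()] to split a fixed national
#'   total (e.g. 3,111 counties over 51 states) into such a vector.
#' @param pop_distribution Named list with elements `meanlog` and `sdlog`
#'   of the per-gender log-normal population distribution.
#' @param policy_freq Named list of sampling probabilities for the policy
#'   codes: `CFR`, `DSM`, `ASD` over \eqn{\{-1, +1\}} and `Eval` over
#'   \eqn{\{-2, -1, 1, 2\}}.
#' @param seed Integer seed; the generator is bit-reproducible for a fixed
#'   seed and configuration.
#'
#' @return An object of class `gp_geography`: a list with tibbles
#'   `states` (`state_id`, `CFR`, `DSM`, `ASD`, `Eval`) and `counties`
#'   (`county_id`, `state_id`, `pop_male`, `pop_female`).
#'
#' @examples
#' geo <- generate_geography(3, counties_per_state = 4, seed = 1)
#' geo$counties
#' @export
generate_geography <- function(n_states,
                               counties_per_state,
                               pop_distribution = list(meanlog = log(11000), sdlog = 1.3),
                               policy_freq = default_policy_freq(),
                               seed = 1L) {
  if (!is.numeric(n_states) || length(n_states) != 1L || n_states < 1) {
    abort("`n_states` must be a positive integer.", class = "geopoisson_config_error")
  }
  n_states <- as.integer(n_states)
  if (any(counties_per_state < 1)) {
    abort("`counties_per_state` must be positive.", class = "geopoisson_config_error")
  }
  if (!is.numeric(pop_distribution$meanlog) || !is.numeric(pop_distribution$sdlog)) {
    abort("`pop_distribution` needs numeric `meanlog` and `sdlog`.",
          class = "geopoisson_config_error")
  }

  with_seed(derive_seed(seed, "geography"), {
    n_cty <- if (length(counties_per_state) == n_states) {
      as.integer(counties_per_state)
    } else if (length(counties_per_state) == 1L) {
      rep(as.integer(counties_per_state), n_states)
    } else if (length(counties_per_state) == 2L) {
      sample(seq(counties_per_state[1], counties_per_state[2]), n_states, replace = TRUE)
    } else {
      abort("`counties_per_state` must have length 1, 2, or `n_states`.",
            class = "geopoisson_config_error")
    }

    state_id <- sprintf("S%02d", seq_len(n_states))
    states <- tibble(
      state_id = state_id,
      CFR  = sample(c(-1L, 1L), n_states, replace = TRUE,
                    prob = policy_freq$CFR),
      DSM  = sample(c(-1L, 1L), n_states, replace = TRUE,
                    prob = policy_freq$DSM),
      ASD  = sample(c(-1L, 1L), n_states, replace = TRUE,
                    prob = policy_freq$ASD),
      Eval = sample(c(-2L, -1L, 1L, 2L), n_states, replace = TRUE,
                    prob = policy_freq$Eval)
    )

    total <- sum(n_cty)
    counties <- tibble(
      county_id  = sprintf("C%05d", seq_len(total)),
      state_id   = rep(state_id, n_cty),
      pop_male   = as.integer(round(exp(rnorm(total, pop_distribution$meanlog,
                                              pop_distribution$sdlog)))),
      pop_female = as.integer(round(exp(rnorm(total, pop_distribution$meanlog,
                                              pop_distribution$sdlog))))
    )
    new_geography(states, counties)
  })
}

#' Default sampling frequencies for state policy codes
#'
#' @return Named list of probability vectors for `CFR`, `DSM`, `ASD`
#'   (over -1, +1) and `Eval` (over -2, -1, 1, 2).
#' @export
default_policy_freq <- function() {
  list(CFR = c(0.5, 0.5), DSM = c(0.5, 0.5), ASD = c(0.5, 0.5),
       Eval = c(0.15, 0.25, 0.30, 0.30))
}

#' Partition a national county total across states
#'
#' Splits `total` counties over `n_states` states with every state keeping
#' at least `min_per_state`, drawing the split from a symmetric
#' Dirichlet-multinomial so state sizes vary realistically. Useful for the
#' national-scale configuration of 3,111 counties over 51 states.
#'
#' @param n_states Number of states.
#' @param total Total number of counties to distribute.
#' @param min_per_state Minimum counties per state.
#' @param concentration Dirichlet concentration; larger values give more
#'   even splits.
#' @param seed Integer seed.
#' @return Integer vector of length `n_states` summing to `total`.
#' @export
partition_counties <- function(n_states = 51L, total = 3111L,
                               min_per_state = 3L, concentration = 4,
                               seed = 1L) {
  stopifnot(total >= n_states * min_per_state)
  with_seed(derive_seed(seed, "partition"), {
    w <- rgamma(n_states, concentration, 1)
    free <- total - n_states * min_per_state
    n <- min_per_state + as.vector(rmultinom(1, free, w / sum(w)))
    as.integer(n)
  })
}

#' Preset geography scales
#'
#' `geography_preset("national")` reproduces the structure of the US claims
#' analysis — 51 states (50 plus the District of Columbia) holding 3,111
#' counties. `geography_preset("desk")` is a small configuration (10 states,
#' 200 counties) for interactive work and simulation studies.
#'
#' @param scale `"national"` or `"desk"`.
#' @param seed Integer seed.
#' @param ... Passed on to [generate_geography()].
#' @return A `gp_geography` object.
#' @export
geography_preset <- function(scale = c("desk", "national"), seed = 1L, ...) {
  scale <- match.arg(scale)
  if (scale == "national") {
    generate_geography(51L, partition_counties(51L, 3111L, seed = seed),
                       seed = seed, ...)
  } else {
    generate_geography(10L, partition_counties(10L, 200L, min_per_state = 5L,
                                               seed = seed),
                       seed = seed, ...)
  }
}

new_geography <- function(states, counties) {
  validate_geography(structure(list(states = states, counties = counties),
                               class = "gp_geography"))
}

validate_geography <- function(geo) {
  st <- geo$states; ct <- geo$counties
  if (anyDuplicated(ct$county_id)) {
    abort("county_ids must be unique.", class = "geopoisson_validation_error")
  }
  if (!all(ct$state_id %in% st$state_id)) {
    abort("every county must reference an existing state.",
          class = "geopoisson_validation_error")
  }
  if (any(ct$pop_male < 0) || any(ct$pop_female < 0)) {
    abort("populations must be nonnegative.", class = "geopoisson_validation_error")
  }
  bad_eval <- !st$Eval %in% c(-2L, -1L, 1L, 2L)
  bad_pm <- !st$CFR %in% c(-1L, 1L) | !st$DSM %in% c(-1L, 1L) | !st$ASD %in% c(-1L, 1L)
  if (any(bad_eval) || any(bad_pm)) {
    abort("policy codes outside their allowed sets.",
          class = "geopoisson_validation_error")
  }
  geo
}

#' @export
print.gp_geography <- function(x, ...) {
  cat(sprintf("<gp_geography> %d states, %d counties, total population %s\n",
              nrow(x$states), nrow(x$counties),
              format(sum(as.double(x$counties$pop_male) + x$counties$pop_female),
                     big.mark = ",")))
  invisible(x)
}
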