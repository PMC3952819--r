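# Design construction, linear predictor, conditional and marginal
# log-likelihoods.

test_that("default design has the bivariate 44-column block layout", {
  s <- small_study()
  d <- s$design
  expect_equal(ncol(d$X), 44)
  expect_equal(nrow(d$X), nrow(s$geo$counties) * 2 * 2)
  # block diagonality: first-disease columns are zero on second-disease rows
  second <- d$disease_idx == 2
  expect_true(all(d$X[second, 1:22] == 0))
  expect_true(all(d$X[!second, 23:44] == 0))
  # centering: every non-intercept column has mean ~0 within its block
  for (k in 1:2) {
    blk <- d$X[d$disease_idx == k, , drop = FALSE]
    nz <- setdiff(which(colSums(blk != 0) > 0), c(1, 23))
    expect_lt(max(abs(colMeans(blk[, nz]))), 1e-10)
  }
})

test_that("free-parameter count follows the spec dimensioning", {
  expect_identical(count_free_parameters(model_spec()), 50L)
  expect_identical(
    count_free_parameters(model_spec(covariates = character(0))), 8L)
  expect_identical(
    count_free_parameters(model_spec("ASD", covariates = character(0))), 3L)
})

test_that("single-county design has 4 rows mapped to one county and state", {
  geo <- generate_geography(1, 1, seed = 5)
  covars <- generate_covariates(geo, seed = 5)
  sim <- simulate_panel(geo, covars, default_parameters(), seed = 5)
  d <- sim$design
  expect_equal(nrow(d$X), 4)
  expect_true(all(d$county_idx == 1))
  expect_true(all(d$state_idx == 1))
})

test_that("zero-offset rows are dropped with a warning", {
  s <- small_study()
  panel <- s$panel
  panel$y[1] <- 0L
  panel$N[1] <- 0L
  expect_warning(d <- build_design(panel, s$covars, s$geo),
                 "zero population")
  expect_equal(nrow(d$X), nrow(panel) - 1)
})

test_that("missing covariate columns raise a schema error naming them", {
  s <- small_study()
  expect_error(build_design(s$panel, dplyr::select(s$covars, -"ConGenM"),
                            s$geo),
               "ConGenM", class = "geopoisson_schema_error")
})

test_that("linear predictor matches a hand-rolled per-row sum", {
  s <- small_study()
  d <- s$design
  set.seed(42)
  params <- parameter_set(rnorm(44, 0, 0.1), diag(0.5, 2), diag(0.2, 2))
  re <- random_effects(matrix(rnorm(nrow(d$states) * 2), ncol = 2),
                       matrix(rnorm(nrow(d$counties) * 2), ncol = 2))
  eta <- linear_predictor(d, params, re)
  oracle <- vapply(seq_along(d$y), function(r) {
    sum(d$X[r, ] * params$b) +
      re$state[d$state_idx[r], d$disease_idx[r]] +
      re$county[d$county_idx[r], d$disease_idx[r]]
  }, numeric(1))
  expect_equal(eta, oracle, tolerance = 1e-14)
  # trivial anchors
  z <- parameter_set(rep(0, 44), diag(2), diag(2))
  re0 <- random_effects(matrix(0, nrow(d$states), 2),
                        matrix(0, nrow(d$counties), 2))
  expect_true(all(linear_predictor(d, z, re0) == 0))
  expect_error(linear_predictor(d, parameter_set(1, diag(2), diag(2)), re0),
               class = "geopoisson_contract_error")
})

test_that("state and county effects cancel in the predictor when opposite", {
  t <- tiny_instance(seed = 8)
  re <- random_effects(matrix(0.5), matrix(-0.5))
  eta <- linear_predictor(t$design, t$params, re)
  expect_equal(unique(round(eta, 12)), log(0.001))
})

test_that("conditional loglik Poisson part matches closed forms", {
  spec1 <- model_spec("ASD", covariates = character(0))
  geo <- generate_geography(1, 1, seed = 2)
  covars <- generate_covariates(geo, seed = 2)
  # mean 1: N = 1, eta = 0, y = 0 -> log P = -1
  panel <- tibble::tibble(county_id = geo$counties$county_id,
                          disease = "ASD", gender = "M", y = 0L, N = 1L)
  d <- suppressWarnings(build_design(panel, covars, geo, spec1))
  p <- parameter_set(setNames(0, "ASD"), matrix(1e-12), matrix(1e-12))
  re0 <- random_effects(matrix(0), matrix(0))
  parts <- conditional_loglik(d, p, re0, parts = TRUE)
  expect_equal(parts$poisson, -1, tolerance = 1e-12)
  # N = 1000, eta = log(0.001), y = 1 -> mean 1 -> log P = -1
  panel2 <- dplyr::mutate(panel, y = 1L, N = 1000L)
  d2 <- suppressWarnings(build_design(panel2, covars, geo, spec1))
  p2 <- parameter_set(setNames(log(0.001), "ASD"), matrix(1e-12), matrix(1e-12))
  parts2 <- conditional_loglik(d2, p2, re0, parts = TRUE)
  expect_equal(parts2$poisson, -1, tolerance = 1e-12)
})

test_that("conditional loglik equals an independent summation oracle", {
  geo <- generate_geography(1, 3, seed = 13)
  covars <- generate_covariates(geo, seed = 13)
  sim <- simulate_panel(geo, covars, default_parameters(), seed = 13)
  d <- sim$design
  p <- default_parameters()
  re <- random_effects(sim$raneff$state[d$states$state_id, , drop = FALSE],
                       sim$raneff$county[d$counties$county_id, , drop = FALSE])
  got <- conditional_loglik(d, p, re)
  # oracle: accumulate terms row by row in reversed order, densities by hand
  eta <- linear_predictor(d, p, re)
  acc <- 0
  for (r in rev(seq_along(d$y))) {
    acc <- acc + d$y[r] * (log(d$N[r]) + eta[r]) - d$N[r] * exp(eta[r]) -
      lgamma(d$y[r] + 1)
  }
  dens2 <- function(v, S) {
    Si <- solve(S)
    -0.5 * sum(v * (Si %*% v)) - 0.5 * log(det(S)) - log(2 * pi)
  }
  for (i in seq_len(nrow(re$state))) acc <- acc + dens2(re$state[i, ], p$Sigma_state)
  for (i in seq_len(nrow(re$county))) acc <- acc + dens2(re$county[i, ], p$Sigma_county)
  expect_equal(got, acc, tolerance = 1e-12)
})

test_that("conditional loglik is invariant to row permutation", {
  geo <- generate_geography(2, 2, seed = 14)
  covars <- generate_covariates(geo, seed = 14)
  sim <- simulate_panel(geo, covars, default_parameters(), seed = 14)
  p <- default_parameters()
  re <- random_effects(
    sim$raneff$state[sim$design$states$state_id, , drop = FALSE],
    sim$raneff$county[sim$design$counties$county_id, , drop = FALSE])
  base <- conditional_loglik(sim$design, p, re)
  set.seed(1)
  for (i in 1:3) {
    perm <- sample(nrow(sim$panel))
    d2 <- build_design(sim$panel[perm, ], covars, geo, model_spec())
    expect_equal(conditional_loglik(d2, p, re), base, tolerance = 1e-10)
  }
})

test_that("marginal loglik matches a fine-grid integration oracle", {
  t <- tiny_instance(seed = 3)
  ml_q <- marginal_loglik(t$design, t$params, "adaptive_quadrature",
                          gh_points = c(15, 15))
  d <- t$design
  g <- seq(-4, 4, length.out = 801)
  h <- g[2] - g[1]
  f <- function(vs, vc) {
    eta <- t$params$b + vs + vc
    exp(sum(d$y * (log(d$N) + eta) - d$N * exp(eta) - lgamma(d$y + 1))) *
      dnorm(vs, 0, sqrt(0.4)) * dnorm(vc, 0, sqrt(0.3))
  }
  oracle <- log(sum(outer(g, g, Vectorize(f))) * h^2)
  expect_equal(ml_q, oracle, tolerance = 1e-8)
})

test_that("laplace marginal matches the 1-D oracle at high information", {
  t <- tiny_instance(seed = 3, pop = 1e9, var_county = 1e-12)
  d <- t$design
  ml_l <- marginal_loglik(d, t$params, "laplace")
  ctr <- log(sum(d$y) / (sum(d$N) * exp(t$params$b)))
  g <- seq(ctr - 0.05, ctr + 0.05, length.out = 200001)
  h <- g[2] - g[1]
  lv <- vapply(g, function(vs) {
    sum(d$y * (log(d$N) + t$params$b + vs) - d$N * exp(t$params$b + vs) -
          lgamma(d$y + 1)) + dnorm(vs, 0, sqrt(0.4), log = TRUE)
  }, numeric(1))
  m <- max(lv)
  oracle <- m + log(sum(exp(lv - m)) * h)
  expect_equal(ml_l, oracle, tolerance = 1e-6)
})

test_that("marginal loglik degenerates to the fixed-effects GLM limit", {
  s <- small_study()
  d <- s$design
  b <- s$params$b
  glm_ll <- sum(d$y * (log(d$N) + as.vector(d$X %*% b)) -
                  d$N * exp(as.vector(d$X %*% b)) - lgamma(d$y + 1))
  p0 <- parameter_set(b, diag(1e-10, 2), diag(1e-10, 2))
  expect_equal(marginal_loglik(d, p0, "laplace"), glm_ll, tolerance = 1e-6)
})

test_that("laplace and quadrature agree on information-rich instances", {
  # agreement tightens as per-cell counts grow; checked in that regime
  geo <- generate_geography(3, 4,
                            pop_distribution = list(meanlog = log(5e7),
                                                    sdlog = 0.1),
                            seed = 31)
  covars <- generate_covariates(geo, seed = 31)
  p <- default_parameters()
  sim <- simulate_panel(geo, covars, p, seed = 31)
  ml_l <- marginal_loglik(sim$design, p, "laplace")
  ml_q <- marginal_loglik(sim$design, p, "adaptive_quadrature")
  expect_equal(ml_l, ml_q, tolerance = 1e-3)
})

test_that("an empty state leaves the marginal loglik unchanged", {
  t <- tiny_instance(seed = 6)
  base <- marginal_loglik(t$design, t$params, "laplace")
  d2 <- t$design
  d2$states <- dplyr::bind_rows(d2$states, tibble::tibble(state_id = "S99"))
  expect_equal(marginal_loglik(d2, t$params, "laplace"), base,
               tolerance = 1e-12)
})

test_that("disease blocks are independent at zero covariance", {
  s <- small_study()
  d <- s$design
  p1 <- parameter_set(s$params$b, diag(c(0.5, 0.5)), diag(c(0.2, 0.2)))
  re0 <- random_effects(matrix(0, nrow(d$states), 2),
                        matrix(0, nrow(d$counties), 2))
  eta1 <- linear_predictor(d, p1, re0)
  b2 <- s$params$b
  b2[14] <- b2[14] + 1   # perturb a first-disease covariate weight
  p2 <- parameter_set(b2, diag(c(0.5, 0.5)), diag(c(0.2, 0.2)))
  eta2 <- linear_predictor(d, p2, re0)
  second <- d$disease_idx == 2
  expect_equal(eta1[second], eta2[second], tolerance = 1e-14)
  expect_false(isTRUE(all.equal(eta1[!second], eta2[!second])))
})

test_that("model spec round-trips through yaml and json", {
  spec <- model_spec(eval_reference = -1L)
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_model_spec(spec, path)
    back <- read_model_spec(path)
    expect_equal(back$diseases, spec$diseases)
    expect_equal(back$covariates, spec$covariates)
    expect_equal(back$eval_reference, spec$eval_reference)
  }
})
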