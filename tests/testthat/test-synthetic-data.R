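# Synthetic geography, covariates, incidence panels and patient tables.

test_that("generators are bit-reproducible for a fixed seed", {
  g1 <- generate_geography(4, c(2, 5), seed = 7)
  g2 <- generate_geography(4, c(2, 5), seed = 7)
  expect_identical(g1, g2)
  c1 <- generate_covariates(g1, seed = 7)
  expect_identical(c1, generate_covariates(g2, seed = 7))
  p <- default_parameters()
  s1 <- simulate_panel(g1, c1, p, seed = 7)
  s2 <- simulate_panel(g1, c1, p, seed = 7)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$raneff, s2$raneff)
  pt1 <- generate_patients(s1$panel, c1, 2, seed = 7, n_per_county = 20)
  expect_identical(pt1, generate_patients(s1$panel, c1, 2, seed = 7,
                                          n_per_county = 20))
})

test_that("geography has the requested structure and invariants", {
  geo <- generate_geography(1, 1, seed = 1)
  expect_equal(nrow(geo$counties), 1)
  n_cty <- partition_counties(51, 3111, seed = 1)
  expect_equal(sum(n_cty), 3111)
  geo_big <- generate_geography(51, n_cty, seed = 1)
  expect_equal(nrow(geo_big$states), 51)
  expect_equal(nrow(geo_big$counties), 3111)
  expect_false(anyDuplicated(geo_big$counties$county_id) > 0)
  expect_true(all(geo_big$counties$state_id %in% geo_big$states$state_id))
  expect_true(all(geo_big$counties$pop_male >= 0))
  expect_true(all(geo_big$states$Eval %in% c(-2L, -1L, 1L, 2L)))
  expect_error(generate_geography(0, 1), class = "geopoisson_config_error")
  expect_error(generate_geography(2, 0), class = "geopoisson_config_error")
})

test_that("covariates respect range and joint-sum invariants", {
  geo <- generate_geography(51, partition_counties(51, 3111, seed = 2),
                            seed = 2)
  covars <- generate_covariates(geo, seed = 2)
  expect_equal(nrow(covars), 3111)
  expect_false(anyNA(covars))
  eth <- as.matrix(covars[, c("AmInd", "Asian", "WHisp", "W", "BHisp", "B",
                              "Pacific")])
  expect_true(all(rowSums(eth) <= 100))
  pct <- setdiff(names(covars), c("county_id", "Income"))
  expect_true(all(as.matrix(covars[, pct]) >= 0 &
                    as.matrix(covars[, pct]) <= 100))
  # right-skewed malformation rates reach the published county maxima
  expect_gt(max(covars$ConGenM), 1.5)
  expect_lt(max(covars$ConGenM), 5)
  expect_lt(median(covars$ConGenM), mean(covars$ConGenM))
})

test_that("degenerate point-mass configs give constant columns", {
  geo <- generate_geography(2, 3, seed = 4)
  covars <- generate_covariates(
    geo, config = list(ConGenM = list(dist = "point", value = 0.3)), seed = 4)
  expect_true(all(covars$ConGenM == 0.3))
})

test_that("panel has one row per county-disease-gender cell with y <= N", {
  s <- small_study()
  expect_equal(nrow(s$panel), nrow(s$geo$counties) * 2 * 2)
  key <- with(s$panel, paste(county_id, disease, gender))
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(s$panel$y >= 0 & s$panel$y <= s$panel$N))
})

test_that("null model mean rate obeys the law of large numbers", {
  # intercept-only truth at rate 0.001, no random effects: the empirical
  # mean of y/N across many counties converges to 0.001
  spec1 <- model_spec("ASD", covariates = character(0))
  geo <- generate_geography(1, 100000,
                            pop_distribution = list(meanlog = log(10000),
                                                    sdlog = 0.5),
                            seed = 17)
  covars <- generate_covariates(geo, seed = 17)
  p <- parameter_set(setNames(log(0.001), "ASD"), matrix(1e-12), matrix(1e-12))
  sim <- simulate_panel(geo, covars, p, spec1, seed = 17)
  male <- sim$panel[sim$panel$gender == "M", ]
  rates <- male$y / male$N
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.001), 3 * se)
})

test_that("drawn random effects reproduce the specified covariances", {
  geo <- generate_geography(300, 10, seed = 23)
  covars <- generate_covariates(geo, seed = 23)
  p <- default_parameters()
  sim <- simulate_panel(geo, covars, p, seed = 23)
  # state-level correlation near its target
  r_state <- cor(sim$raneff$state)[1, 2]
  n <- nrow(sim$raneff$state)
  se_r <- (1 - 0.974^2) / sqrt(n - 3)
  expect_lt(abs(r_state - 0.974), 3 * se_r)
  # county-level sample covariance near its target
  vc <- sim$raneff$county
  cc <- cov(vc)
  m <- nrow(vc)
  for (i in 1:2) for (j in 1:2) {
    se_c <- sqrt((p$Sigma_county[i, i] * p$Sigma_county[j, j] +
                    p$Sigma_county[i, j]^2) / m)
    expect_lt(abs(cc[i, j] - p$Sigma_county[i, j]), 3 * se_c)
  }
})

test_that("zero-population counties always yield zero counts", {
  geo <- generate_geography(1, 3, seed = 5)
  geo$counties$pop_male[2] <- 0L
  geo$counties$pop_female[2] <- 0L
  covars <- generate_covariates(geo, seed = 5)
  sim <- simulate_panel(geo, covars, default_parameters(), seed = 5)
  zero_rows <- sim$panel$county_id == geo$counties$county_id[2]
  expect_true(all(sim$panel$y[zero_rows] == 0))
})

test_that("fixed effects are recovered by a GLM in the zero-variance limit", {
  p0 <- default_parameters()
  p_novar <- parameter_set(p0$b, diag(1e-12, 2), diag(1e-12, 2))
  geo <- generate_geography(10, 300, seed = 21)
  covars <- generate_covariates(geo, seed = 21)
  sim <- simulate_panel(geo, covars, p_novar, seed = 21)
  d <- sim$design
  g <- glm.fit(d$X, d$y, offset = log(d$N), family = poisson(),
               control = list(maxit = 100))
  info <- crossprod(d$X, d$X * g$fitted.values)
  se <- sqrt(diag(chol2inv(chol(info + diag(1e-9, ncol(d$X))))))
  z <- abs(g$coefficients - p0$b) / se
  expect_gte(mean(z <= 3), 0.95)
})

test_that("patient generation honors marginals and the target odds ratio", {
  # single large county: the 2x2 joint solved from margins + OR
  panel <- tibble::tibble(county_id = "C1",
                          disease = rep(c("ASD", "ID"), each = 2),
                          gender = rep(c("M", "F"), 2),
                          y = c(2000L, 500L, 300L, 200L),
                          N = rep(1000000L, 4))
  covars <- tibble::tibble(county_id = "C1", ConGenM = 0.5, ConGenF = 0.2)
  pts <- generate_patients(panel, covars, target_or = 5.53, seed = 1,
                           n_per_county = 1e6)
  tab <- table(pts$flag_ASD, pts$flag_ConGen)
  or_hat <- (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1])
  se_log <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or_hat) - log(5.53)), 3 * se_log)
  # marginal prevalence matches the county rate
  expect_lt(abs(mean(pts$flag_ASD) - 0.002), 3 * sqrt(0.002 / 1e6))
  # independence at OR 1
  pts1 <- generate_patients(panel, covars, target_or = 1, seed = 2,
                            n_per_county = 2e5)
  t1 <- table(pts1$flag_ASD, pts1$flag_ConGen)
  or1 <- (t1[2, 2] * t1[1, 1]) / (t1[1, 2] * t1[2, 1])
  expect_lt(abs(log(or1)), 3 * sqrt(sum(1 / t1)))
})

test_that("zero-prevalence counties contribute no flagged patients", {
  panel <- tibble::tibble(county_id = rep(c("C1", "C2"), 2),
                          disease = rep(c("ASD", "ID"), each = 2),
                          gender = "M",
                          y = c(0L, 10L, 0L, 0L), N = 1000L)
  covars <- tibble::tibble(county_id = c("C1", "C2"),
                           ConGenM = c(0, 1), ConGenF = c(0, 1))
  pts <- generate_patients(panel, covars, target_or = 5.53, seed = 3,
                           n_per_county = 500)
  c1 <- pts[pts$county_id == "C1", ]
  expect_false(any(c1$flag_ASD) || any(c1$flag_ConGen))
})

test_that("infeasible odds ratios are rejected with the attainable range", {
  expect_error(joint_prob_from_or(0.3, 0.4, -2),
               class = "geopoisson_feasibility_error")
  expect_error(joint_prob_from_or(0.3, 0.4, Inf),
               class = "geopoisson_feasibility_error")
  expect_equal(joint_prob_from_or(0.3, 0.4, 1), 0.12)
  # the solved cell always reproduces the requested odds ratio
  set.seed(9)
  for (i in 1:20) {
    p1 <- runif(1, 0.01, 0.9); p2 <- runif(1, 0.01, 0.9)
    psi <- exp(runif(1, -3, 3))
    p11 <- joint_prob_from_or(p1, p2, psi)
    or <- (p11 * (1 - p1 - p2 + p11)) / ((p1 - p11) * (p2 - p11))
    expect_equal(or, psi, tolerance = 1e-8)
  }
})
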