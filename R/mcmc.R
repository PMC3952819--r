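#' Prior specification for the Bayesian fit
#'
#' Weakly-informative defaults: independent zero-mean normal priors with
#' standard deviation 10 on every fixed-effect weight, and inverse-Wishart
#' priors (df 3, scale \eqn{0.1 I}) on each random-effect covariance —
#' proper but diffuse at the scale of log-rate effects.
#'
#' @param b_sd Prior standard deviation of each fixed effect.
#' @param iw_df Inverse-Wishart degrees of freedom (must exceed
#'   \eqn{d - 1}).
#' @param iw_scale Inverse-Wishart scale matrix, or a scalar multiplying
#'   the identity.
#' @return An object of class `gp_prior_spec`.
#' @export
prior_spec <- function(b_sd = 10, iw_df = 3, iw_scale = 0.1) {
  if (b_sd <= 0 || iw_df <= 0) {
    abort("priors must be proper: b_sd > 0, iw_df > 0.",
          class = "geopoisson_validation_error")
  }
  structure(list(b_sd = b_sd, iw_df = iw_df, iw_scale = iw_scale),
            class = "gp_prior_spec")
}

#' Markov chain configuration
#'
#' @param n_iter Total iterations per chain.
#' @param burnin Burn-in iterations discarded (must be < `n_iter`).
#'   Proposal scales adapt during burn-in only, preserving detailed
#'   balance afterwards.
#' @param thin Thinning interval for retained draws.
#' @param n_chains Number of chains (>= 1).
#' @param seed Master seed; each chain derives its own stream.
#' @param adapt Adapt proposal scales during burn-in.
#' @return An object of class `gp_chain_config`.
#' @export
chain_config <- function(n_iter = 25000L, burnin = 5000L, thin = 2L,
                         n_chains = 2L, seed = 1L, adapt = TRUE) {
  if (burnin >= n_iter || n_chains < 1 || thin < 1) {
    abort("need burnin < n_iter, thin >= 1 and n_chains >= 1.",
          class = "geopoisson_validation_error")
  }
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = seed, adapt = isTRUE(adapt)),
            class = "gp_chain_config")
}

#' Fit the multilevel bivariate Poisson model by MCMC
#'
#' Metropolis-within-Gibbs sampler: random-walk Metropolis updates for each
#' fixed-effect weight and for each state's and county's random-effect
#' pair (all county blocks are conditionally independent given the state
#' effects, so they are updated in one vectorised sweep, and likewise the
#' state blocks), with conjugate inverse-Wishart draws for the two
#' covariance matrices given the sampled effects. Proposal scales adapt
#' toward standard acceptance targets during burn-in only. The sampler is
#' deterministic given the chain seed.
#'
#' @param design A `gp_design`.
#' @param priors A `gp_prior_spec`.
#' @param chain A `gp_chain_config`.
#' @param prior_only If `TRUE`, drop the likelihood term and sample the
#'   prior hierarchy (random effects drawn directly from their Gaussian,
#'   covariances by the conjugate update); used for sampler validation.
#' @return An object of class `gp_mcmc_fit`: retained draws (fixed effects
#'   and covariance entries) pooled over chains, per-chain draw arrays,
#'   posterior means/sds of the random effects, split-\eqn{\hat R}
#'   convergence diagnostics, acceptance rates, and the summary tables
#'   (see [summary.gp_mcmc_fit()]).
#' @examples
#' s <- simulate_study(3, 5, seed = 1)
#' fit <- fit_mcmc(s$design, chain = chain_config(400, 200, 1, 1, seed = 1))
#' tidy(fit)
#' @export
fit_mcmc <- function(design, priors = prior_spec(),
                     chain = chain_config(), prior_only = FALSE) {
  stopifnot(inherits(design, "gp_design"), inherits(priors, "gp_prior_spec"),
            inherits(chain, "gp_chain_config"))
  d <- length(design$spec$diseases)
  if (priors$iw_df <= d - 1) {
    abort("inverse-Wishart df must exceed dimension - 1.",
          class = "geopoisson_validation_error")
  }
  chains <- lapply(seq_len(chain$n_chains), function(ch) {
    run_chain(design, priors, chain, chain_seed = derive_seed(chain$seed,
                                                              paste0("chain", ch)),
              prior_only = prior_only)
  })

  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  avg_over_chains <- function(field) {
    lapply(setNames(c("state", "county"), c("state", "county")), function(lv) {
      Reduce(`+`, lapply(chains, function(ch) ch[[field]][[lv]])) / length(chains)
    })
  }
  re_mean <- avg_over_chains("re_mean")
  re_sd <- lapply(avg_over_chains("re_var"), sqrt)
  rhat <- split_rhat(lapply(chains, `[[`, "draws"))
  converged <- all(is.finite(rhat)) && max(rhat, na.rm = TRUE) < 1.05
  if (!converged) {
    warn(sprintf("chains not converged by split-Rhat < 1.05 (max = %.3f); summaries are provisional.",
                 max(rhat, na.rm = TRUE)))
  }

  fit <- structure(list(
    draws = draws, chain_draws = lapply(chains, `[[`, "draws"),
    re_mean = re_mean, re_sd = re_sd,
    accept = chains[[1]]$accept, rhat = rhat, converged = converged,
    design = design, priors = priors, chain = chain,
    n_params = ncol(draws)), class = c("gp_mcmc_fit", "gp_fit"))
  fit$summary <- summary(fit)
  fit
}

# Internal: one MCMC chain.
run_chain <- function(design, priors, chain, chain_seed, prior_only) {
  X <- design$X; y <- design$y; N <- design$N
  d <- length(design$spec$diseases)
  p <- ncol(X); S <- nrow(design$states); C <- nrow(design$counties)
  sidx <- design$state_idx; cidx <- design$county_idx; didx <- design$disease_idx

  col_disease <- didx[apply(X != 0, 2, which.max)]
  rows_by_col <- lapply(seq_len(p), function(j) which(didx == col_disease[j]))
  Xcol <- lapply(seq_len(p), function(j) X[rows_by_col[[j]], j])
  county_state <- design$counties$state_idx
  # classify columns by the coarsest hierarchy level they are constant
  # within: such columns admit likelihood-invariant translation moves
  # against that level's random effects (parameter expansion), which break
  # the slow confounded directions of the posterior
  col_level <- character(p)
  xs_list <- vector("list", p); xc_list <- vector("list", p)
  for (j in seq_len(p)) {
    rj <- rows_by_col[[j]]; xj <- X[rj, j]
    sv <- tapply(xj, design$state_idx[rj], function(v) diff(range(v)))
    cv <- tapply(xj, design$county_idx[rj], function(v) diff(range(v)))
    if (max(sv) < 1e-12) {
      col_level[j] <- "state"
      xs <- numeric(nrow(design$states))
      xs[as.integer(names(sv))] <- tapply(xj, design$state_idx[rj], `[`, 1)
      xs_list[[j]] <- xs
    } else if (max(cv) < 1e-12) {
      col_level[j] <- "county"
      xc <- numeric(nrow(design$counties))
      xc[as.integer(names(cv))] <- tapply(xj, design$county_idx[rj], `[`, 1)
      xc_list[[j]] <- xc
    } else {
      col_level[j] <- "none"
    }
  }

  S0 <- if (is.matrix(priors$iw_scale)) priors$iw_scale else diag(priors$iw_scale, d)
  nu0 <- priors$iw_df

  with_seed(chain_seed, {
    b <- if (prior_only) rep(0, p) else glm_start(X, y, N)
    Vs <- matrix(0, S, d); Vc <- matrix(0, C, d)
    Sig_s <- diag(0.5, d); Sig_c <- diag(0.5, d)
    eta <- as.vector(X %*% b) + Vs[cbind(sidx, didx)] + Vc[cbind(cidx, didx)]
    mu <- N * exp(eta)

    scale_b <- rep(0.05, p); scale_c <- rep(0.4, C); scale_s <- rep(0.3, S)
    acc_b <- numeric(p); acc_c <- numeric(C); acc_s <- numeric(S); win <- 0L
    # Fisher preconditioner at the GLM start for joint fixed-effect moves
    mu0 <- N * exp(pmin(as.vector(X %*% b), 0))
    Fjoint <- crossprod(X, X * mu0) + diag(1e-6 * max(mu0), p)
    Rfish <- chol(Fjoint)
    scale_bj <- 1; acc_bj <- 0

    keep <- seq(chain$burnin + 1L, chain$n_iter) %% chain$thin == 0L
    M <- sum(keep)
    nm <- c(colnames(X), sigma_names(d))
    draws <- matrix(NA_real_, M, length(nm), dimnames = list(NULL, nm))
    re_sum <- list(s = matrix(0, S, d), c = matrix(0, C, d),
                   s2 = matrix(0, S, d), c2 = matrix(0, C, d))
    m_at <- 0L

    for (it in seq_len(chain$n_iter)) {
      if (prior_only) {
        Vs <- mvn_draw(S, Sig_s); Vc <- mvn_draw(C, Sig_c)
        b <- rnorm(p, 0, priors$b_sd)
      } else {
        Qs <- solve(Sig_s); Qc <- solve(Sig_c)
        # fixed effects: per-coordinate random-walk Metropolis
        for (j in seq_len(p)) {
          delta <- rnorm(1, 0, scale_b[j])
          rj <- rows_by_col[[j]]
          de <- Xcol[[j]] * delta
          mu_new <- mu[rj] * exp(de)
          dll <- sum(y[rj] * de) - sum(mu_new - mu[rj]) +
            dnorm(b[j] + delta, 0, priors$b_sd, log = TRUE) -
            dnorm(b[j], 0, priors$b_sd, log = TRUE)
          if (is.finite(dll) && log(runif(1)) < dll) {
            b[j] <- b[j] + delta
            eta[rj] <- eta[rj] + de
            mu[rj] <- mu_new
            acc_b[j] <- acc_b[j] + 1
          }
        }
        # county effects: conditionally independent blocks, one sweep
        upd <- block_rw_update(Vc, cidx, didx, eta, mu, y, N, Qc, scale_c)
        Vc <- upd$V; eta <- upd$eta; mu <- upd$mu; acc_c <- acc_c + upd$acc
        # state effects
        upd <- block_rw_update(Vs, sidx, didx, eta, mu, y, N, Qs, scale_s)
        Vs <- upd$V; eta <- upd$eta; mu <- upd$mu; acc_s <- acc_s + upd$acc

        # joint fixed-effect move, preconditioned by the GLM Fisher matrix
        step <- backsolve(Rfish, rnorm(p)) * scale_bj
        eta_new <- eta + as.vector(X %*% step)
        mu_new <- N * exp(eta_new)
        dll <- sum(y * (eta_new - eta)) - sum(mu_new - mu) +
          sum(dnorm(b + step, 0, priors$b_sd, log = TRUE) -
                dnorm(b, 0, priors$b_sd, log = TRUE))
        if (is.finite(dll) && log(runif(1)) < dll) {
          b <- b + step; eta <- eta_new; mu <- mu_new; acc_bj <- acc_bj + 1
        }

        # translation moves: shift a hierarchy-constant covariate's weight
        # while absorbing the shift into that level's random effects. The
        # likelihood is invariant and the conditional of the shift given
        # everything else is Gaussian, so this is an exact Gibbs draw that
        # traverses the confounded weight/random-effect ridges directly.
        tau2 <- priors$b_sd^2
        for (j in seq_len(p)) {
          lv <- col_level[j]
          if (lv == "none") next
          k <- col_disease[j]
          if (lv == "state") {
            x <- xs_list[[j]]; V <- Vs; Q <- Qs
          } else {
            x <- xc_list[[j]]; V <- Vc; Q <- Qc
          }
          prec <- 1 / tau2 + Q[k, k] * sum(x^2)
          mean_d <- (sum(x * as.vector(V %*% Q[, k])) - b[j] / tau2) / prec
          dlt <- rnorm(1, mean_d, sqrt(1 / prec))
          b[j] <- b[j] + dlt
          if (lv == "state") Vs[, k] <- Vs[, k] - dlt * x
          else Vc[, k] <- Vc[, k] - dlt * x
        }

        # translation between each state's effect and its counties'
        # effects: again an exact multivariate-Gaussian Gibbs draw
        m_s <- tabulate(county_state, S)
        QcVc_sum <- rowsum_safe2(Vc %*% Qc, county_state, S)
        for (s0 in seq_len(S)) {
          Pd <- Qs + m_s[s0] * Qc
          rhs <- -as.vector(Qs %*% Vs[s0, ]) + QcVc_sum[s0, ]
          ch <- chol(Pd)
          mean_d <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
          dlt <- mean_d + backsolve(ch, rnorm(d))
          Vs[s0, ] <- Vs[s0, ] + dlt
          in_s <- county_state == s0
          Vc[in_s, ] <- sweep(Vc[in_s, , drop = FALSE], 2, dlt, `-`)
        }
      }

      # conjugate inverse-Wishart updates of the covariances
      Sig_s <- riwish(nu0 + S, S0 + crossprod(Vs))
      Sig_c <- riwish(nu0 + C, S0 + crossprod(Vc))

      win <- win + 1L
      if (chain$adapt && it <= chain$burnin && win == 50L) {
        scale_b <- adapt_scale(scale_b, acc_b / 50, 0.44)
        scale_c <- adapt_scale(scale_c, acc_c / 50, 0.30)
        scale_s <- adapt_scale(scale_s, acc_s / 50, 0.30)
        scale_bj <- adapt_scale(scale_bj, acc_bj / 50, 0.25)
        acc_b[] <- 0; acc_c[] <- 0; acc_s[] <- 0
        acc_bj <- 0; win <- 0L
      }
      if (it == chain$burnin) { acc_b[] <- 0; acc_c[] <- 0; acc_s[] <- 0 }

      if (it > chain$burnin && keep[it - chain$burnin]) {
        m_at <- m_at + 1L
        draws[m_at, ] <- c(b, sigma_entries(Sig_s), sigma_entries(Sig_c))
        re_sum$s <- re_sum$s + Vs; re_sum$s2 <- re_sum$s2 + Vs^2
        re_sum$c <- re_sum$c + Vc; re_sum$c2 <- re_sum$c2 + Vc^2
      }
      if (!prior_only && !all(is.finite(mu))) {
        abort("divergent chain: non-finite Poisson means.",
              class = "geopoisson_divergence_error")
      }
    }

    re_mean <- list(state = re_sum$s / M, county = re_sum$c / M)
    re_var <- list(state = pmax(re_sum$s2 / M - (re_sum$s / M)^2, 0),
                   county = pmax(re_sum$c2 / M - (re_sum$c / M)^2, 0))
    rownames(re_mean$state) <- rownames(re_var$state) <- design$states$state_id
    rownames(re_mean$county) <- rownames(re_var$county) <- design$counties$county_id
    post_iter <- chain$n_iter - chain$burnin
    list(draws = draws, re_mean = re_mean, re_var = re_var,
         accept = list(b = acc_b / post_iter,
                       county = acc_c / post_iter,
                       state = acc_s / post_iter))
  })
}

# Internal: vectorised random-walk Metropolis over conditionally
# independent unit blocks (all counties, or all states).
block_rw_update <- function(V, unit_idx, didx, eta, mu, y, N, Q, scales) {
  n_unit <- nrow(V); d <- ncol(V)
  E <- matrix(rnorm(n_unit * d), n_unit, d) * scales
  de <- E[cbind(unit_idx, didx)]
  mu_new <- mu * exp(de)
  dll <- rowsum_safe(y * de - (mu_new - mu), unit_idx, n_unit)
  Vn <- V + E
  dprior <- -0.5 * (rowSums((Vn %*% Q) * Vn) - rowSums((V %*% Q) * V))
  acc <- log(runif(n_unit)) < (dll + dprior)
  acc[!is.finite(dll + dprior)] <- FALSE
  V[acc, ] <- Vn[acc, ]
  touched <- acc[unit_idx]
  eta[touched] <- eta[touched] + de[touched]
  mu[touched] <- mu_new[touched]
  list(V = V, eta = eta, mu = mu, acc = as.numeric(acc))
}

# Internal: rowsum over matrix rows grouped by index, fixed group count.
rowsum_safe2 <- function(X, group, n) {
  out <- matrix(0, n, ncol(X))
  sm <- rowsum(X, group)
  out[as.integer(rownames(sm)), ] <- sm
  out
}

adapt_scale <- function(s, rate, target) {
  s * exp(pmin(pmax(rate - target, -0.25), 0.25))
}

# Internal: inverse-Wishart draw via the Wishart of the inverse scale.
riwish <- function(df, S) {
  W <- rWishart(1, df, solve(S))[, , 1]
  solve(W)
}

sigma_names <- function(d) {
  nm <- function(level) {
    idx <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
    sprintf("Sigma_%s[%d,%d]", level, idx[, "row"], idx[, "col"])
  }
  c(nm("state"), nm("county"))
}

sigma_entries <- function(S) S[upper.tri(S, diag = TRUE)]

glm_start <- function(X, y, N) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, offset = log(N), family = poisson())),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate design: start at the pooled log rate per intercept column
    coef <- numeric(ncol(X))
    intercepts <- which(colSums(X == 0) == 0 | colMeans(X != 0) > 0.99)
    for (j in seq_len(ncol(X))) {
      rows <- which(X[, j] != 0)
      if (length(rows) > 0 && all(X[rows, j] == 1)) {
        coef[j] <- log(max(sum(y[rows]), 0.5) / sum(N[rows]))
      }
    }
    return(coef)
  }
  coef <- fit$coefficients
  coef[!is.finite(coef)] <- 0
  coef
}

# Internal: split-Rhat per parameter across (half-)chains.
split_rhat <- function(chain_list) {
  halves <- list()
  for (ch in chain_list) {
    M <- nrow(ch)
    h <- M %/% 2
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(h + 1):(2 * h), , drop = FALSE]))
  }
  m <- length(halves); n <- nrow(halves[[1]])
  vapply(seq_len(ncol(halves[[1]])), function(j) {
    x <- vapply(halves, function(h) h[, j], numeric(n))
    mns <- colMeans(x); vars <- apply(x, 2, stats::var)
    W <- mean(vars)
    B <- n * stats::var(mns)
    if (W < .Machine$double.eps) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1)) |> setNames(colnames(chain_list[[1]]))
}
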