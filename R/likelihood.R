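#' Linear predictor of the multilevel Poisson model
#'
#' Computes the log-rate \eqn{\eta = X b + v_{state} + v_{county}} for each
#' design row; the expected count of a row is \eqn{N \exp(\eta)}.
#'
#' @param design A `gp_design`.
#' @param params A `gp_parameter_set`.
#' @param raneff A `gp_random_effects` whose matrices are ordered like
#'   `design$states` and `design$counties`.
#' @return Numeric vector of log-rates, one per design row.
#' @export
linear_predictor <- function(design, params, raneff) {
  stopifnot(inherits(design, "gp_design"), inherits(params, "gp_parameter_set"),
            inherits(raneff, "gp_random_effects"))
  if (length(params$b) != ncol(design$X)) {
    abort(sprintf("length(b) = %d but design has %d fixed-effect columns.",
                  length(params$b), ncol(design$X)),
          class = "geopoisson_contract_error")
  }
  d <- length(design$spec$diseases)
  if (nrow(raneff$state) != nrow(design$states) ||
      nrow(raneff$county) != nrow(design$counties) ||
      ncol(raneff$state) != d || ncol(raneff$county) != d) {
    abort("random-effect matrices do not match the design's hierarchy.",
          class = "geopoisson_contract_error")
  }
  as.vector(design$X %*% params$b) +
    raneff$state[cbind(design$state_idx, design$disease_idx)] +
    raneff$county[cbind(design$county_idx, design$disease_idx)]
}

#' Conditional log-likelihood given the random effects
#'
#' The Poisson log-likelihood of the observed counts at the linear
#' predictor implied by `params` and `raneff`,
#' \eqn{\sum_r [y_r (\log N_r + \eta_r) - N_r e^{\eta_r} - \log(y_r!)]},
#' plus the log-densities of the state-level effects under
#' \eqn{N(0, \Sigma_{state})} and of the county-level effects under
#' \eqn{N(0, \Sigma_{county})}. Factorial terms are computed through the
#' log-gamma function and retained, so values are comparable across
#' methods and implementations.
#'
#' @inheritParams linear_predictor
#' @param parts If `TRUE`, return a list with elements `poisson`,
#'   `raneff`, and `total` instead of the scalar total.
#' @return Scalar log-likelihood (or a list when `parts = TRUE`).
#' @export
conditional_loglik <- function(design, params, raneff, parts = FALSE) {
  assert_psd(params$Sigma_state, "Sigma_state")
  assert_psd(params$Sigma_county, "Sigma_county")
  eta <- linear_predictor(design, params, raneff)
  pois <- sum(design$y * (log(design$N) + eta) - design$N * exp(eta) -
                lgamma(design$y + 1))
  re <- sum(mvn_logdens(raneff$state, params$Sigma_state)) +
    sum(mvn_logdens(raneff$county, params$Sigma_county))
  if (parts) list(poisson = pois, raneff = re, total = pois + re)
  else pois + re
}

# ---------------------------------------------------------------------------
# Per-state slices and the inner mode/Hessian machinery shared by the
# Laplace and adaptive-quadrature marginalizations and by empirical Bayes.

# Internal: index rows/counties by state, with fixed-effect offsets o = Xb.
state_slices <- function(design, b) {
  o <- as.vector(design$X %*% b)
  lapply(seq_len(nrow(design$states)), function(s) {
    cty <- which(design$counties$state_idx == s)
    rows <- which(design$state_idx == s)
    list(state = s, counties = cty, rows = rows,
         y = design$y[rows], N = design$N[rows], o = o[rows],
         # county position within this state's block, and disease index
         cpos = match(design$county_idx[rows], cty),
         dis = design$disease_idx[rows])
  })
}

# Internal: joint log-density (Poisson rows + Gaussian priors) of one
# state's random effects u = c(v_state (d), v_county (m*d)), its gradient
# and negative Hessian. u is indexed state-major then county-major,
# disease-minor.
state_joint <- function(sl, u, Qs, Qc, d, want_hessian = FALSE) {
  m <- length(sl$counties)
  vs <- u[seq_len(d)]
  vc <- matrix(u[-seq_len(d)], ncol = d, byrow = TRUE)  # m x d
  eta <- sl$o + vs[sl$dis] + vc[cbind(sl$cpos, sl$dis)]
  mu <- sl$N * exp(eta)
  f <- sum(sl$y * (log(sl$N) + eta) - mu - lgamma(sl$y + 1)) -
    0.5 * sum(vs * (Qs %*% vs)) + 0.5 * determinant(Qs)$modulus -
    0.5 * d * log(2 * pi) -
    0.5 * sum((vc %*% Qc) * vc) + 0.5 * m * determinant(Qc)$modulus -
    0.5 * m * d * log(2 * pi)
  f <- as.numeric(f)

  res <- sl$y - mu
  # index of each row's county component within u (county-major, disease-minor)
  comp <- d + (sl$cpos - 1L) * d + sl$dis
  g_state <- vapply(seq_len(d), function(k) sum(res[sl$dis == k]), numeric(1)) -
    as.vector(Qs %*% vs)
  g_cty <- rowsum_safe(res, comp, d + m * d)[-seq_len(d)] -
    as.vector(Qc %*% t(vc))
  grad <- c(g_state, g_cty)

  H <- NULL
  if (want_hessian) {
    q <- d + m * d
    H <- matrix(0, q, q)
    mu_state <- vapply(seq_len(d), function(k) sum(mu[sl$dis == k]), numeric(1))
    mu_comp <- rowsum_safe(mu, comp, q)
    diag(H) <- c(mu_state, mu_comp[-seq_len(d)])
    # state-county cross terms couple only within the same disease
    if (m > 0) {
      for (k in seq_len(d)) {
        idx <- seq(d + k, q, by = d)
        H[k, idx] <- H[idx, k] <- mu_comp[idx]
      }
    }
    # add the Gaussian prior precisions
    H[seq_len(d), seq_len(d)] <- H[seq_len(d), seq_len(d)] + Qs
    for (c0 in seq_len(m)) {
      idx <- d + (c0 - 1L) * d + seq_len(d)
      H[idx, idx] <- H[idx, idx] + Qc
    }
    # H is the negative Hessian (positive definite)
  }
  list(f = f, grad = grad, negH = H)
}

rowsum_safe <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Internal: Newton mode of one state's random effects. Returns mode,
# objective at mode, and negative Hessian there.
state_mode <- function(sl, Qs, Qc, d, start = NULL, tol = 1e-10, maxit = 50L) {
  m <- length(sl$counties)
  u <- start %||% numeric(d + m * d)
  cur <- state_joint(sl, u, Qs, Qc, d, want_hessian = TRUE)
  for (it in seq_len(maxit)) {
    step <- tryCatch(solve(cur$negH, cur$grad), error = function(e) {
      solve(cur$negH + diag(1e-8, nrow(cur$negH)), cur$grad)
    })
    t_step <- 1
    repeat {
      u_new <- u + t_step * step
      cand <- state_joint(sl, u_new, Qs, Qc, d, want_hessian = TRUE)
      if (is.finite(cand$f) && cand$f >= cur$f - 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-10) { cand <- cur; u_new <- u; break }
    }
    moved <- cand$f - cur$f
    u <- u_new; cur <- cand
    if (abs(moved) < tol && sqrt(sum(cur$grad^2)) < 1e-6) break
  }
  list(u = u, f = cur$f, negH = cur$negH, grad = cur$grad)
}

#' Marginal log-likelihood, integrating out the random effects
#'
#' Approximates \eqn{\log \int p(y \mid b, v)\, p(v \mid \Sigma)\, dv},
#' factorised over states (county effects are nested inside their state's
#' integral). Two approximations are available: a Laplace approximation at
#' the joint per-state mode, and a nested adaptive Gauss-Hermite scheme
#' that integrates each county's effects on a mode-centered grid
#' conditional on the state effect, then the state effect on an outer
#' adapted grid. Both are deterministic given their settings; the
#' quadrature method is the more accurate on small blocks and the Laplace
#' method scales to many counties per state.
#'
#' @param design A `gp_design`.
#' @param params A `gp_parameter_set` with positive-definite covariances.
#' @param method `"laplace"` or `"adaptive_quadrature"`.
#' @param gh_points Nodes per dimension for the quadrature method:
#'   `c(outer, inner)` for the state and county grids.
#' @return Scalar approximate marginal log-likelihood.
#' @export
marginal_loglik <- function(design, params,
                            method = c("laplace", "adaptive_quadrature"),
                            gh_points = c(7L, 5L)) {
  method <- match.arg(method)
  stopifnot(inherits(design, "gp_design"), inherits(params, "gp_parameter_set"))
  d <- length(design$spec$diseases)
  Qs <- solve(params$Sigma_state); Qc <- solve(params$Sigma_county)
  slices <- state_slices(design, params$b)
  total <- 0
  for (sl in slices) {
    total <- total + if (method == "laplace") {
      state_marginal_laplace(sl, Qs, Qc, d)
    } else {
      state_marginal_aghq(sl, params$Sigma_state, params$Sigma_county,
                          Qs, Qc, d, gh_points)
    }
  }
  total
}

state_marginal_laplace <- function(sl, Qs, Qc, d) {
  md <- state_mode(sl, Qs, Qc, d)
  q <- length(md$u)
  ch <- tryCatch(chol(md$negH), error = function(e) {
    warn("Hessian not positive definite at mode; adding jitter.")
    chol(md$negH + diag(1e-6, q))
  })
  md$f + 0.5 * q * log(2 * pi) - sum(log(diag(ch)))
}

# Nested adaptive Gauss-Hermite: outer grid over the state effect (adapted
# at the joint mode with the state block of the inverse joint Hessian),
# inner per-county grids adapted at the county conditional mode given each
# outer node.
state_marginal_aghq <- function(sl, Ss, Sc, Qs, Qc, d, gh_points) {
  md <- state_mode(sl, Qs, Qc, d)
  gh_out <- pracma::gaussHermite(gh_points[1])
  gh_in <- pracma::gaussHermite(gh_points[2])
  q <- length(md$u)
  cov_joint <- tryCatch(solve(md$negH), error = function(e) {
    solve(md$negH + diag(1e-6, q))
  })
  L_out <- t(chol(as.matrix(cov_joint[seq_len(d), seq_len(d), drop = FALSE])))

  nodes <- gh_grid(gh_out, d)            # t-nodes (n x d), log-weights
  m <- length(sl$counties)
  logvals <- numeric(nrow(nodes$t))
  for (j in seq_len(nrow(nodes$t))) {
    vs <- md$u[seq_len(d)] + sqrt(2) * as.vector(L_out %*% nodes$t[j, ])
    lv <- mvn_logdens(rbind(vs), Ss)
    for (c0 in seq_len(m)) {
      lv <- lv + county_integral_aghq(sl, c0, vs, Sc, Qc, d, gh_in)
    }
    logvals[j] <- lv + nodes$logw[j] + sum(nodes$t[j, ]^2)
  }
  # log of sum( w_j e^{||t||^2} g(node_j) ) + d/2 log 2 + log det L
  logsumexp(logvals) + 0.5 * d * log(2) + sum(log(diag(L_out)))
}

# Internal: log integral over one county's effects given the state effect.
county_integral_aghq <- function(sl, c0, vs, Sc, Qc, d, gh) {
  rows <- which(sl$cpos == c0)
  y <- sl$y[rows]; N <- sl$N[rows]; o <- sl$o[rows] + vs[sl$dis[rows]]
  dis <- sl$dis[rows]
  obj <- function(vc) {
    eta <- o + vc[dis]
    sum(y * (log(N) + eta) - N * exp(eta) - lgamma(y + 1)) +
      mvn_logdens(rbind(vc), Sc)
  }
  # 2-D (or 1-D) Newton for the conditional mode
  vc <- numeric(d)
  for (it in 1:50) {
    eta <- o + vc[dis]; mu <- N * exp(eta)
    g <- vapply(seq_len(d), function(k) sum((y - mu)[dis == k]), numeric(1)) -
      as.vector(Qc %*% vc)
    Hm <- diag(vapply(seq_len(d), function(k) sum(mu[dis == k]), numeric(1)), d) + Qc
    step <- solve(Hm, g)
    f0 <- obj(vc); t_step <- 1
    repeat {
      vn <- vc + t_step * step
      if (is.finite(obj(vn)) && obj(vn) >= f0 - 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-10) { vn <- vc; break }
    }
    conv <- sqrt(sum((vn - vc)^2)) < 1e-10
    vc <- vn
    if (conv) break
  }
  eta <- o + vc[dis]; mu <- N * exp(eta)
  Hm <- diag(vapply(seq_len(d), function(k) sum(mu[dis == k]), numeric(1)), d) + Qc
  L <- t(chol(solve(Hm)))
  nodes <- gh_grid(gh, d)
  lv <- vapply(seq_len(nrow(nodes$t)), function(j) {
    v <- vc + sqrt(2) * as.vector(L %*% nodes$t[j, ])
    obj(v) + nodes$logw[j] + sum(nodes$t[j, ]^2)
  }, numeric(1))
  logsumexp(lv) + 0.5 * d * log(2) + sum(log(diag(L)))
}

# Internal: product grid of 1-D Gauss-Hermite nodes in d dimensions.
gh_grid <- function(gh, d) {
  if (d == 1) return(list(t = matrix(gh$x, ncol = 1), logw = log(gh$w)))
  g <- expand.grid(rep(list(seq_along(gh$x)), d))
  t_nodes <- matrix(gh$x[as.matrix(g)], ncol = d)
  logw <- rowSums(matrix(log(gh$w)[as.matrix(g)], ncol = d))
  list(t = t_nodes, logw = logw)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
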