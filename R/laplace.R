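#' Fit the model by Laplace marginal maximum likelihood
#'
#' Maximum-likelihood cross-check of the Bayesian fit. The random effects
#' are integrated out by a Laplace approximation at their joint mode; the
#' fixed effects are profiled at the penalised joint mode by a sparse
#' Newton solver (all states and counties at once), and the covariance
#' parameters — on an unconstrained log-Cholesky scale that keeps both
#' matrices positive definite — are optimised by box-constrained
#' quasi-Newton over the profiled Laplace objective. Standard errors for
#' the fixed effects are Wald errors from the inverse joint Hessian at the
#' optimum, conditional on the fitted covariances.
#'
#' The `"auto"` start solves the fixed-effects-only Poisson regression
#' (standard IRLS with the log-population offset) and starts both
#' random-effect variances at 0.1. In the degenerate limit of vanishing
#' variances the objective reduces exactly to the fixed-effects Poisson
#' GLM log-likelihood.
#'
#' @param design A `gp_design`.
#' @param start `"auto"`, or a `gp_parameter_set` providing starting
#'   values.
#' @param fix_sigma If `TRUE` (requires `start` to be a
#'   `gp_parameter_set`), the covariances are held at their starting
#'   values and only the fixed and random effects are fitted — fitting
#'   with known variance components. With variances near zero this is the
#'   exact zero-variance limit of the model, a plain Poisson GLM.
#' @param control List: `outer_maxit` (quasi-Newton iterations),
#'   `inner_tol` (penalised-mode Newton tolerance), `var_floor`
#'   (lower bound on random-effect standard deviations).
#' @return An object of class `gp_laplace_fit`: `b`, `se_b`,
#'   `Sigma_state`, `Sigma_county`, maximised `loglik`, the random-effect
#'   modes, and a convergence flag (`converged = FALSE` returns the best
#'   iterate rather than failing).
#' @examples
#' s <- simulate_study(3, 8, seed = 5)
#' fit <- fit_laplace(s$design)
#' glance(fit)
#' @export
fit_laplace <- function(design, start = "auto", control = list(),
                        fix_sigma = FALSE) {
  stopifnot(inherits(design, "gp_design"))
  ctl <- modifyList(list(outer_maxit = 60L, inner_tol = 1e-10,
                         var_floor = 1e-4), control)
  d <- length(design$spec$diseases)
  X <- design$X; y <- design$y; N <- design$N
  p <- ncol(X); S <- nrow(design$states); C <- nrow(design$counties)
  q <- d * (S + C)

  # random-effect incidence matrix: states unit-major then counties
  Z <- Matrix::sparseMatrix(
    i = rep(seq_along(y), 2),
    j = c((design$state_idx - 1L) * d + design$disease_idx,
          d * S + (design$county_idx - 1L) * d + design$disease_idx),
    x = 1, dims = c(length(y), q))
  Xs <- Matrix::Matrix(X, sparse = TRUE)

  if (identical(start, "auto")) {
    b <- glm_start(X, y, N)
    Ss <- diag(0.1, d); Sc <- diag(0.1, d)
  } else {
    stopifnot(inherits(start, "gp_parameter_set"))
    b <- start$b; Ss <- start$Sigma_state; Sc <- start$Sigma_county
  }

  env <- new.env()
  env$theta <- c(b, numeric(q))

  profile_obj <- function(psi) {
    Sg <- tryCatch(psi_to_sigmas(psi, d), error = function(e) NULL)
    if (is.null(Sg)) return(1e10)
    sol <- tryCatch(
      penalized_mode(Xs, Z, y, N, Sg$Qs, Sg$Qc, S, C, d, env$theta, ctl$inner_tol),
      error = function(e) NULL)
    if (is.null(sol)) return(1e10)
    env$theta <- sol$theta
    # Laplace marginal: penalised joint at the mode, plus the Gaussian
    # normalisation and the curvature correction over the random effects
    logdet_P <- -S * as.numeric(determinant(Sg$Ss)$modulus) -
      C * as.numeric(determinant(Sg$Sc)$modulus)
    Hvv <- sol$Hvv
    ch <- Matrix::Cholesky(Hvv, LDL = FALSE, perm = TRUE)
    logdet_H <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    val <- sol$pois_ll - 0.5 * sol$quad + 0.5 * logdet_P - 0.5 * logdet_H
    if (!is.finite(val)) return(1e10)
    -val
  }

  psi0 <- c(sigma_to_psi(Ss), sigma_to_psi(Sc))
  if (fix_sigma) {
    if (identical(start, "auto")) {
      abort("`fix_sigma = TRUE` requires explicit starting covariances.",
            class = "geopoisson_validation_error")
    }
    opt <- list(par = psi0, convergence = 0L,
                counts = c(`function` = 1L))
  } else {
    lower <- rep(c(log(ctl$var_floor), -20)[psi_bound_pattern(d)], 2)
    upper <- rep(c(log(50), 20)[psi_bound_pattern(d)], 2)
    opt <- optim(psi0, profile_obj, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = ctl$outer_maxit, factr = 1e7,
                                pgtol = 1e-10))
  }
  converged <- opt$convergence == 0
  if (!converged) {
    warn("Laplace fit did not fully converge; returning best iterate.")
  }

  # boundary polish: the log-Cholesky scale puts zero variance infinitely
  # far away with a vanishing gradient, so a quasi-Newton iterate can
  # stall above the floor when the true maximiser is degenerate. Test the
  # floored-variance candidate for each level and keep any improvement.
  k <- d * (d + 1) / 2
  floor_psi <- sigma_to_psi(diag(ctl$var_floor^2, d))
  best <- opt$par
  best_val <- profile_obj(best)
  for (cand_idx in if (fix_sigma) list() else
         list(seq_len(k), k + seq_len(k), seq_len(2 * k))) {
    cand <- best
    cand[cand_idx] <- rep(floor_psi, length.out = length(cand_idx))
    val <- profile_obj(cand)
    if (val < best_val - 1e-10) {
      best <- cand
      best_val <- val
    }
  }
  opt$par <- best

  final <- -profile_obj(opt$par)
  Sg <- psi_to_sigmas(opt$par, d)
  theta <- env$theta
  b_hat <- theta[seq_len(p)]
  names(b_hat) <- colnames(X)
  sol <- penalized_mode(Xs, Z, y, N, Sg$Qs, Sg$Qc, S, C, d, theta, ctl$inner_tol)
  # columns carrying no data (e.g. a policy level absent from the sampled
  # states) have zero curvature: their weights get NA standard errors
  no_info <- colSums(X^2) == 0
  Hd <- as.matrix(sol$H)
  keep_idx <- c(which(!no_info), p + seq_len(q))
  se_b <- setNames(rep(NA_real_, p), colnames(X))
  inv <- tryCatch(chol2inv(chol(Hd[keep_idx, keep_idx])), error = function(e) {
    warn("joint Hessian near-singular; standard errors use a ridge.")
    chol2inv(chol(Hd[keep_idx, keep_idx] +
                    diag(1e-8 * max(diag(Hd)), length(keep_idx))))
  })
  se_b[!no_info] <- sqrt(diag(inv))[seq_len(sum(!no_info))]

  u <- theta[-seq_len(p)]
  vs <- matrix(u[seq_len(d * S)], S, d, byrow = TRUE,
               dimnames = list(design$states$state_id, design$spec$diseases))
  vc <- matrix(u[-seq_len(d * S)], C, d, byrow = TRUE,
               dimnames = list(design$counties$county_id, design$spec$diseases))

  structure(list(b = b_hat, se_b = se_b,
                 Sigma_state = Sg$Ss, Sigma_county = Sg$Sc,
                 psi = opt$par, loglik = final,
                 raneff = random_effects(vs, vc),
                 converged = converged, outer_iterations = opt$counts[["function"]],
                 design = design),
            class = c("gp_laplace_fit", "gp_fit"))
}

#' @export
print.gp_laplace_fit <- function(x, ...) {
  cat(sprintf("<gp_laplace_fit> logLik %.3f; %d fixed effects; converged: %s\n",
              x$loglik, length(x$b), x$converged))
  invisible(x)
}

# Internal: joint Newton over (b, v) of the penalised Poisson
# log-likelihood at fixed covariance precisions. Sparse; warm-started.
penalized_mode <- function(Xs, Z, y, N, Qs, Qc, S, C, d, theta0, tol,
                           maxit = 60L) {
  p <- ncol(Xs); q <- ncol(Z)
  P <- Matrix::bdiag(Matrix::kronecker(Matrix::Diagonal(S), Qs),
                     Matrix::kronecker(Matrix::Diagonal(C), Qc))
  theta <- theta0
  obj <- function(theta) {
    eta <- as.vector(Xs %*% theta[seq_len(p)] + Z %*% theta[-seq_len(p)])
    u <- theta[-seq_len(p)]
    pll <- sum(y * (log(N) + eta) - N * exp(eta) - lgamma(y + 1))
    list(val = pll - 0.5 * sum(u * as.vector(P %*% u)), pll = pll, eta = eta,
         quad = sum(u * as.vector(P %*% u)))
  }
  cur <- obj(theta)
  for (it in seq_len(maxit)) {
    mu <- N * exp(cur$eta)
    res <- y - mu
    u <- theta[-seq_len(p)]
    grad <- c(as.vector(Matrix::crossprod(Xs, res)),
              as.vector(Matrix::crossprod(Z, res)) - as.vector(P %*% u))
    W <- mu
    XtW <- Matrix::crossprod(Xs, Matrix::Diagonal(x = W))
    H <- rbind(cbind(XtW %*% Xs, XtW %*% Z),
               cbind(Matrix::t(XtW %*% Z),
                     Matrix::crossprod(Z, Matrix::Diagonal(x = W) %*% Z) + P))
    step <- tryCatch(
      as.vector(Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(H)),
                              grad)),
      error = function(e) as.vector(Matrix::solve(
        H + Matrix::Diagonal(x = 1e-10 * pmax(Matrix::diag(H), 1)), grad)))
    t_step <- 1; improved <- FALSE
    repeat {
      cand_theta <- theta + t_step * step
      cand <- obj(cand_theta)
      if (is.finite(cand$val) && cand$val >= cur$val - 1e-12) {
        improved <- TRUE; break
      }
      t_step <- t_step / 2
      if (t_step < 1e-10) break
    }
    if (!improved) break
    moved <- cand$val - cur$val
    theta <- cand_theta; cur <- cand
    if (moved < tol && sqrt(sum(grad^2)) < 1e-6) break
  }
  mu <- N * exp(cur$eta)
  Hvv <- Matrix::crossprod(Z, Matrix::Diagonal(x = mu) %*% Z) + P
  XtW <- Matrix::crossprod(Xs, Matrix::Diagonal(x = mu))
  H <- rbind(cbind(XtW %*% Xs, XtW %*% Z), cbind(Matrix::t(XtW %*% Z), Hvv))
  list(theta = theta, pois_ll = cur$pll, quad = cur$quad, Hvv = Hvv, H = H)
}

# Internal: covariance <-> unconstrained log-Cholesky parameters.
# d = 1: psi = log sd. d = 2: (log l11, l21, log l22) with Sigma = L L'.
sigma_to_psi <- function(S) {
  L <- t(chol(S))
  if (nrow(S) == 1) return(log(L[1, 1]))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

psi_to_sigma_one <- function(psi, d) {
  if (d == 1) {
    L <- matrix(exp(psi), 1, 1)
  } else {
    L <- matrix(c(exp(psi[1]), psi[2], 0, exp(psi[3])), 2, 2)
  }
  L %*% t(L)
}

psi_to_sigmas <- function(psi, d) {
  k <- d * (d + 1) / 2
  Ss <- psi_to_sigma_one(psi[seq_len(k)], d)
  Sc <- psi_to_sigma_one(psi[k + seq_len(k)], d)
  list(Ss = Ss, Sc = Sc, Qs = safe_inverse(Ss), Qc = safe_inverse(Sc))
}

# Internal: inverse of a small SPD matrix, with a relative ridge when the
# optimiser proposes a nearly singular covariance (correlation -> 1).
safe_inverse <- function(S) {
  tryCatch(chol2inv(chol(S)), error = function(e) {
    chol2inv(chol(S + diag(1e-10 * max(diag(S), 1), nrow(S))))
  })
}

# Internal: which psi positions are log-diagonals (pattern index 1) vs
# free off-diagonals (pattern index 2), per level.
psi_bound_pattern <- function(d) {
  if (d == 1) 1L else c(1L, 2L, 1L)
}
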