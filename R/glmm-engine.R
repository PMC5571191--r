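# Core estimation machinery: random-intercept GLMMs by Laplace approximation.
#
# Inner loop: penalized iteratively reweighted least squares (PIRLS) for the
# joint mode of (beta, u) given the variance parameters.  Outer loop:
# maximization of the Laplace-approximated marginal log-likelihood over the
# log random-effect variances (plus log theta for the negative binomial and
# log residual variance for the Gaussian).  Sparse linear algebra via Matrix.

glmm_families <- c("poisson", "negative_binomial", "binomial", "gaussian")

family_funs <- function(family) {
  switch(family,
    poisson = list(
      link = "log",
      linkfun = function(mu) log(mu),
      linkinv = function(eta) pmin(exp(eta), 1e10),
      mu_eta = function(eta) pmin(exp(eta), 1e10),
      irls = function(y, eta, mu, aux) {
        w <- pmax(mu, 1e-10)
        list(w = w, z = eta + (y - mu) / w)
      },
      loglik = function(y, mu, aux) sum(stats::dpois(y, mu, log = TRUE)),
      simulate = function(mu, aux) stats::rpois(length(mu), mu)
    ),
    negative_binomial = list(
      link = "log",
      linkfun = function(mu) log(mu),
      linkinv = function(eta) pmin(exp(eta), 1e10),
      mu_eta = function(eta) pmin(exp(eta), 1e10),
      irls = function(y, eta, mu, aux) {
        mu <- pmax(mu, 1e-10)
        w <- mu * aux$theta / (aux$theta + mu)
        list(w = pmax(w, 1e-10), z = eta + (y - mu) / mu)
      },
      loglik = function(y, mu, aux) {
        sum(stats::dnbinom(y, size = aux$theta, mu = pmax(mu, 1e-10),
                           log = TRUE))
      },
      simulate = function(mu, aux) {
        stats::rnbinom(length(mu), size = aux$theta, mu = mu)
      }
    ),
    binomial = list(
      link = "logit",
      linkfun = function(mu) stats::qlogis(mu),
      linkinv = function(eta) stats::plogis(eta),
      mu_eta = function(eta) {
        p <- stats::plogis(eta)
        p * (1 - p)
      },
      irls = function(y, eta, mu, aux) {
        w <- pmax(mu * (1 - mu), 1e-10)
        list(w = w, z = eta + (y - mu) / w)
      },
      loglik = function(y, mu, aux) {
        mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
        sum(y * log(mu) + (1 - y) * log(1 - mu))
      },
      simulate = function(mu, aux) stats::rbinom(length(mu), 1L, mu)
    ),
    gaussian = list(
      link = "identity",
      linkfun = function(mu) mu,
      linkinv = function(eta) eta,
      mu_eta = function(eta) rep(1, length(eta)),
      irls = function(y, eta, mu, aux) {
        list(w = rep(1 / aux$sigma2, length(y)), z = y)
      },
      loglik = function(y, mu, aux) {
        sum(stats::dnorm(y, mu, sqrt(aux$sigma2), log = TRUE))
      },
      simulate = function(mu, aux) {
        stats::rnorm(length(mu), mu, sqrt(aux$sigma2))
      }
    ),
    stop("unknown family: ", family)
  )
}

#' Numerical control settings for the GLMM fitter
#'
#' @param maxit_pirls Maximum penalized-IRLS iterations per inner solve.
#' @param tol_pirls Relative tolerance on the penalized deviance.
#' @param rho_bounds Bounds for the log random-effect variances in the
#'   outer optimization; the lower bound acts as the variance-zero
#'   boundary.
#' @param log_theta_bounds Bounds for the log negative-binomial dispersion.
#' @param fix_theta Optional fixed dispersion (skips its estimation).
#' @param fix_variance Optional numeric vector of fixed random-effect
#'   variances, one per grouping factor (0 drops the term).
#' @param outer_hessian Compute the numerical Hessian of the outer
#'   objective at the optimum (needed for dispersion / variance standard
#'   errors and Satterthwaite df; skipped in repeated refits for speed).
#' @param n_boot Default number of parametric-bootstrap replicates.
#' @return List of class `glmm_control`.
#' @export
glmm_control <- function(maxit_pirls = 100L, tol_pirls = 1e-10,
                         rho_bounds = c(-15, 8),
                         log_theta_bounds = c(-4, 12),
                         fix_theta = NULL, fix_variance = NULL,
                         outer_hessian = TRUE, n_boot = 1000L) {
  structure(list(maxit_pirls = maxit_pirls, tol_pirls = tol_pirls,
                 rho_bounds = rho_bounds,
                 log_theta_bounds = log_theta_bounds,
                 fix_theta = fix_theta, fix_variance = fix_variance,
                 outer_hessian = outer_hessian, n_boot = n_boot),
            class = "glmm_control")
}

# Build the sparse random-effects design from a named list of factors.
make_ranef_design <- function(groups, n) {
  if (!length(groups)) {
    return(list(Z = NULL, q = integer(0), levels = list()))
  }
  blocks <- lapply(groups, function(f) {
    f <- factor(f)
    Matrix::sparseMatrix(i = seq_len(n), j = as.integer(f),
                         x = 1, dims = c(n, nlevels(f)))
  })
  Z <- do.call(cbind, blocks)
  list(Z = Z, q = vapply(groups, function(f) nlevels(factor(f)), 1L),
       levels = lapply(groups, function(f) levels(factor(f))))
}

# Penalized IRLS for the joint (beta, u) mode at fixed variance parameters.
# A is cbind(X, Z), dense for small systems, sparse otherwise; prec is the
# per-column prior precision of u.  Returns the final penalized
# information matrix M = A'WA + diag(0, prec), reused for the Laplace
# log-determinant and the coefficient covariance.
pirls_fit <- function(y, X, A, prec, fam, aux, start, control) {
  n <- nrow(X); p <- ncol(X); q <- length(prec)
  dense <- is.matrix(A)
  coefs <- start
  penvec <- c(rep(0, p), prec)
  eta <- as.numeric(A %*% coefs)
  mu <- fam$linkinv(eta)
  obj <- function(cf, mu) {
    -fam$loglik(y, mu, aux) + 0.5 * sum(prec * cf[p + seq_len(q)]^2)
  }
  make_M <- function(w) {
    if (dense) {
      M <- crossprod(A, A * w)
      diag(M) <- diag(M) + penvec
      M
    } else {
      Matrix::forceSymmetric(
        Matrix::crossprod(A, Matrix::Diagonal(x = w) %*% A) +
          Matrix::Diagonal(x = penvec))
    }
  }
  f_old <- obj(coefs, mu)
  conv <- FALSE
  M <- NULL
  for (it in seq_len(control$maxit_pirls)) {
    iw <- fam$irls(y, eta, mu, aux)
    M <- make_M(iw$w)
    rhs <- if (dense) as.numeric(crossprod(A, iw$w * iw$z)) else
      as.numeric(Matrix::crossprod(A, iw$w * iw$z))
    new <- tryCatch(
      if (dense) solve(M, rhs) else as.numeric(Matrix::solve(M, rhs)),
      error = function(e) NULL)
    if (is.null(new) || any(!is.finite(new))) break
    step <- 1
    repeat {
      cand <- coefs + step * (new - coefs)
      eta_c <- as.numeric(A %*% cand)
      mu_c <- fam$linkinv(eta_c)
      f_new <- obj(cand, mu_c)
      if (is.finite(f_new) && f_new <= f_old + 1e-8) break
      step <- step / 2
      if (step < 1e-6) break
    }
    coefs <- cand; eta <- eta_c; mu <- mu_c
    if (abs(f_old - f_new) < control$tol_pirls * (abs(f_old) + 1)) {
      conv <- TRUE
      f_old <- f_new
      break
    }
    f_old <- f_new
  }
  iw <- fam$irls(y, eta, mu, aux)
  M <- make_M(iw$w)
  list(coefs = coefs, eta = eta, mu = mu, w = iw$w, M = M, dense = dense,
       penalized_obj = f_old, converged = conv)
}

# Laplace marginal log-likelihood at the joint mode.  The u-block of the
# penalized information M is exactly Z'WZ + D.
laplace_loglik <- function(fit, y, prec, var_vec, q_sizes, fam, aux, p) {
  ll <- fam$loglik(y, fit$mu, aux)
  q <- length(prec)
  if (q == 0L) return(ll)
  u <- fit$coefs[p + seq_len(q)]
  uidx <- p + seq_len(q)
  ld <- if (fit$dense) {
    as.numeric(determinant(fit$M[uidx, uidx, drop = FALSE],
                           logarithm = TRUE)$modulus)
  } else {
    as.numeric(Matrix::determinant(fit$M[uidx, uidx, drop = FALSE],
                                   logarithm = TRUE)$modulus)
  }
  ll - 0.5 * sum(prec * u^2) - 0.5 * sum(q_sizes * log(var_vec)) - 0.5 * ld
}

#' Low-level Laplace GLMM fitter
#'
#' Fits a random-intercept generalized linear mixed model by maximizing the
#' Laplace-approximated marginal likelihood.  Most users should call
#' [fit_glmm()] with a [model_spec()]; this function works directly on a
#' response vector, a dense fixed-effects design and a list of grouping
#' factors, and is the engine behind every model in the package.
#'
#' @param y Response vector (counts, 0/1, or real for `gaussian`).
#' @param X Dense fixed-effects design matrix (including intercept).
#' @param groups Named list of grouping factors (0, 1 or 2 elements), each
#'   of length `length(y)`; each contributes an independent batch of
#'   Gaussian random intercepts.
#' @param family One of `"poisson"`, `"negative_binomial"`, `"binomial"`,
#'   `"gaussian"`.
#' @param control A [glmm_control()].
#' @param start Optional list with elements `beta`, `u`, `par` (outer
#'   parameters) used to warm-start repeated fits.
#' @return List with elements `beta`, `se`, `vcov` (fixed effects),
#'   `u` (conditional modes), `variance_components`, `theta`, `sigma2`,
#'   `loglik`, `converged`, `outer_par`, `outer_vcov`, `n`, `fitted`, plus
#'   bookkeeping used by the higher-level wrappers.
#' @export
laplace_glmm <- function(y, X, groups = list(), family = "poisson",
                         control = glmm_control(), start = NULL) {
  family <- match.arg(family, glmm_families)
  fam <- family_funs(family)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n)
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial family requires a 0/1 response")
  }
  if (family %in% c("poisson", "negative_binomial") &&
      any(y < 0 | y != round(y))) {
    stop("count families require non-negative integer responses")
  }
  if (family != "gaussian" && stats::var(y) == 0) {
    stop("degenerate response: no variation")
  }
  groups <- lapply(groups, factor)
  if (any(vapply(groups, nlevels, 1L) < 2L)) {
    stop("grouping factors must have at least 2 levels")
  }

  # fixed variances, if any: zero-variance batches are dropped outright
  fixv <- control$fix_variance
  est_batch <- rep(TRUE, length(groups))
  fixed_var <- rep(NA_real_, length(groups))
  if (!is.null(fixv)) {
    stopifnot(length(fixv) == length(groups), all(fixv >= 0))
    est_batch <- rep(FALSE, length(groups))
    fixed_var <- fixv
  }
  active <- which(est_batch | fixed_var > 1e-10)
  g_act <- groups[active]
  rd <- make_ranef_design(g_act, n)
  Z <- rd$Z; q_sizes <- rd$q; q <- sum(q_sizes)
  # dense algebra for small systems (much faster for the repeated refits
  # of the bootstrap and null test), sparse Matrix otherwise
  dense <- (p + q) <= 64L
  A <- if (dense) {
    if (q > 0L) cbind(X, as.matrix(Z)) else X
  } else {
    Xs <- Matrix::Matrix(X, sparse = TRUE)
    if (q > 0L) cbind(Xs, Z) else Xs
  }

  est_theta <- family == "negative_binomial" && is.null(control$fix_theta)
  est_sigma <- family == "gaussian"
  n_rho <- sum(est_batch[active])

  # starting values
  beta0 <- numeric(p)
  mu_y <- mean(y)
  beta0[1] <- switch(family,
    poisson = log(max(mu_y, 0.05)),
    negative_binomial = log(max(mu_y, 0.05)),
    binomial = stats::qlogis(min(max(mu_y, 0.02), 0.98)),
    gaussian = mu_y)
  theta0 <- if (family == "negative_binomial") {
    if (!is.null(control$fix_theta)) control$fix_theta else {
      v <- stats::var(y)
      t0 <- if (v > mu_y) mu_y^2 / (v - mu_y) else 20
      min(max(t0, 0.2), 100)
    }
  } else NULL
  sigma20 <- if (est_sigma) max(stats::var(y) / 2, 1e-6) else NULL

  par0 <- c(rep(log(0.1), n_rho),
            if (est_theta) log(theta0),
            if (est_sigma) log(sigma20))
  lower <- c(rep(control$rho_bounds[1], n_rho),
             if (est_theta) control$log_theta_bounds[1],
             if (est_sigma) -15)
  upper <- c(rep(control$rho_bounds[2], n_rho),
             if (est_theta) control$log_theta_bounds[2],
             if (est_sigma) 15)
  if (!is.null(start$par) && length(start$par) == length(par0)) {
    par0 <- pmin(pmax(start$par, lower), upper)
  }

  cache <- new.env(parent = emptyenv())
  cache$coefs <- c(beta0, rep(0, q))
  if (!is.null(start$beta) && length(start$beta) == p) {
    cache$coefs[seq_len(p)] <- start$beta
  }

  unpack <- function(par) {
    idx <- 0L
    vv <- numeric(length(active))
    for (k in seq_along(active)) {
      if (est_batch[active[k]]) {
        idx <- idx + 1L
        vv[k] <- exp(par[idx])
      } else {
        vv[k] <- fixed_var[active[k]]
      }
    }
    theta <- if (family == "negative_binomial") {
      if (est_theta) { idx <- idx + 1L; exp(par[idx]) } else control$fix_theta
    } else NULL
    sigma2 <- if (est_sigma) { idx <- idx + 1L; exp(par[idx]) } else NULL
    list(var = vv, theta = theta, sigma2 = sigma2)
  }

  inner <- function(par) {
    pp <- unpack(par)
    prec <- if (q > 0L) rep(1 / pp$var, q_sizes) else numeric(0)
    aux <- list(theta = pp$theta, sigma2 = pp$sigma2)
    fit <- pirls_fit(y, X, A, prec, fam, aux, cache$coefs, control)
    cache$coefs <- fit$coefs
    list(fit = fit, prec = prec, aux = aux, pp = pp)
  }
  objective <- function(par) {
    res <- tryCatch(inner(par), error = function(e) NULL)
    if (is.null(res)) return(1e10)
    ll <- laplace_loglik(res$fit, y, res$prec, res$pp$var, q_sizes,
                         fam, res$aux, p)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  opt_conv <- TRUE
  if (length(par0) == 1L) {
    # one-dimensional outer problem: golden-section/Brent search
    opt <- stats::optimize(objective, lower = lower, upper = upper,
                           tol = 1e-6)
    par_hat <- opt$minimum
    # the boundary (variance -> 0) can beat the interior bracket
    f_lo <- objective(lower)
    if (f_lo < opt$objective) par_hat <- lower
  } else if (length(par0)) {
    # nlminb return codes are unreliable near variance boundaries and on
    # flat dispersion ridges; restart until either the code is clean or a
    # restart no longer improves the objective meaningfully
    par_hat <- par0
    f_prev <- Inf
    opt_conv <- FALSE
    for (round in 1:4) {
      opt <- stats::nlminb(par_hat, objective, lower = lower,
                           upper = upper,
                           control = list(rel.tol = 1e-9, iter.max = 300))
      par_hat <- opt$par
      if (opt$convergence == 0 || opt$objective > f_prev - 1e-3) {
        opt_conv <- TRUE
        break
      }
      f_prev <- opt$objective
    }
  } else {
    par_hat <- numeric(0)
  }
  res <- inner(par_hat)
  loglik <- laplace_loglik(res$fit, y, res$prec, res$pp$var, q_sizes,
                           fam, res$aux, p)

  # fixed-effects covariance: beta block of the inverse penalized
  # information (X'WX - X'WZ H^-1 Z'WX)^-1, from the final PIRLS M
  M <- res$fit$M
  vcov_beta <- if (res$fit$dense) {
    solve(M)[seq_len(p), seq_len(p), drop = FALSE]
  } else {
    Ep <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                               dims = c(p + q, p))
    as.matrix(Matrix::solve(M, Ep))[seq_len(p), , drop = FALSE]
  }
  vcov_beta <- (vcov_beta + t(vcov_beta)) / 2
  se <- sqrt(pmax(diag(vcov_beta), 0))

  outer_vcov <- NULL
  if (length(par_hat) && isTRUE(control$outer_hessian)) {
    Hout <- tryCatch(stats::optimHess(par_hat, objective),
                     error = function(e) NULL)
    if (!is.null(Hout)) {
      outer_vcov <- tryCatch(solve(Hout), error = function(e) NULL)
    }
  }

  vc <- res$pp$var
  names(vc) <- names(g_act)
  beta <- res$fit$coefs[seq_len(p)]
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  u <- if (q > 0L) res$fit$coefs[p + seq_len(q)] else numeric(0)

  structure(list(
    beta = beta, se = se, vcov = vcov_beta, u = u,
    variance_components = vc, theta = res$pp$theta, sigma2 = res$pp$sigma2,
    loglik = loglik, converged = opt_conv && res$fit$converged,
    outer_par = par_hat, outer_vcov = outer_vcov,
    outer_names = c(if (n_rho) paste0("log_var_", names(g_act)[
      est_batch[active]]),
      if (est_theta) "log_theta", if (est_sigma) "log_sigma2"),
    family = family, n = n, p = p, q_sizes = q_sizes,
    groups = g_act, levels = rd$levels,
    fitted = res$fit$mu, linear_predictor = res$fit$eta,
    X = X, y = y, Z = Z, control = control
  ), class = "laplace_glmm")
}

# Refit helper used by the bootstrap and the null test: same design, new y.
refit_response <- function(engine, y_new, start_from_fit = TRUE) {
  start <- if (start_from_fit) {
    list(beta = engine$beta, par = engine$outer_par)
  } else NULL
  ctl <- engine$control
  ctl$outer_hessian <- FALSE  # refits only need coefficients
  laplace_glmm(y_new, engine$X, engine$groups, engine$family,
               ctl, start = start)
}

# Simulate a response vector from a fitted engine (parametric: new random
# intercepts drawn from the fitted variances).
simulate_response <- function(engine) {
  fam <- family_funs(engine$family)
  eta <- as.numeric(engine$X %*% engine$beta)
  if (length(engine$q_sizes)) {
    u_new <- stats::rnorm(sum(engine$q_sizes), 0,
                          rep(sqrt(engine$variance_components),
                              engine$q_sizes))
    eta <- eta + as.numeric(engine$Z %*% u_new)
  }
  mu <- fam$linkinv(eta)
  fam$simulate(mu, list(theta = engine$theta, sigma2 = engine$sigma2))
}
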