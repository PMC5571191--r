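#' Per-term Wald tests
#'
#' For the Poisson, negative-binomial and binomial GLMMs the statistic is
#' the Wald z = estimate / se against the standard normal.  For the
#' Gaussian LMM the statistic is t with Satterthwaite-approximated degrees
#' of freedom, computed from numerical gradients of each coefficient's
#' variance with respect to the variance parameters and the outer-Hessian
#' covariance of those parameters; when that computation is unavailable
#' the residual degrees of freedom `n - p` are used and recorded in the
#' `df_method` column.
#'
#' @param fit A `glmm_fit`.
#' @return Data frame with columns `term`, `estimate`, `se`, `statistic`,
#'   `p_value` (and `df`, `df_method` for Gaussian fits).
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  eng <- fit$engine
  est <- eng$beta
  se <- eng$se
  if (any(se == 0)) {
    warning("zero standard error for terms: ",
            paste(names(se)[se == 0], collapse = ", "))
  }
  stat <- ifelse(se > 0, est / se, NA_real_)
  if (eng$family == "gaussian") {
    df <- satterthwaite_df(eng)
    p <- 2 * stats::pt(-abs(stat), df$df)
    out <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), statistic = unname(stat),
                      df = df$df, p_value = unname(p),
                      df_method = df$method, stringsAsFactors = FALSE)
  } else {
    p <- 2 * stats::pnorm(-abs(stat))
    out <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), statistic = unname(stat),
                      p_value = unname(p), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Exact fixed-effect covariance of a Gaussian LMM at given variance
# parameters (per-batch variances and residual variance): beta block of
# the inverse of [X Z]'W[X Z] + diag(0, prec), W = I/sigma2.
gaussian_beta_cov <- function(eng, var_vec, sigma2) {
  p <- eng$p
  q <- sum(eng$q_sizes)
  w <- rep(1 / sigma2, eng$n)
  Xs <- Matrix::Matrix(eng$X, sparse = TRUE)
  A <- if (q > 0L) cbind(Xs, eng$Z) else Xs
  prec <- if (q > 0L) rep(1 / var_vec, eng$q_sizes) else numeric(0)
  W <- Matrix::Diagonal(x = w)
  M <- Matrix::forceSymmetric(Matrix::crossprod(A, W %*% A) +
                                Matrix::Diagonal(x = c(rep(0, p), prec)))
  Ep <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                             dims = c(p + q, p))
  V <- as.matrix(Matrix::solve(M, Ep))[seq_len(p), , drop = FALSE]
  (V + t(V)) / 2
}

# Satterthwaite df per fixed effect of a Gaussian LMM fitted by ML:
# df_j = 2 v_j^2 / (g_j' Vpar g_j), with v_j = Var(beta_j) as a function
# of the outer parameters, g_j its numerical gradient and Vpar the
# inverse outer Hessian.
satterthwaite_df <- function(eng) {
  p <- eng$p
  fallback <- list(df = rep(eng$n - p, p), method = "residual")
  if (eng$family != "gaussian") return(fallback)
  par <- eng$outer_par
  nv <- length(eng$variance_components)
  if (is.null(eng$outer_vcov) || length(par) != nv + 1L) return(fallback)
  vj_at <- function(pp) {
    diag(gaussian_beta_cov(eng, exp(pp[seq_len(nv)]), exp(pp[nv + 1L])))
  }
  h <- 1e-4
  G <- tryCatch({
    g <- matrix(0, length(par), p)
    for (k in seq_along(par)) {
      up <- par; up[k] <- up[k] + h
      dn <- par; dn[k] <- dn[k] - h
      g[k, ] <- (vj_at(up) - vj_at(dn)) / (2 * h)
    }
    g
  }, error = function(e) NULL)
  if (is.null(G)) return(fallback)
  v <- diag(eng$vcov)
  denom <- vapply(seq_len(p), function(j) {
    as.numeric(t(G[, j]) %*% eng$outer_vcov %*% G[, j])
  }, 1)
  df <- ifelse(denom > 0, 2 * v^2 / denom, eng$n - p)
  df <- pmin(pmax(df, 1), eng$n - p)
  list(df = df, method = "satterthwaite")
}

#' Backward selection of non-significant terms
#'
#' Iteratively refits the model, removing at each step the least
#' significant removable term with p >= `alpha`.  Marginality is
#' respected: a quadratic or interaction term must leave the model before
#' the main effects it contains become removable, so selection starts with
#' polynomial and interaction terms.  The intercept is never removed.
#'
#' @param spec Initial [model_spec()].
#' @param data Analysis data.
#' @param alpha Significance threshold for retention (default 0.05).
#' @param control A [glmm_control()].
#' @return List with `spec` (final), `fit` (final `glmm_fit`) and `trace`,
#'   a data frame recording every removal step.
#' @export
backward_select <- function(spec, data, alpha = 0.05,
                            control = glmm_control()) {
  stopifnot(inherits(spec, "model_spec"))
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- fit_glmm(spec, data, control)
    tab <- fit$coefficients
    tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
    protected <- unlist(lapply(spec$fixed, function(tm) {
      pt <- parse_term(tm)
      if (pt$type %in% c("quadratic", "interaction")) pt$vars else NULL
    }))
    removable <- tab[!(tab$term %in% protected), , drop = FALSE]
    cand <- removable[!is.na(removable$p_value) &
                        removable$p_value >= alpha, , drop = FALSE]
    if (!nrow(cand)) break
    drop_term <- cand$term[which.max(cand$p_value)]
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, dropped = drop_term,
      p_value = cand$p_value[which.max(cand$p_value)],
      stringsAsFactors = FALSE))
    spec$fixed <- setdiff(spec$fixed, drop_term)
    if (!length(spec$fixed)) {
      fit <- fit_glmm(spec, data, control)
      break
    }
  }
  list(spec = spec, fit = fit, trace = trace)
}

#' Parametric-bootstrap confidence intervals
#'
#' Simulates responses from the fitted model -- new random intercepts from
#' the estimated variances, then observations from the error family --
#' refits the full model on each replicate, and returns percentile 2.5 /
#' 97.5 intervals per fixed-effect term (and for the negative-binomial
#' dispersion).  Replicates whose refit does not converge are dropped and
#' counted; more than 10% failures triggers a warning recorded in the
#' result.
#'
#' @param fit A converged `glmm_fit`.
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return Object of class `glmm_boot`: list with `ci` (term, lower,
#'   upper), `draws` (replicate x term matrix), `theta_draws`, `n_fail`,
#'   `warning`.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000L, seed) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (missing(seed)) stop("a seed is required for bootstrap_ci")
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) stop("n_boot must be at least 1")
  if (!fit$converged) stop("bootstrap requires a converged fit")
  eng <- fit$engine
  set.seed(seed)
  p <- eng$p
  draws <- matrix(NA_real_, n_boot, p,
                  dimnames = list(NULL, names(eng$beta)))
  theta_draws <- if (!is.null(eng$theta)) rep(NA_real_, n_boot) else NULL
  n_fail <- 0L
  for (b in seq_len(n_boot)) {
    y_star <- simulate_response(eng)
    ref <- tryCatch(refit_response(eng, y_star), error = function(e) NULL)
    if (is.null(ref) || !ref$converged) {
      n_fail <- n_fail + 1L
      next
    }
    draws[b, ] <- ref$beta
    if (!is.null(theta_draws)) theta_draws[b] <- ref$theta
  }
  ok <- stats::complete.cases(draws)
  if (!any(ok)) stop("all bootstrap replicates failed")
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), names = FALSE)
  ci <- data.frame(term = colnames(draws), lower = qs[1, ],
                   upper = qs[2, ], stringsAsFactors = FALSE)
  rownames(ci) <- NULL
  warn <- n_fail > 0.1 * n_boot
  if (warn) {
    warning(sprintf("%d of %d bootstrap refits failed to converge",
                    n_fail, n_boot))
  }
  structure(list(ci = ci, draws = draws[ok, , drop = FALSE],
                 theta_draws = theta_draws, n_boot = n_boot,
                 n_fail = n_fail, warning = warn, seed = seed),
            class = "glmm_boot")
}

#' @export
print.glmm_boot <- function(x, ...) {
  cat(sprintf("Parametric bootstrap, %d replicates (%d failed)\n",
              x$n_boot, x$n_fail))
  print(x$ci, row.names = FALSE)
  invisible(x)
}

#' Predicted response curve over one predictor
#'
#' Evaluates the fitted model over a grid of natural-unit values of one
#' scaled predictor, holding the other covariates at specified values
#' (scaled covariates default to their observed mean, i.e. scaled zero;
#' unscaled 0/1 indicators default to the reference level 0).  Standard
#' errors come from the delta method on the linear predictor.
#'
#' @param fit A `glmm_fit`.
#' @param term Name of the (linear) predictor to vary.
#' @param grid Natural-unit grid; defaults to 100 points over the observed
#'   range.
#' @param at Named list of natural-unit values for the remaining
#'   covariates.
#' @return Data frame with the grid, linear predictor and its se, and the
#'   response-scale prediction `fit` with `se_fit`.
#' @export
predict_curve <- function(fit, term, grid = NULL, at = list()) {
  stopifnot(inherits(fit, "glmm_fit"))
  spec <- fit$spec
  vars <- spec_base_vars(spec)
  if (!term %in% vars) stop("term '", term, "' is not in the model")
  bad <- setdiff(names(at), vars)
  if (length(bad)) stop("unknown covariates in 'at': ",
                        paste(bad, collapse = ", "))
  if (is.null(grid)) {
    x <- fit$data[[term]]
    grid <- seq(min(x), max(x), length.out = 100)
  }
  ng <- length(grid)
  natural <- list()
  for (v in vars) {
    natural[[v]] <- if (v == term) grid
    else if (!is.null(at[[v]])) rep(at[[v]], ng)
    else if (!is.null(fit$scaling[[v]])) rep(fit$scaling[[v]]$center, ng)
    else rep(0, ng)
  }
  cols <- lapply(vars, function(v) {
    s <- fit$scaling[[v]]
    if (is.null(s)) natural[[v]] else (natural[[v]] - s$center) / s$scale
  })
  names(cols) <- vars
  terms <- spec$fixed
  Xg <- matrix(1, ng, 1L + length(terms),
               dimnames = list(NULL, c("(Intercept)", terms)))
  for (tm in terms) {
    pt <- parse_term(tm)
    Xg[, tm] <- switch(pt$type,
      linear = cols[[pt$vars]],
      quadratic = cols[[pt$vars]]^2,
      interaction = cols[[pt$vars[1]]] * cols[[pt$vars[2]]])
  }
  beta <- fit$engine$beta
  eta <- as.numeric(Xg %*% beta)
  se_eta <- sqrt(pmax(rowSums((Xg %*% fit$engine$vcov) * Xg), 0))
  fam <- family_funs(fit$spec$family)
  mu <- fam$linkinv(eta)
  out <- data.frame(grid, eta = eta, se_eta = se_eta, fit = mu,
                    se_fit = se_eta * abs(fam$mu_eta(eta)))
  names(out)[1] <- term
  out
}

#' Optimum (vertex) of a quadratic effect in natural units
#'
#' For a model containing `term` and `term^2` with a negative quadratic
#' coefficient, the linear predictor is maximized at the scaled value
#' `-b1 / (2 * b2)`; the value is mapped back to natural units through the
#' stored scaling constants.  This reproduces quantities such as "the peak
#' effort with the largest effect on lifetime pup production".
#'
#' @param fit A `glmm_fit`.
#' @param term Base name of the predictor (its `^2` term must be in the
#'   model).
#' @return List with `ok`; when `ok` is `TRUE` also `scaled` and
#'   `natural`, otherwise `reason`.
#' @export
vertex_in_natural_units <- function(fit, term) {
  stopifnot(inherits(fit, "glmm_fit"))
  beta <- fit$engine$beta
  qname <- paste0(term, "^2")
  if (!all(c(term, qname) %in% names(beta))) {
    stop("model must contain both '", term, "' and '", qname, "'")
  }
  b1 <- unname(beta[term])
  b2 <- unname(beta[qname])
  if (b2 >= 0) {
    return(list(ok = FALSE,
                reason = "non-negative quadratic coefficient: no interior maximum"))
  }
  v <- -b1 / (2 * b2)
  s <- fit$scaling[[term]]
  nat <- if (is.null(s)) v else s$center + s$scale * v
  list(ok = TRUE, scaled = v, natural = nat, term = term)
}
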