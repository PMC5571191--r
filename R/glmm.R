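#' Declarative mixed-model specification
#'
#' Describes one of the analysis models: response, error family,
#' fixed-effect terms and random-intercept structure.  Terms are given as
#' strings: a plain variable name (`"max_pups"`), a quadratic term
#' (`"max_pups^2"`), or a two-way interaction (`"mast_peak:max_pups"`).
#' Quadratic and interaction columns are built from the *scaled* linear
#' variables (scale-then-square), the usual convention for polynomial
#' terms in mixed models, and a quadratic term requires its linear term to
#' be present.
#'
#' Continuous predictors listed in `scale_vars` are standardized to mean
#' zero / unit sample sd within the analysis data before fitting; with the
#' default `NULL`, every numeric base variable with more than two distinct
#' values is scaled (binary indicators such as primiparity or mast flags
#' are left on their 0/1 coding, reference level 0).
#'
#' @param response Response variable name.
#' @param fixed Character vector of fixed-effect terms (intercept is
#'   implicit).
#' @param family `"poisson"`, `"negative_binomial"`, `"binomial"` or
#'   `"gaussian"`; links are log, log, logit and identity respectively.
#' @param random `"none"`, `"cohort"` (cohort random intercept) or
#'   `"female_in_cohort"` (independent female and cohort intercept
#'   batches, i.e. squirrel identity nested within cohort).
#' @param scale_vars Variables to scale, or `NULL` for the automatic rule.
#' @return List of class `model_spec`.
#' @examples
#' model_spec("lifetime_pups",
#'            c("peak_effort", "peak_effort^2", "lifespan", "primiparity"),
#'            family = "poisson", random = "cohort")
#' @export
model_spec <- function(response, fixed,
                       family = c("poisson", "negative_binomial",
                                  "binomial", "gaussian"),
                       random = c("none", "cohort", "female_in_cohort"),
                       scale_vars = NULL) {
  family <- match.arg(family)
  random <- match.arg(random)
  stopifnot(is.character(response), length(response) == 1L,
            is.character(fixed))
  parsed <- lapply(fixed, parse_term)
  quad <- vapply(parsed, function(t) t$type == "quadratic", TRUE)
  for (t in parsed[quad]) {
    if (!t$vars %in% fixed) {
      stop("quadratic term for '", t$vars,
           "' requires its linear term in the model")
    }
  }
  structure(list(response = response, fixed = fixed, family = family,
                 link = switch(family, poisson = "log",
                               negative_binomial = "log",
                               binomial = "logit", gaussian = "identity"),
                 random = random, scale_vars = scale_vars),
            class = "model_spec")
}

parse_term <- function(term) {
  if (grepl("\\^2$", term)) {
    list(term = term, type = "quadratic", vars = sub("\\^2$", "", term))
  } else if (grepl(":", term, fixed = TRUE)) {
    vars <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(vars) != 2L) stop("only two-way interactions supported: ",
                                 term)
    list(term = term, type = "interaction", vars = vars)
  } else {
    list(term = term, type = "linear", vars = term)
  }
}

spec_base_vars <- function(spec) {
  unique(unlist(lapply(spec$fixed, function(t) parse_term(t)$vars)))
}

# Build y, X, grouping factors and scaling info for a spec on a data set.
build_design <- function(spec, data) {
  vars <- spec_base_vars(spec)
  need <- c(spec$response, vars,
            switch(spec$random, none = NULL, cohort = "cohort",
                   female_in_cohort = c("cohort", "female_id")))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing variables: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(data[need])
  data <- data[keep, , drop = FALSE]
  if (!nrow(data)) stop("no complete cases for model ", spec$response)

  scale_vars <- spec$scale_vars
  if (is.null(scale_vars)) {
    scale_vars <- vars[vapply(vars, function(v) {
      x <- data[[v]]
      is.numeric(x) && length(unique(x)) > 2L
    }, TRUE)]
  }
  scaling <- list()
  cols <- list()
  for (v in vars) {
    x <- as.numeric(data[[v]])
    if (v %in% scale_vars) {
      s <- scale_predictors(x)
      scaling[[v]] <- list(center = s$center, scale = s$scale)
      cols[[v]] <- s$scaled
    } else {
      cols[[v]] <- x
    }
  }
  X <- matrix(1, nrow(data), 1L + length(spec$fixed),
              dimnames = list(NULL, c("(Intercept)", spec$fixed)))
  for (tm in spec$fixed) {
    pt <- parse_term(tm)
    X[, tm] <- switch(pt$type,
      linear = cols[[pt$vars]],
      quadratic = cols[[pt$vars]]^2,
      interaction = cols[[pt$vars[1]]] * cols[[pt$vars[2]]])
  }
  groups <- switch(spec$random,
    none = list(),
    cohort = list(cohort = factor(data$cohort)),
    female_in_cohort = list(cohort = factor(data$cohort),
                            female = factor(data$female_id)))
  y <- data[[spec$response]]
  if (spec$family == "binomial") y <- as.numeric(y)
  list(y = y, X = X, groups = groups, scaling = scaling, data = data)
}

#' Fit a random-intercept GLMM from a model specification
#'
#' Estimation is by Laplace approximation of the marginal likelihood with
#' a penalized-IRLS inner loop (see [laplace_glmm()]).  With the
#' random-effect variance at the boundary (zero) the fit coincides with
#' the corresponding fixed-effects GLM.  Wald tests are attached per term
#' (z against the standard normal for the GLMM families; t with
#' Satterthwaite degrees of freedom for the Gaussian LMM).
#'
#' @param spec A [model_spec()].
#' @param data Data frame holding the response, predictors and grouping
#'   variables (`cohort`, `female_id` as required).
#' @param control A [glmm_control()].
#' @return Object of class `glmm_fit`: list with `coefficients` (per-term
#'   table of estimate, se, statistic, p), `engine` (the full
#'   [laplace_glmm()] result), `variance_components`, `theta`, `sigma2`,
#'   `loglik`, `converged`, `scaling`, `spec`, `n`.
#' @seealso [backward_select()], [bootstrap_ci()], [predict_curve()],
#'   [vertex_in_natural_units()]
#' @export
fit_glmm <- function(spec, data, control = glmm_control()) {
  stopifnot(inherits(spec, "model_spec"))
  des <- build_design(spec, data)
  eng <- laplace_glmm(des$y, des$X, des$groups, spec$family, control)
  out <- structure(list(
    coefficients = NULL,
    engine = eng,
    variance_components = eng$variance_components,
    theta = eng$theta, sigma2 = eng$sigma2,
    loglik = eng$loglik, converged = eng$converged,
    scaling = des$scaling, spec = spec, n = eng$n,
    data = des$data
  ), class = "glmm_fit")
  out$coefficients <- wald_tests(out)
  out
}

#' Fit a negative-binomial GLMM
#'
#' Convenience wrapper around [fit_glmm()] that forces the
#' negative-binomial family (variance `mu + mu^2 / theta`); the dispersion
#' `theta` is estimated jointly with the variance parameters in the outer
#' optimization.
#'
#' @inheritParams fit_glmm
#' @return A `glmm_fit` with the estimated `theta`.
#' @export
fit_negative_binomial <- function(spec, data, control = glmm_control()) {
  spec$family <- "negative_binomial"
  spec$link <- "log"
  fit_glmm(spec, data, control)
}

#' @export
coef.glmm_fit <- function(object, ...) object$engine$beta

#' @export
vcov.glmm_fit <- function(object, ...) object$engine$vcov

#' @export
logLik.glmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$engine$p +
              length(object$variance_components) +
              !is.null(object$theta) + !is.null(object$sigma2),
            class = "logLik")
}

#' @export
print.glmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s GLMM (%s link), N = %d%s\n",
              gsub("_", " ", x$spec$family), x$spec$link, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("Response:", x$spec$response, "\n")
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$statistic <- round(tab$statistic, 2)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  if (length(x$variance_components)) {
    cat("Random-effect variances:",
        paste(sprintf("%s = %.4g", names(x$variance_components),
                      x$variance_components), collapse = ", "), "\n")
  }
  if (!is.null(x$theta)) {
    cat(sprintf("Negative binomial dispersion: %.3g\n", x$theta))
  }
  if (!is.null(x$sigma2)) {
    cat(sprintf("Residual variance: %.4g\n", x$sigma2))
  }
  cat(sprintf("Log-likelihood (Laplace): %.3f\n", x$loglik))
  invisible(x)
}
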