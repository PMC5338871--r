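# Core model: logit-linked binomial mixed model with a single year random
# intercept, fit by adaptive Gauss-Hermite quadrature through lme4::glmer,
# falling back to the Laplace approximation for many year levels and to a
# plain logistic fit when the design has a single year or the random effect
# is switched off.

#' Fit the spawning-condition mixed logistic model
#'
#' Maximizes the marginal likelihood of `spawning ~ fixed terms + (1 | year)`
#' by adaptive Gauss-Hermite quadrature (default 21 nodes; the Laplace
#' approximation is used when there are more than 40 year levels, or set
#' `nAGQ = 1`; `nAGQ = 0` profiles the fixed effects out by penalized IRLS,
#' the fastest mode, appropriate for large AIC screening loops). With a
#' single year level, or `random = FALSE`, an ordinary
#' logistic regression is fit and the random-intercept SD is fixed at 0.
#' When the random-intercept SD estimate hits the 0 boundary the fit
#' coincides with the plain logistic fit.
#'
#' Complete separation is flagged; with `penalize = TRUE` (fixed-effects
#' path only) the coefficients are re-estimated at the Jeffreys-prior
#' (Firth) penalized solution and the fit records that provenance.
#'
#' @param design a `spawn_design` from [build_design()], or any list with a
#'   `data` data.frame (containing the response and `year`), `terms`, and
#'   `response` element.
#' @param terms fixed-effect term names (default: the design's terms).
#' @param random include the year random intercept (default `TRUE`).
#' @param nAGQ quadrature nodes (default 21).
#' @param penalize use a Firth-penalized fit if separation is detected.
#' @param hierarchy_override allow interactions without their margins.
#' @return an object of class `spawn_fit` with components `coefficients`,
#'   `vcov`, `ranef_sd`, `ranef_sd_se`, `ranef_sd_ci` (95% Wald interval on
#'   the log scale), `ranef` (per-year predicted intercepts), `logLik`,
#'   `df`, `aic`, `deviance` (-2 marginal logLik), `null_deviance`, `n`,
#'   `engine`, `converged`, `separation`, `terms`, `meta`.
#' @export
spawn_glmm <- function(design, terms = NULL, random = TRUE, nAGQ = 21,
                       penalize = FALSE, hierarchy_override = FALSE,
                       compute_sd_se = TRUE) {
  terms <- terms %||% design$terms
  data <- design$data
  response <- design$response %||% "spawning"
  y <- data[[response]]
  if (length(unique(y)) < 2) stopf("response has a single class; cannot fit")
  for (t in intersect(terms, names(INTERACTION_MARGINS))) {
    mm <- INTERACTION_MARGINS[[t]]
    mm <- setdiff(mm, "temperature")  # continuous margin not required as factor
    if (!hierarchy_override && !all(mm %in% terms)) {
      stopf("interaction '%s' requires margin(s) %s (or hierarchy_override = TRUE)",
            t, paste(setdiff(mm, terms), collapse = ", "))
    }
  }
  df <- data[, unique(c(response, "year", terms)), drop = FALSE]
  for (nm in names(df)) if (is.factor(df[[nm]])) df[[nm]] <- droplevels(df[[nm]])
  n_year <- if ("year" %in% names(df)) nlevels(factor(df$year)) else 1L
  use_re <- random && n_year >= 2
  rhs <- if (length(terms)) paste(sprintf("`%s`", terms), collapse = " + ") else "1"
  n <- nrow(df)
  n_fixed_min <- length(terms) + 1
  if (n < n_fixed_min + 5) stopf("too few rows (%d) for %d parameters", n, n_fixed_min)

  separation <- FALSE
  if (use_re) {
    if (n_year > 40) nAGQ <- 1
    form <- stats::as.formula(paste(response, "~", rhs, "+ (1 | year)"))
    fit <- suppressMessages(lme4::glmer(
      form, data = df, family = stats::binomial(),
      nAGQ = nAGQ,
      control = lme4::glmerControl(
        optimizer = if (nAGQ == 0) "bobyqa" else "nloptwrap",
        calc.derivs = FALSE,
        check.conv.singular = "ignore"
      )
    ))
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    theta <- lme4::getME(fit, "theta")
    ll <- as.numeric(stats::logLik(fit))
    dfree <- length(beta) + 1L
    conv <- length(fit@optinfo$conv$lme4) == 0
    re <- lme4::ranef(fit)$year
    ranef_df <- data.frame(year = rownames(re), intercept = re[[1]])
    sd_se <- if (compute_sd_se) ranef_sd_wald_se(fit, theta, beta) else NA_real_
    separation <- any(abs(beta) > 15)
    engine <- if (nAGQ > 1) "glmer_agq" else if (nAGQ == 1) "glmer_laplace" else "glmer_pirls"
  } else {
    form <- stats::as.formula(paste(response, "~", rhs))
    fit <- stats::glm(form, data = df, family = stats::binomial())
    beta <- stats::coef(fit)
    separation <- !fit$converged || any(abs(beta[!is.na(beta)]) > 15)
    if (separation && penalize) {
      X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), df)
      fr <- firth_logistic(X, df[[response]])
      beta <- fr$coef
      V <- fr$vcov
      engine <- "glm_firth"
      ll <- fr$loglik
    } else {
      if (anyNA(beta)) stopf("rank-deficient fixed-effect design (aliased: %s)",
                             paste(names(beta)[is.na(beta)], collapse = ", "))
      V <- stats::vcov(fit)
      ll <- as.numeric(stats::logLik(fit))
      engine <- "glm"
    }
    theta <- 0
    dfree <- length(beta)
    conv <- TRUE
    ranef_df <- data.frame(year = unique(as.character(df$year)), intercept = 0)
    sd_se <- NA_real_
  }
  null_dev <- {
    p0 <- mean(y)
    -2 * (sum(y) * log(p0) + (n - sum(y)) * log(1 - p0))
  }
  # Wald interval for the SD on the log scale (respects positivity; the
  # sampling distribution of an SD estimate is right-skewed at few groups)
  sd_ci <- if (!is.na(sd_se) && theta > 0) {
    unname(theta * exp(c(-1, 1) * stats::qnorm(0.975) * sd_se / theta))
  } else c(NA_real_, NA_real_)
  structure(list(
    coefficients = beta,
    vcov = V,
    ranef_sd = unname(theta),
    ranef_sd_se = sd_se,
    ranef_sd_ci = sd_ci,
    ranef = ranef_df,
    logLik = ll,
    df = dfree,
    aic = -2 * ll + 2 * dfree,
    deviance = -2 * ll,
    null_deviance = null_dev,
    n = n,
    terms = terms,
    response = response,
    engine = engine,
    converged = conv,
    separation = separation,
    penalized = engine == "glm_firth",
    meta = design$meta,
    data = df,
    model = fit
  ), class = "spawn_fit")
}

# Wald SE of the random-intercept SD via the hessian of the marginal
# deviance; NA at the boundary or on failure. With adaptive quadrature the
# deviance function takes c(theta, beta); the Laplace/PIRLS deviance is a
# function of theta alone with beta profiled out, giving a profile Wald SE.
ranef_sd_wald_se <- function(fit, theta, beta) {
  if (theta < 1e-6) return(NA_real_)
  tryCatch({
    devfun <- lme4::getME(fit, "devfun")
    pars <- tryCatch({
      devfun(c(theta, beta))
      c(theta, beta)
    }, error = function(e) theta)
    H <- stats::optimHess(pars, devfun)
    Vfull <- 2 * solve(H)
    sqrt(Vfull[1, 1])
  }, error = function(e) NA_real_)
}

# Firth (Jeffreys-prior) penalized logistic regression by modified IRLS.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    Vinv <- solve(XtWX)
    h <- rowSums((XW %*% Vinv) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(Vinv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  XtWX <- crossprod(X * sqrt(w))
  ll <- sum(y * log(p) + (1 - y) * log(1 - p)) + 0.5 * determinant(XtWX)$modulus
  names(beta) <- colnames(X)
  list(coef = beta, vcov = solve(XtWX), loglik = as.numeric(ll))
}

#' @export
print.spawn_fit <- function(x, ...) {
  cat(sprintf("<spawn_fit> %s, n = %d\n", x$engine, x$n))
  cat("  terms:", if (length(x$terms)) paste(x$terms, collapse = ", ") else "(intercept only)", "\n")
  cat(sprintf("  logLik = %.3f, AIC = %.2f, year SD = %.4f\n",
              x$logLik, x$aic, x$ranef_sd))
  if (x$separation) cat("  note: separation detected",
                        if (x$penalized) "(Firth-penalized fit)" else "", "\n")
  invisible(x)
}

#' @export
summary.spawn_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, ranef_sd = object$ranef_sd,
              ranef_sd_se = object$ranef_sd_se,
              aic = object$aic, logLik = object$logLik, n = object$n,
              engine = object$engine,
              pct_deviance = 100 * (object$null_deviance - object$deviance) /
                object$null_deviance)
  class(out) <- "summary.spawn_fit"
  out
}

#' @export
print.summary.spawn_fit <- function(x, ...) {
  cat(sprintf("Mixed logistic spawning model (%s), n = %d\n", x$engine, x$n))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nYear random-intercept SD: %.4f", x$ranef_sd))
  if (!is.na(x$ranef_sd_se)) cat(sprintf(" (Wald SE %.4f)", x$ranef_sd_se))
  cat(sprintf("\nlogLik %.3f, AIC %.2f, deviance explained %.1f%%\n",
              x$logLik, x$aic, x$pct_deviance))
  invisible(x)
}

#' @export
coef.spawn_fit <- function(object, ...) object$coefficients

#' @export
vcov.spawn_fit <- function(object, ...) object$vcov

#' @export
logLik.spawn_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n, class = "logLik")
}

# Fixed-effects model matrix for (possibly re-encoded) data. Factor columns
# are re-leveled to the fit's training levels; levels unseen in training map
# to the reference level (warning, or error under strict).
fit_model_matrix <- function(object, data, strict = FALSE) {
  rhs <- if (length(object$terms)) {
    paste(sprintf("`%s`", object$terms), collapse = " + ")
  } else "1"
  unseen <- character(0)
  for (t in object$terms) {
    if (is.factor(object$data[[t]])) {
      levs <- levels(object$data[[t]])
      f <- factor(as.character(data[[t]]), levels = levs)
      bad <- is.na(f) & !is.na(data[[t]])
      if (any(bad)) {
        unseen <- c(unseen, t)
        f[bad] <- levs[1]
      }
      data[[t]] <- f
    }
  }
  if (length(unseen)) {
    msg <- sprintf("level(s) unseen in training mapped to reference for: %s",
                   paste(unique(unseen), collapse = ", "))
    if (strict) stopf("%s", msg) else warnf("%s", msg)
  }
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data)
  cn <- names(object$coefficients)
  missing_cols <- setdiff(cn, colnames(mm))
  if (length(missing_cols)) {
    add <- matrix(0, nrow(mm), length(missing_cols),
                  dimnames = list(NULL, missing_cols))
    mm <- cbind(mm, add)
  }
  mm[, cn, drop = FALSE]
}

#' Population-level predictions with delta-method standard errors
#'
#' Predicts the probability that an examined mature female is in spawning
#' condition, with the year random intercept set to 0 (population level, as
#' used for multi-year prediction maps). The standard error is obtained by
#' the delta method: the SE of the linear predictor mapped through the
#' logistic derivative `p(1-p)`.
#'
#' `newdata` may be encoded design columns, or raw covariates (collections
#' schema plus terrain statistic columns), which are re-encoded with the
#' stored bin edges and factor levels; unseen factor levels map to the
#' reference level with a warning (`strict = TRUE` raises instead).
#'
#' @param object a `spawn_fit`.
#' @param newdata data.frame; default: the fitted data.
#' @param type `"response"` (probability) or `"link"`.
#' @param se.fit return standard errors (default `TRUE`).
#' @param strict error on unseen factor levels.
#' @param ... unused.
#' @return data.frame with `fit`, `se.fit`, `eta`, `se.eta`.
#' @export
predict.spawn_fit <- function(object, newdata = NULL, type = c("response", "link"),
                              se.fit = TRUE, strict = FALSE, ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) {
    object$data
  } else {
    enc <- all(object$terms %in% names(newdata)) &&
      all(vapply(object$terms, function(t) {
        !is.factor(object$data[[t]]) || is.factor(newdata[[t]])
      }, logical(1)))
    if (enc) newdata else apply_design_meta(object$meta, object$terms, newdata,
                                            strict = strict)
  }
  X <- fit_model_matrix(object, data, strict = strict)
  eta <- drop(X %*% object$coefficients)
  se_eta <- if (se.fit) sqrt(rowSums((X %*% object$vcov) * X)) else NULL
  p <- stats::plogis(eta)
  out <- data.frame(fit = if (type == "response") p else eta)
  if (se.fit) {
    out$se.fit <- if (type == "response") p * (1 - p) * se_eta else se_eta
  }
  out$eta <- eta
  if (se.fit) out$se.eta <- se_eta
  out
}

#' @export
fitted.spawn_fit <- function(object, ...) {
  predict(object, se.fit = FALSE)$fit
}

#' @export
residuals.spawn_fit <- function(object, type = c("deviance", "response"), ...) {
  type <- match.arg(type)
  y <- object$data[[object$response]]
  p <- fitted(object)
  if (type == "response") return(y - p)
  d2 <- -2 * (y * log(p) + (1 - y) * log(1 - p))
  sign(y - p) * sqrt(pmax(d2, 0))
}

#' Simulate spawning flags from a fitted model
#'
#' Draws Bernoulli responses at the population-level fitted probabilities;
#' with `re.form = "draw"` a fresh year intercept `N(0, ranef_sd)` is drawn
#' per simulation and shared across rows of the same year.
#'
#' @param object a `spawn_fit`.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param newdata optional covariates (see [predict.spawn_fit()]).
#' @param re.form `NA` (population level, default) or `"draw"`.
#' @param ... unused.
#' @return data.frame of `nsim` simulated 0/1 columns.
#' @export
simulate.spawn_fit <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                               re.form = NA, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object, newdata = newdata, se.fit = FALSE)
  eta <- pr$eta
  data <- if (is.null(newdata)) object$data else newdata
  out <- lapply(seq_len(nsim), function(s) {
    eta_s <- eta
    if (identical(re.form, "draw") && "year" %in% names(data)) {
      yl <- factor(data$year)
      u <- stats::rnorm(nlevels(yl), 0, object$ranef_sd)
      eta_s <- eta + u[as.integer(yl)]
    }
    stats::rbinom(length(eta_s), 1, stats::plogis(eta_s))
  })
  names(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}

#' Percent deviance explained along a nested model sequence
#'
#' For a nested sequence of fits on identical rows, term `i`'s percent
#' deviance explained is `100 * (deviance[i-1] - deviance[i]) / null`, with
#' the null deviance taken from the intercept-only model; the total is
#' `100 * (null - final) / null` and the per-term values sum to it exactly.
#' Deviance here is -2 times the marginal log-likelihood, so adding the year
#' random intercept is itself a step with an attributable share.
#'
#' @param fits list of `spawn_fit` objects, nested, starting from the
#'   intercept-only fixed-effects model.
#' @param labels optional step labels (default: the term added at each step).
#' @return data.frame with `term` and `pct_deviance`, plus attribute `total`.
#' @export
deviance_explained <- function(fits, labels = NULL) {
  if (length(fits) < 2) stopf("need at least two nested fits")
  ns <- vapply(fits, function(f) f$n, 0)
  if (length(unique(ns)) != 1) stopf("fits are not on identical rows")
  tl <- lapply(fits, function(f) f$terms)
  for (i in seq_along(fits)[-1]) {
    if (!all(tl[[i - 1]] %in% tl[[i]])) stopf("fits are not a nested sequence")
  }
  null_dev <- fits[[1]]$deviance
  devs <- vapply(fits, function(f) f$deviance, 0)
  if (is.null(labels)) {
    labels <- vapply(seq_along(fits)[-1], function(i) {
      added <- setdiff(tl[[i]], tl[[i - 1]])
      if (length(added)) paste(added, collapse = "+")
      else if (fits[[i]]$ranef_sd > 0 || fits[[i]]$engine != "glm") "year" else "(none)"
    }, "")
  }
  pct <- 100 * (devs[-length(devs)] - devs[-1]) / null_dev
  out <- data.frame(term = labels, pct_deviance = pct)
  attr(out, "total") <- 100 * (null_dev - devs[length(devs)]) / null_dev
  out
}

#' Serialize a fitted model to JSON
#'
#' Records coefficients, covariance, the random-intercept SD, bin metadata
#' and convergence diagnostics, sufficient to reproduce predictions.
#'
#' @param fit a `spawn_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spawn_fit_json <- function(fit, path) {
  obj <- list(
    terms = fit$terms,
    coefficients = as.list(fit$coefficients),
    vcov = unclass(fit$vcov),
    ranef_sd = fit$ranef_sd,
    ranef = fit$ranef,
    logLik = fit$logLik, aic = fit$aic, n = fit$n,
    engine = fit$engine, converged = fit$converged,
    separation = fit$separation, penalized = fit$penalized,
    meta = list(edges = fit$meta$edges, levels = fit$meta$levels,
                lunar_mode = fit$meta$lunar_mode)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
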