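#' Parametric growth-model curves
#'
#' Evaluates the three classical reparameterized growth forms used for
#' microbioreactor biomass curves, each parameterized directly by capacity
#' \code{A}, maximal growth rate \code{mu} (slope at the inflection) and lag
#' period \code{lambda} (intercept of the inflection tangent with the
#' baseline):
#' \itemize{
#'   \item logistic: \eqn{y = A / (1 + \exp(4\mu(\lambda - t)/A + 2))}
#'   \item Gompertz: \eqn{y = A \exp(-\exp(\mu e (\lambda - t)/A + 1))}
#'   \item Richards: \eqn{y = A (1 + \nu e^{1+\nu}
#'     \exp(\mu (1+\nu)^{1+1/\nu} (\lambda - t)/A))^{-1/\nu}}
#' }
#' All three approach \code{A} as \eqn{t \to \infty}.
#'
#' @param model one of \code{"logistic"}, \code{"gompertz"},
#'   \code{"richards"}.
#' @param t time vector (hours).
#' @param A,mu,lambda capacity, maximal rate, lag.
#' @param nu Richards shape parameter (ignored by the other forms).
#' @return biomass values at \code{t}.
#' @export
growth_model_value <- function(model, t, A, mu, lambda, nu = 1) {
  assert_that(A > 0 && mu > 0, "A and mu must be positive")
  switch(match.arg(model, c("logistic", "gompertz", "richards")),
    logistic = A / (1 + exp(4 * mu * (lambda - t) / A + 2)),
    gompertz = A * exp(-exp(mu * exp(1) * (lambda - t) / A + 1)),
    richards = A * (1 + nu * exp(1 + nu) *
                      exp(mu * (1 + nu)^(1 + 1 / nu) * (lambda - t) / A)
                    )^(-1 / nu))
}

growth_models <- c("logistic", "gompertz", "richards")

# Deterministic starting values: A0 = max biomass, mu0 = max finite-difference
# slope, lambda0 = intercept of the max-slope tangent with the baseline.
growth_start_values <- function(time, biomass) {
  A0 <- max(biomass)
  slopes <- diff(biomass) / diff(time)
  i <- which.max(slopes)
  mu0 <- max(slopes[i], 1e-8)
  tmid <- (time[i] + time[i + 1]) / 2
  ymid <- (biomass[i] + biomass[i + 1]) / 2
  y0 <- min(biomass)
  lambda0 <- tmid - (ymid - y0) / mu0
  list(A = A0, mu = mu0, lambda = max(lambda0, 0))
}

#' Fit a parametric growth model to one biomass curve
#'
#' Nonlinear least squares fit of one of the forms in
#' \code{\link{growth_model_value}} to a biomass curve (readings normalised to
#' time 0). Initialisation is deterministic (see Details in the vignette);
#' the Richards shape \code{nu} is bounded in [0.1, 10] for identifiability.
#' Non-convergence is reported via \code{converged = FALSE} with the solver
#' message; there is no silent fallback to another model.
#'
#' @param time strictly increasing time vector (hours), length >= 8.
#' @param biomass biomass readings, same length.
#' @param model model name.
#' @return object of class \code{growth_fit}: list with \code{model},
#'   \code{A}, \code{mu}, \code{lambda}, \code{nu} (Richards only, else NA),
#'   \code{rss}, \code{aic} (Gaussian likelihood), \code{converged},
#'   \code{message}, \code{n}.
#' @export
fit_growth_model <- function(time, biomass, model = "gompertz") {
  model <- match.arg(model, growth_models)
  assert_that(length(time) == length(biomass) && length(time) >= 8,
              "need >= 8 (time, biomass) samples")
  assert_that(all(diff(time) > 0), "times must be strictly increasing")

  st <- growth_start_values(time, biomass)
  n <- length(time)
  dat <- data.frame(t = time, y = biomass)

  failed <- function(msg) {
    structure(list(model = model, A = NA_real_, mu = NA_real_,
                   lambda = NA_real_, nu = NA_real_, rss = NA_real_,
                   aic = NA_real_, converged = FALSE, message = msg, n = n),
              class = "growth_fit")
  }
  if (stats::sd(biomass) < 1e-12) {
    return(failed("constant biomass: no growth signal to fit"))
  }

  form <- switch(model,
    logistic = y ~ A / (1 + exp(4 * mu * (lambda - t) / A + 2)),
    gompertz = y ~ A * exp(-exp(mu * exp(1) * (lambda - t) / A + 1)),
    richards = y ~ A * (1 + nu * exp(1 + nu) *
                          exp(mu * (1 + nu)^(1 + 1 / nu) * (lambda - t) / A)
                        )^(-1 / nu))
  start <- st
  lower <- c(A = 1e-8, mu = 1e-8, lambda = -Inf)
  upper <- c(A = Inf, mu = Inf, lambda = Inf)
  if (model == "richards") {
    start$nu <- 1
    lower <- c(lower, nu = 0.1)
    upper <- c(upper, nu = 10)
  }

  fit <- tryCatch(
    stats::nls(form, data = dat, start = start, algorithm = "port",
               lower = lower, upper = upper,
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) e)

  if (!inherits(fit, "error")) {
    cf <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
  } else {
    # Same model, direct RSS minimization: log-scale for the positive
    # parameters, Richards nu kept inside its bounds by clamping.
    rss_fn <- function(par) {
      A <- exp(par[1]); mu <- exp(par[2]); lambda <- par[3]
      nu <- if (model == "richards") min(max(par[4], 0.1), 10) else 1
      yhat <- growth_model_value(model, time, A, mu, lambda, nu)
      sum((biomass - yhat)^2)
    }
    p0 <- c(log(start$A), log(start$mu), start$lambda,
            if (model == "richards") 1)
    opt <- tryCatch(stats::optim(p0, rss_fn, method = "Nelder-Mead",
                                 control = list(maxit = 2000,
                                                reltol = 1e-12)),
                    error = function(e) e)
    if (inherits(opt, "error")) return(failed(conditionMessage(opt)))
    if (opt$convergence != 0) {
      return(failed(paste("optim fallback did not converge:",
                          opt$convergence)))
    }
    cf <- c(A = exp(opt$par[1]), mu = exp(opt$par[2]), lambda = opt$par[3])
    if (model == "richards") {
      cf <- c(cf, nu = min(max(opt$par[4], 0.1), 10))
    }
    rss <- opt$value
  }
  k <- length(cf)
  aic <- n * log(2 * pi * rss / n) + n + 2 * (k + 1)
  structure(list(model = model,
                 A = unname(cf["A"]), mu = unname(cf["mu"]),
                 lambda = unname(cf["lambda"]),
                 nu = if (model == "richards") unname(cf["nu"]) else NA_real_,
                 rss = rss, aic = aic, converged = TRUE, message = "ok",
                 n = n),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("growth_fit [%s]: NOT converged (%s)\n", x$model, x$message))
  } else {
    cat(sprintf(
      "growth_fit [%s]: A=%.4g, mu=%.4g, lambda=%.4g, AIC=%.2f\n",
      x$model, x$A, x$mu, x$lambda, x$aic))
  }
  invisible(x)
}

#' Select the best growth model by AIC
#'
#' Among converged fits, returns the one with minimal AIC. Ties (within
#' \code{tol}) are broken toward the model with fewer parameters, so the
#' 4-parameter Richards form never wins on equal footing.
#'
#' @param fits list of \code{growth_fit} objects for the same curve.
#' @param tol AIC difference treated as a tie.
#' @return the selected \code{growth_fit}.
#' @export
select_best_model <- function(fits, tol = 1e-8) {
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  assert_that(length(ok) > 0, "no converged fit to select from")
  npar <- vapply(ok, function(f) if (f$model == "richards") 4L else 3L,
                 integer(1))
  aics <- vapply(ok, function(f) f$aic, numeric(1))
  best <- min(aics)
  cand <- which(aics <= best + tol)
  ok[[cand[order(npar[cand], aics[cand])[1]]]]
}

#' Compare a growth parameter across strain/treatment groups
#'
#' One-way ANOVA on a fitted parameter (e.g. \code{mu} or \code{lambda})
#' across groups, followed by either Tukey's Honest Significant Difference
#' test for all pairwise comparisons (\code{scheme = "all_pairs"}) or a
#' Dunnett-style many-to-one comparison against a named control
#' (\code{scheme = "vs_control"}). The many-to-one comparison is implemented
#' with pooled-variance t statistics and Bonferroni adjustment over the
#' control contrasts (flagged in the output as \code{method}), a conservative
#' stand-in for the multivariate-t Dunnett adjustment.
#'
#' @param values numeric vector of per-well parameter estimates.
#' @param group group label per value.
#' @param scheme \code{"all_pairs"} or \code{"vs_control"}.
#' @param control control group label (required for \code{vs_control}).
#' @param welch use Welch ANOVA instead of the classical equal-variance one.
#' @return list with \code{anova_p}, \code{comparisons} (data frame with
#'   \code{contrast}, \code{estimate}, \code{p_value}, \code{p_adjusted})
#'   and \code{method}.
#' @export
compare_growth_params <- function(values, group,
                                  scheme = c("all_pairs", "vs_control"),
                                  control = NULL, welch = FALSE) {
  scheme <- match.arg(scheme)
  group <- factor(group)
  assert_that(nlevels(group) >= 2, "need >= 2 groups")
  assert_that(all(table(group) >= 2), "need >= 2 values per group")
  dat <- data.frame(value = values, group = group)

  anova_p <- if (welch) {
    stats::oneway.test(value ~ group, data = dat, var.equal = FALSE)$p.value
  } else {
    fit0 <- stats::aov(value ~ group, data = dat)
    summary(fit0)[[1]][["Pr(>F)"]][1]
  }

  if (scheme == "all_pairs") {
    fit <- stats::aov(value ~ group, data = dat)
    tk <- stats::TukeyHSD(fit)$group
    comp <- data.frame(contrast = rownames(tk),
                       estimate = tk[, "diff"],
                       p_value = tk[, "p adj"],
                       p_adjusted = tk[, "p adj"],
                       row.names = NULL)
    method <- "tukey_hsd"
  } else {
    assert_that(!is.null(control) && control %in% levels(group),
                "control group must be one of the group labels")
    fit <- stats::aov(value ~ group, data = dat)
    mse <- sum(stats::resid(fit)^2) / fit$df.residual
    means <- tapply(dat$value, dat$group, mean)
    ns <- table(dat$group)
    others <- setdiff(levels(group), control)
    est <- means[others] - means[control]
    se <- sqrt(mse * (1 / ns[others] + 1 / ns[[control]]))
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), df = fit$df.residual)
    comp <- data.frame(contrast = paste(others, control, sep = "-"),
                       estimate = as.numeric(est),
                       p_value = as.numeric(p),
                       p_adjusted = pmin(1, as.numeric(p) * length(others)),
                       row.names = NULL)
    method <- "dunnett_bonferroni"
  }
  list(anova_p = anova_p, comparisons = comp, method = method)
}
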