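## Maximum-likelihood fitters for the three conditional models, their
## log-likelihoods, and the ridge-penalized variants used when bootstrap
## refits are unstable.

.SOCIAL_COVARS <- c("alcohol_prev", "mood_prev", "non_working", "t08", "t16")
.ALC_COVARS <- c("mood_prev", "non_working", "t08", "t16", "social_now")
.MOOD_COVARS <- c("alcohol_now", "alcohol_prev", "mood_prev", "non_working",
                  "t08", "t16", "social_now")

.design <- function(mf, covars) {
  X <- cbind(intercept = 1, as.matrix(mf[covars]))
  storage.mode(X) <- "double"
  X
}

.se_from_vcov <- function(V) {
  if (is.null(V)) return(NULL)
  d <- diag(V)
  sqrt(ifelse(d > 0, d, NA_real_))
}

.separation_flag <- function(coef, se) {
  any(abs(coef) > 10, na.rm = TRUE) || any(se > 50, na.rm = TRUE)
}

## log-likelihoods ------------------------------------------------------------

#' Log-likelihood of a parameter set on a model frame
#'
#' Evaluate the log-likelihood of a full parameter object on the rows of a
#' [model_frame()] (for the alcohol model, on its non-intervention rows).
#' Useful for comparing fitted with generating parameters.
#'
#' @param params a `social_params`, `alcohol_params` or `mood_params` object.
#' @param mf a [model_frame()].
#' @return scalar log-likelihood.
#' @export
social_loglik <- function(params, mf) {
  p <- social_prob(params, mf)
  sum(mf$social * log(p) + (1 - mf$social) * log1p(-p))
}

#' @rdname social_loglik
#' @export
alcohol_loglik <- function(params, mf) {
  mf <- mf[!mf$intervention, , drop = FALSE]
  sum(log(zip_pmf(params, mf, mf$alcohol_units)))
}

#' @rdname social_loglik
#' @export
mood_loglik <- function(params, mf) {
  p <- mood_probs(params, mf)
  sum(log(pmax(p[cbind(seq_len(nrow(p)), mf$mood + 3L)], 1e-300)))
}

## social model ---------------------------------------------------------------

#' Fit the social-interaction logistic model
#'
#' Logistic regression of social interaction on lagged alcohol units, lagged
#' mood, the non-working-day flag and time of day, using rows 2..T of the
#' series (the first time point is fixed and only supplies lags). `ridge > 0`
#' switches to a ridge-penalized maximum-likelihood fit (slopes penalized,
#' intercept free), intended for unstable bootstrap refits.
#'
#' @param series a `trial_series`.
#' @param grid matching `measurement_grid` (default: series attribute).
#' @param ridge non-negative ridge penalty on the slopes.
#' @param mf a pre-built [model_frame()] (rebuilt from the series when
#'   omitted); lets several fitters share one frame.
#' @return a `social_fit`: parameters, SEs, covariance, log-likelihood and a
#'   quasi-separation flag (`|coef| > 10` or `se > 50`).
#' @export
fit_social <- function(series, grid = attr(series, "grid"), ridge = 0,
                       mf = NULL) {
  if (is.null(mf)) mf <- model_frame(series, grid)
  X <- .design(mf, .SOCIAL_COVARS)
  y <- mf$social
  if (ridge > 0) {
    fit <- .ridge_logistic(X, y, ridge)
  } else {
    g <- stats::glm.fit(X, y, family = stats::binomial())
    V <- tryCatch(solve(crossprod(X * sqrt(g$weights))),
                  error = function(e) NULL)
    fit <- list(coef = g$coefficients, vcov = V, converged = g$converged)
  }
  se <- .se_from_vcov(fit$vcov)
  cf <- fit$coef
  params <- social_params(cf[["intercept"]], cf[["alcohol_prev"]],
                          cf[["mood_prev"]], cf[["non_working"]],
                          cf[["t08"]], cf[["t16"]])
  names(se) <- names(cf)
  structure(list(params = params, coef = cf, se = se, vcov = fit$vcov,
                 loglik = social_loglik(params, mf), nobs = length(y),
                 separation = .separation_flag(cf, se),
                 converged = isTRUE(fit$converged), ridge = ridge),
            class = "social_fit")
}

.ridge_logistic <- function(X, y, ridge) {
  pen <- c(0, rep(ridge, ncol(X) - 1)) # intercept unpenalized
  nll <- function(th) {
    p <- .expit(drop(X %*% th))
    -sum(y * log(p) + (1 - y) * log1p(-p)) + sum(pen * th^2)
  }
  gr <- function(th) drop(crossprod(X, .expit(drop(X %*% th)) - y)) + 2 * pen * th
  opt <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 500))
  H <- stats::optimHess(opt$par, nll, gr)
  V <- tryCatch(solve(H), error = function(e) NULL)
  list(coef = stats::setNames(opt$par, colnames(X)), vcov = V,
       converged = opt$convergence == 0)
}

## alcohol model --------------------------------------------------------------

#' Fit the zero-inflated Poisson alcohol model
#'
#' Direct maximum-likelihood fit (BFGS with analytic gradient) of the
#' zero-inflated Poisson model for alcohol units on the non-intervention rows
#' only, since consumption under abstinence is deterministically zero. Both
#' components (logit of the structural-zero probability; log Poisson mean)
#' use lagged mood, the non-working-day flag, time of day and current social
#' interaction. Quasi-separation in the zero component is permitted and
#' flagged, not suppressed. `ridge > 0` penalizes the slopes of both
#' components.
#'
#' @inheritParams fit_social
#' @param se compute standard errors (numerical Hessian)? Refit-heavy
#'   callers like the bootstrap switch this off.
#' @return an `alcohol_fit` with an [alcohol_params()] object, coefficient
#'   vector (`zero_*`, `count_*`), SEs from the numerical Hessian,
#'   log-likelihood and separation flag.
#' @export
fit_alcohol <- function(series, grid = attr(series, "grid"), ridge = 0,
                        se = TRUE, mf = NULL) {
  if (is.null(mf)) mf <- model_frame(series, grid)
  sub <- mf[!mf$intervention, , drop = FALSE]
  if (nrow(sub) < 2)
    stop("too few non-intervention rows to fit the alcohol model", call. = FALSE)
  X <- .design(sub, .ALC_COVARS)
  y <- sub$alcohol_units
  if (all(y == 0))
    stop("all non-intervention alcohol counts are zero; count component cannot be fit",
         call. = FALSE)
  k <- ncol(X)
  pen <- c(0, rep(ridge, k - 1), 0, rep(ridge, k - 1))

  nll <- function(th) {
    zl <- .clip_lp(drop(X %*% th[1:k]))
    cl <- .clip_lp(drop(X %*% th[(k + 1):(2 * k)]))
    pi0 <- stats::plogis(zl); lam <- exp(cl)
    l0 <- log(pi0 + (1 - pi0) * exp(-lam))
    lpos <- log1p(-pi0) + y * cl - lam - lgamma(y + 1)
    -sum(ifelse(y == 0, l0, lpos)) + sum(pen * th^2)
  }
  grd <- function(th) {
    zl <- .clip_lp(drop(X %*% th[1:k]))
    cl <- .clip_lp(drop(X %*% th[(k + 1):(2 * k)]))
    pi0 <- stats::plogis(zl); lam <- exp(cl)
    L0 <- pi0 + (1 - pi0) * exp(-lam)
    dz <- ifelse(y == 0, pi0 * (1 - pi0) * (1 - exp(-lam)) / L0, -pi0)
    dc <- ifelse(y == 0, -(1 - pi0) * exp(-lam) * lam / L0, y - lam)
    -c(drop(crossprod(X, dz)), drop(crossprod(X, dc))) + 2 * pen * th
  }

  # starts: logistic fit for P(zero), Poisson fit on positives for the mean
  sz <- tryCatch(stats::glm.fit(X, as.numeric(y == 0),
                                family = stats::binomial())$coefficients,
                 error = function(e) rep(0, k))
  sc <- tryCatch(stats::glm.fit(X[y > 0, , drop = FALSE], y[y > 0],
                                family = stats::poisson())$coefficients,
                 error = function(e) rep(0, k))
  sz[!is.finite(sz)] <- 0; sc[!is.finite(sc)] <- 0
  start <- c(pmin(pmax(sz, -8), 8), pmin(pmax(sc, -8), 8))

  opt <- stats::optim(start, nll, grd, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-10))
  V <- if (se) {
    H <- stats::optimHess(opt$par, nll, grd)
    tryCatch(solve(H), error = function(e) NULL)
  }
  se_v <- .se_from_vcov(V)

  nm <- c("intercept", .ALC_COVARS)
  zero <- stats::setNames(opt$par[1:k], sub("social_now", "social", nm))
  count <- stats::setNames(opt$par[(k + 1):(2 * k)], sub("social_now", "social", nm))
  cf <- c(stats::setNames(zero, paste0("zero_", names(zero))),
          stats::setNames(count, paste0("count_", names(count))))
  if (!is.null(se_v)) names(se_v) <- names(cf)
  params <- alcohol_params(zero = zero, count = count)
  structure(list(params = params, coef = cf, se = se_v, vcov = V,
                 loglik = -(opt$value - sum(pen * opt$par^2)),
                 nobs = length(y),
                 separation = .separation_flag(cf, se_v),
                 converged = opt$convergence == 0, ridge = ridge),
            class = "alcohol_fit")
}

## mood model -----------------------------------------------------------------

#' Fit the proportional-odds mood model
#'
#' Cumulative-logit (proportional-odds) fit of mood (-2..2) on current and
#' lagged alcohol units, lagged mood, the non-working-day flag, time of day
#' and current social interaction, on rows 2..T over all periods. The
#' category set is fixed at -2..2: categories unobserved in the data keep
#' their place, with boundary cutpoints pushed to +-Inf (probability zero)
#' and a `missing_categories` flag raised, so that effect estimates stay on a
#' stable scale across bootstrap refits. With exactly two observed categories
#' the model reduces to (and is fit as) a logistic regression.
#'
#' @inheritParams fit_social
#' @param se compute standard errors (requires the Hessian)?
#' @return a `mood_fit` with a [mood_params()] object (cutpoints for
#'   `P(Y >= j)`, positive slopes meaning better mood), slope SEs,
#'   log-likelihood, and flags.
#' @export
fit_mood <- function(series, grid = attr(series, "grid"), ridge = 0,
                     se = TRUE, mf = NULL) {
  if (is.null(mf)) mf <- model_frame(series, grid)
  obs_lv <- sort(unique(mf$mood))
  if (length(obs_lv) < 2)
    stop("mood has fewer than 2 observed categories; model cannot be fit",
         call. = FALSE)
  X <- as.matrix(mf[.MOOD_COVARS])
  if (ridge > 0) {
    fit <- .ridge_polr(X, mf$mood, obs_lv, ridge)
  } else if (length(obs_lv) == 2) {
    # collapsed ordinal model == logistic regression on the upper category
    Xb <- cbind(intercept = 1, X)
    g <- stats::glm.fit(Xb, as.numeric(mf$mood == obs_lv[2]),
                        family = stats::binomial())
    V <- tryCatch(solve(crossprod(Xb * sqrt(g$weights))),
                  error = function(e) NULL)
    fit <- list(slopes = g$coefficients[-1],
                alpha_obs = g$coefficients[[1]], # P(Y >= upper) threshold
                vcov_slopes = if (!is.null(V)) V[-1, -1, drop = FALSE],
                converged = g$converged)
  } else {
    d <- data.frame(y = factor(mf$mood, levels = obs_lv), X)
    # explicit starts (zero slopes, empirical cumulative-logit thresholds)
    # keep the internal optimizer away from non-finite initial deviances
    fr <- cumsum(table(d$y) / nrow(d))
    zeta0 <- stats::qlogis(pmin(pmax(fr[-length(fr)], 1e-4), 1 - 1e-4))
    pf <- MASS::polr(y ~ ., data = d, Hess = se,
                     start = c(rep(0, ncol(X)), zeta0))
    V <- if (se) tryCatch(solve(pf$Hessian), error = function(e) NULL)
    ns <- length(pf$coefficients)
    fit <- list(slopes = pf$coefficients,
                alpha_obs = -pf$zeta, # P(Y >= level m+1) = expit(-zeta_m + eta)
                vcov_slopes = if (!is.null(V)) V[1:ns, 1:ns, drop = FALSE],
                converged = pf$convergence == 0)
  }

  # map thresholds between observed categories onto the fixed -2..2 scale
  cut_cats <- -1:2
  alpha <- vapply(cut_cats, function(cc) {
    m <- sum(obs_lv < cc)
    if (m == 0) Inf else if (m == length(obs_lv)) -Inf else fit$alpha_obs[[m]]
  }, numeric(1))

  b <- fit$slopes
  params <- mood_params(cutpoints = alpha,
                        b_alcohol_now = b[["alcohol_now"]],
                        b_alcohol_prev = b[["alcohol_prev"]],
                        b_mood_prev = b[["mood_prev"]],
                        b_non_working = b[["non_working"]],
                        b_t08 = b[["t08"]], b_t16 = b[["t16"]],
                        b_social = b[["social_now"]])
  se <- .se_from_vcov(fit$vcov_slopes)
  if (!is.null(se)) names(se) <- names(params$slopes)
  structure(list(params = params, coef = params$slopes, cutpoints = alpha,
                 se = se, vcov = fit$vcov_slopes,
                 loglik = mood_loglik(params, mf), nobs = nrow(mf),
                 missing_categories = length(obs_lv) < 5,
                 separation = .separation_flag(params$slopes, se),
                 converged = isTRUE(fit$converged), ridge = ridge),
            class = "mood_fit")
}

.ridge_polr <- function(X, y, obs_lv, ridge) {
  # theta = (alpha_1, -log-gaps..., slopes); cutpoints kept ordered by
  # construction
  nlv <- length(obs_lv)
  ns <- ncol(X)
  ncut <- nlv - 1
  yi <- match(y, obs_lv)
  unpack <- function(th) {
    a1 <- th[1]
    alpha <- a1 - c(0, cumsum(exp(th[seq_len(ncut - 1) + 1])))
    list(alpha = alpha, beta = th[(ncut + 1):(ncut + ns)])
  }
  nll <- function(th) {
    pp <- unpack(th)
    eta <- drop(X %*% pp$beta)
    pge <- cbind(1, vapply(pp$alpha, function(a) .expit(a + eta),
                           numeric(length(eta))), 0)
    pr <- pge[cbind(seq_along(eta), yi)] - pge[cbind(seq_along(eta), yi + 1L)]
    -sum(log(pmax(pr, 1e-300))) + ridge * sum(pp$beta^2)
  }
  # empirical cumulative logits as starts
  fr <- as.numeric(table(factor(y, levels = obs_lv))) / length(y)
  a_emp <- stats::qlogis(rev(cumsum(rev(fr)))[-1]) # P(Y >= level m+1)
  gaps <- pmax(-diff(a_emp), 1e-3)
  start <- c(a_emp[1], if (ncut > 1) log(gaps), rep(0, ns))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 1000))
  pp <- unpack(opt$par)
  H <- tryCatch(stats::optimHess(opt$par, nll), error = function(e) NULL)
  V <- tryCatch(solve(H), error = function(e) NULL)
  list(slopes = stats::setNames(pp$beta, colnames(X)),
       alpha_obs = pp$alpha,
       vcov_slopes = if (!is.null(V))
         V[(ncut + 1):(ncut + ns), (ncut + 1):(ncut + ns), drop = FALSE],
       converged = opt$convergence == 0)
}

## shared methods -------------------------------------------------------------

#' @export
print.social_fit <- function(x, ...) .print_fit(x, "Social interaction (logistic)")
#' @export
print.alcohol_fit <- function(x, ...) .print_fit(x, "Alcohol units (zero-inflated Poisson)")
#' @export
print.mood_fit <- function(x, ...) .print_fit(x, "Mood (proportional odds)")

.print_fit <- function(x, title) {
  cat(title, sprintf("- %d rows, logLik %.2f\n", x$nobs, x$loglik))
  print(round(fit_summary_table(x)[c("term", "estimate", "ci_low", "ci_high")],
              3), row.names = FALSE)
  if (isTRUE(x$separation))
    cat("note: coefficients/SEs suggest quasi-complete separation\n")
  invisible(x)
}

#' @export
coef.social_fit <- function(object, ...) object$coef
#' @export
coef.alcohol_fit <- function(object, ...) object$coef
#' @export
coef.mood_fit <- function(object, ...) object$coef
#' @export
logLik.social_fit <- function(object, ...) object$loglik
#' @export
logLik.alcohol_fit <- function(object, ...) object$loglik
#' @export
logLik.mood_fit <- function(object, ...) object$loglik

#' Coefficient table of a fitted conditional model
#'
#' Estimates with normal-approximation 95% confidence intervals, one row per
#' coefficient, in the layout of a published coefficient table.
#'
#' @param fit a `social_fit`, `alcohol_fit` or `mood_fit`.
#' @param z normal quantile for the interval (default 97.5%).
#' @return data.frame with columns `term`, `estimate`, `se`, `ci_low`,
#'   `ci_high`.
#' @export
fit_summary_table <- function(fit, z = stats::qnorm(0.975)) {
  est <- fit$coef
  se <- if (is.null(fit$se)) rep(NA_real_, length(est)) else fit$se
  data.frame(term = names(est), estimate = as.numeric(est),
             se = as.numeric(se),
             ci_low = as.numeric(est) - z * as.numeric(se),
             ci_high = as.numeric(est) + z * as.numeric(se),
             row.names = NULL)
}
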