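## Parameter containers for the three conditional models, their probability
## functions, and single-draw samplers.
##
## Covariate rows are supplied as a data.frame (or list) with the fields
## produced by model_frame(): alcohol_prev, mood_prev, non_working, t08, t16,
## plus social (current) for the alcohol and mood models and alcohol_units
## (current) for the mood model.

#' Coefficients of the social-interaction logistic model
#'
#' Log-odds scale; time-of-day reference is the midnight measurement (`T00`).
#'
#' @param intercept,b_alcohol_prev,b_mood_prev,b_non_working,b_t08,b_t16
#'   finite numeric coefficients.
#' @return an object of class `social_params` (named numeric vector).
#' @export
social_params <- function(intercept = 0, b_alcohol_prev = 0, b_mood_prev = 0,
                          b_non_working = 0, b_t08 = 0, b_t16 = 0) {
  p <- c(intercept = intercept, b_alcohol_prev = b_alcohol_prev,
         b_mood_prev = b_mood_prev, b_non_working = b_non_working,
         b_t08 = b_t08, b_t16 = b_t16)
  if (!all(is.finite(p))) stop("social_params must all be finite", call. = FALSE)
  structure(p, class = "social_params")
}

#' Coefficients of the zero-inflated Poisson alcohol model
#'
#' The `zero` component is the logit of the structural-zero probability (the
#' probability of being in a non-drinking setting); the `count` component is
#' the log mean of the Poisson part. Both components use the same covariates.
#' Zero-component coefficients may be very large in magnitude
#' (quasi-separation regime).
#'
#' @param zero,count named numeric vectors with elements `intercept`,
#'   `mood_prev`, `non_working`, `t08`, `t16`, `social`.
#' @return an object of class `alcohol_params`.
#' @export
alcohol_params <- function(zero = c(intercept = 0, mood_prev = 0, non_working = 0,
                                    t08 = 0, t16 = 0, social = 0),
                           count = c(intercept = 0, mood_prev = 0, non_working = 0,
                                     t08 = 0, t16 = 0, social = 0)) {
  nm <- c("intercept", "mood_prev", "non_working", "t08", "t16", "social")
  zero <- zero[nm]; count <- count[nm]
  if (anyNA(zero) || anyNA(count) || !all(is.finite(c(zero, count))))
    stop("alcohol_params components must be complete and finite", call. = FALSE)
  names(zero) <- names(count) <- nm
  structure(list(zero = zero, count = count), class = "alcohol_params")
}

#' Coefficients of the proportional-odds mood model
#'
#' Parameterized as `P(Y >= j) = expit(alpha_j + x'beta)` over the ordered
#' categories -2..2, so positive slopes mean better mood. The four cutpoints
#' `alpha_1..alpha_4` (for categories >= -1, >= 0, >= 1, >= 2) must be
#' non-increasing; `-Inf`/`+Inf` are allowed to represent categories with
#' probability zero (they arise when refitting on samples where a boundary
#' category was never observed).
#'
#' @param cutpoints numeric length 4, non-increasing.
#' @param b_alcohol_now,b_alcohol_prev,b_mood_prev,b_non_working,b_t08,b_t16,b_social
#'   finite slopes on the latent log-odds scale.
#' @return an object of class `mood_params`.
#' @export
mood_params <- function(cutpoints = c(2, 1, -1, -2),
                        b_alcohol_now = 0, b_alcohol_prev = 0, b_mood_prev = 0,
                        b_non_working = 0, b_t08 = 0, b_t16 = 0, b_social = 0) {
  if (length(cutpoints) != 4 || anyNA(cutpoints))
    stop("mood cutpoints must be 4 numeric values", call. = FALSE)
  if (is.unsorted(rev(cutpoints)))
    stop("mood cutpoints must be non-increasing", call. = FALSE)
  slopes <- c(b_alcohol_now = b_alcohol_now, b_alcohol_prev = b_alcohol_prev,
              b_mood_prev = b_mood_prev, b_non_working = b_non_working,
              b_t08 = b_t08, b_t16 = b_t16, b_social = b_social)
  if (!all(is.finite(slopes))) stop("mood slopes must be finite", call. = FALSE)
  structure(list(cutpoints = cutpoints, slopes = slopes), class = "mood_params")
}

## linear predictors ----------------------------------------------------------

.x_field <- function(x, field, default = NULL) {
  v <- x[[field]]
  if (is.null(v)) {
    if (is.null(default)) stop("covariate '", field, "' missing", call. = FALSE)
    v <- default
  }
  as.numeric(v)
}

.social_lp <- function(params, x) {
  params[["intercept"]] +
    params[["b_alcohol_prev"]] * .x_field(x, "alcohol_prev") +
    params[["b_mood_prev"]]    * .x_field(x, "mood_prev") +
    params[["b_non_working"]]  * .x_field(x, "non_working") +
    params[["b_t08"]]          * .x_field(x, "t08") +
    params[["b_t16"]]          * .x_field(x, "t16")
}

.alc_component_lp <- function(comp, x, social) {
  comp[["intercept"]] +
    comp[["mood_prev"]]   * .x_field(x, "mood_prev") +
    comp[["non_working"]] * .x_field(x, "non_working") +
    comp[["t08"]]         * .x_field(x, "t08") +
    comp[["t16"]]         * .x_field(x, "t16") +
    comp[["social"]]      * social
}

.mood_lp <- function(params, x) {
  b <- params$slopes
  b[["b_alcohol_now"]]  * .x_field(x, "alcohol_now") +
    b[["b_alcohol_prev"]] * .x_field(x, "alcohol_prev") +
    b[["b_mood_prev"]]    * .x_field(x, "mood_prev") +
    b[["b_non_working"]]  * .x_field(x, "non_working") +
    b[["b_t08"]]          * .x_field(x, "t08") +
    b[["b_t16"]]          * .x_field(x, "t16") +
    b[["b_social"]]       * .x_field(x, "social_now")
}

## probability functions ------------------------------------------------------

#' Probability of social interaction given its direct causes
#'
#' @param params a [social_params()] object.
#' @param x covariate row(s): `alcohol_prev`, `mood_prev`, `non_working`,
#'   `t08`, `t16` (list or data.frame; logicals are coerced to 0/1).
#' @return probability vector in (0, 1).
#' @export
social_prob <- function(params, x) .expit(.social_lp(params, x))

#' Zero-inflated Poisson probability mass for alcohol units
#'
#' `P(AU = k | x) = pi(x) 1[k = 0] + (1 - pi(x)) Poisson(k; lambda(x))`, with
#' `pi` the structural-zero probability (expit of the zero-component linear
#' predictor) and `lambda` the Poisson mean (exp of the count-component
#' linear predictor).
#'
#' @param params an [alcohol_params()] object.
#' @param x covariate row(s): `mood_prev`, `non_working`, `t08`, `t16`,
#'   `social_now`.
#' @param k non-negative integer count(s).
#' @return probability vector.
#' @export
zip_pmf <- function(params, x, k) {
  if (any(k < 0) || any(k != floor(k)))
    stop("k must be a non-negative integer", call. = FALSE)
  social <- .x_field(x, "social_now")
  pi0 <- .expit(.alc_component_lp(params$zero, x, social))
  lam <- exp(.clip_lp(.alc_component_lp(params$count, x, social)))
  pi0 * (k == 0) + (1 - pi0) * stats::dpois(k, lam)
}

#' Category probabilities of the proportional-odds mood model
#'
#' @param params a [mood_params()] object.
#' @param x covariate row(s): `alcohol_now`, `alcohol_prev`, `mood_prev`,
#'   `non_working`, `t08`, `t16`, `social_now`.
#' @return matrix with one row per covariate row and columns `-2`..`2`,
#'   each row a probability simplex.
#' @export
mood_probs <- function(params, x) {
  eta <- .mood_lp(params, x)
  # P(Y >= j), j over categories -1, 0, 1, 2; +-Inf cutpoints map to 1/0
  pge <- vapply(params$cutpoints, function(a) {
    if (is.infinite(a)) rep(as.numeric(a > 0), length(eta)) else .expit(a + eta)
  }, numeric(length(eta)))
  pge <- matrix(pge, nrow = length(eta))
  p <- cbind(1 - pge[, 1],
             pge[, 1] - pge[, 2],
             pge[, 2] - pge[, 3],
             pge[, 3] - pge[, 4],
             pge[, 4])
  p[p < 0] <- 0 # clipping guards tiny negative rounding from equal cutpoints
  colnames(p) <- as.character(-2:2)
  p
}

## samplers -------------------------------------------------------------------
## Inverse-CDF draws from supplied (or freshly drawn) uniforms, so that the
## trial simulator and the g-computation engine share one documented draw
## order and common-random-number coupling is exact.

.draw_social <- function(params, x, u) as.integer(u < social_prob(params, x))

.draw_alcohol <- function(params, x, intervention, u_zero, u_pois) {
  n <- length(u_zero)
  social <- .x_field(x, "social_now")
  pi0 <- .expit(.alc_component_lp(params$zero, x, social))
  lam <- exp(.clip_lp(.alc_component_lp(params$count, x, social)))
  out <- ifelse(u_zero < pi0, 0L, stats::qpois(u_pois, lam))
  out[rep_len(as.logical(intervention), n)] <- 0L
  as.integer(out)
}

.draw_mood <- function(params, x, u) {
  p <- mood_probs(params, x)
  if (nrow(p) == 1 && length(u) > 1) p <- p[rep(1L, length(u)), , drop = FALSE]
  cum <- p                                # P(Y <= k) by running sum over columns
  for (j in 2:4) cum[, j] <- cum[, j - 1] + p[, j]
  as.integer(-2L + rowSums(u > cum[, 1:4, drop = FALSE]))
}

#' Draw one value from each conditional model
#'
#' Single random draws from the social, alcohol and mood models. Under
#' intervention (abstinence) the alcohol draw is deterministically zero and
#' the alcohol model is not consulted.
#'
#' @param params the matching parameter object.
#' @param x covariate row(s), as for the corresponding probability function.
#' @param intervention logical; abstinence at this time point?
#' @param n number of draws per covariate row (covariates recycled).
#' @return integer vector: 0/1 for social, a count for alcohol, a mood level
#'   in -2..2 for mood.
#' @export
sample_social <- function(params, x, n = 1) {
  .draw_social(params, x, stats::runif(max(n, length(.x_field(x, "mood_prev")))))
}

#' @rdname sample_social
#' @export
sample_alcohol <- function(params, x, intervention = FALSE, n = 1) {
  m <- max(n, length(.x_field(x, "mood_prev")))
  .draw_alcohol(params, x, intervention, stats::runif(m), stats::runif(m))
}

#' @rdname sample_social
#' @export
sample_mood <- function(params, x, n = 1) {
  m <- max(n, length(.x_field(x, "mood_prev")))
  .draw_mood(params, x, stats::runif(m))
}
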