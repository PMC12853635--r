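## Parametric-bootstrap standard errors and normal-approximation confidence
## intervals for the U-CATE series and its aggregates.

.fit_all <- function(trial, grid, ridge = 0, se = TRUE) {
  mf <- model_frame(trial, grid)
  list(social = fit_social(trial, grid, ridge = ridge, mf = mf),
       alcohol = fit_alcohol(trial, grid, ridge = ridge, se = se, mf = mf),
       mood = fit_mood(trial, grid, ridge = ridge, se = se, mf = mf))
}

.try_fit_all <- function(trial, grid, refit_penalty) {
  fits <- tryCatch(suppressWarnings(.fit_all(trial, grid, se = FALSE)),
                   error = function(e) e)
  ridged <- FALSE
  bad <- inherits(fits, "error") ||
    !all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))
  if (bad && refit_penalty > 0) {
    # one retry with a ridge penalty; separation makes occasional unstable
    # refits certain, a weak penalty usually restores convergence
    fits <- tryCatch(suppressWarnings(
      .fit_all(trial, grid, ridge = refit_penalty, se = FALSE)),
      error = function(e) e)
    ridged <- TRUE
    bad <- inherits(fits, "error") ||
      !all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))
  }
  list(fits = if (!bad) fits, ridged = ridged, ok = !bad,
       error = if (inherits(fits, "error")) conditionMessage(fits))
}

#' Parametric bootstrap for the U-CATE series
#'
#' For each of `n_boot` replicates: simulate one complete trial from the
#' supplied (fitted) models under the treatment assignment observed in the
#' grid, with the first time point fixed at the observed initial state; refit
#' all three models on the simulated trial; and re-run the g-computation
#' estimator with the refitted models. The standard deviation of the
#' replicate estimates at each time point approximates the estimator's
#' standard error, and 95% confidence intervals are formed by normal
#' approximation around the point estimates. Aggregate standard errors come
#' from the bootstrap distribution of the replicate-level aggregate.
#'
#' Replicates whose refits fail (after one ridge-penalized retry, see
#' `refit_penalty`) are dropped and recorded in the diagnostics; if more than
#' `max_fail` of the replicates fail the run aborts. Replicate `b` uses a
#' deterministic sub-seed of `(seed, b)`, so individual replicates are
#' reproducible and the result is invariant to replicate order.
#'
#' @inheritParams gcompute
#' @param point the point-estimate `ucate_series` around which the intervals
#'   are centred; computed with `gcompute(..., n_reps = n_reps_point)` when
#'   omitted.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param n_reps_inner g-computation repetitions inside each replicate.
#' @param n_reps_point repetitions for the point estimate when `point` is
#'   omitted.
#' @param refit_penalty ridge strength for the one retry of a failed refit
#'   (0 disables the retry).
#' @param max_fail maximum tolerated fraction of failed replicates.
#' @param z normal quantile for the 95% interval.
#' @return the `ucate_series` with `se`, `ci_low`, `ci_high` filled;
#'   attributes `boot_estimates` (successful replicate-by-time matrix),
#'   `diagnostics` (per-replicate data.frame with convergence, separation and
#'   ridge flags) and `n_effective`.
#' @export
parametric_bootstrap <- function(social, alcohol, mood, grid, initial_state,
                                 point = NULL, n_boot = 500,
                                 n_reps_inner = 800, n_reps_point = 800,
                                 seed = 1L, coupled = TRUE,
                                 refit_penalty = 0.01, max_fail = 0.2,
                                 z = stats::qnorm(0.975)) {
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  social <- .as_params(social); alcohol <- .as_params(alcohol)
  mood <- .as_params(mood)
  if (is.null(point))
    point <- gcompute(social, alcohol, mood, grid, initial_state,
                      n_reps = n_reps_point, seed = .sub_seed(seed, 0),
                      coupled = coupled)
  Tn <- nrow(grid)
  intervene <- grid$intervention
  est <- matrix(NA_real_, n_boot, Tn - 1)
  diag_rows <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    sb <- .sub_seed(seed, b)
    set.seed(sb)
    sim <- .sim_engine(social, alcohol, mood, grid, initial_state, 1L,
                       intervene)
    trial <- data.frame(social = sim$S[1, ], alcohol_units = sim$AU[1, ],
                        mood = sim$Y[1, ])
    r <- .try_fit_all(trial, grid, refit_penalty)
    if (r$ok) {
      g <- gcompute(r$fits$social, r$fits$alcohol, r$fits$mood, grid,
                    initial_state, n_reps = n_reps_inner,
                    seed = .sub_seed(sb, 1), coupled = coupled)
      est[b, ] <- g$estimate
    }
    diag_rows[[b]] <- data.frame(
      replicate = b, seed = sb, ok = r$ok, ridged = r$ridged,
      social_separation = if (r$ok) r$fits$social$separation else NA,
      alcohol_separation = if (r$ok) r$fits$alcohol$separation else NA,
      mood_missing_categories = if (r$ok) r$fits$mood$missing_categories else NA,
      error = if (is.null(r$error)) "" else r$error
    )
  }
  diagnostics <- do.call(rbind, diag_rows)
  ok <- !is.na(est[, 1])
  n_eff <- sum(ok)
  if (n_boot - n_eff > max_fail * n_boot)
    stop(sprintf("parametric bootstrap aborted: %d of %d replicates failed",
                 n_boot - n_eff, n_boot), call. = FALSE)
  boot <- est[ok, , drop = FALSE]
  se <- apply(boot, 2, stats::sd)
  point$se <- se
  point$ci_low <- point$estimate - z * se
  point$ci_high <- point$estimate + z * se
  attr(point, "boot_estimates") <- boot
  attr(point, "diagnostics") <- diagnostics
  attr(point, "n_effective") <- n_eff
  point
}
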