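## The top-level model-fitting interface: ucate() fits the three conditional
## models to an observed (or simulated) trial, runs the g-computation
## estimator and, optionally, the parametric bootstrap.

#' Estimate the individual-specific effect of abstinence on mood (U-CATE)
#'
#' Fits the three stationary conditional models (logistic social-interaction
#' model, zero-inflated Poisson alcohol model on non-intervention rows,
#' proportional-odds mood model) to a single-participant trial series, then
#' estimates the per-time-point U-CATE -- the difference in expected mood
#' between "always abstain" and "always drink as usual", conditional on the
#' individual and the fixed calendar -- by g-computation Monte Carlo.
#' With `boot = TRUE` a parametric bootstrap attaches standard errors and
#' normal-approximation 95% confidence intervals.
#'
#' @param data a `trial_series` (from [simulate_trial()] or
#'   [read_trial_csv()]).
#' @param grid the matching `measurement_grid` (default: series attribute).
#' @param n_reps Monte Carlo repetitions for the point estimates.
#' @param boot run the parametric bootstrap?
#' @param n_boot bootstrap replicates.
#' @param n_reps_inner g-computation repetitions inside each bootstrap
#'   replicate.
#' @param seed master seed; all stages derive deterministic sub-seeds from
#'   it, so identical calls give identical results.
#' @param coupled share random numbers across the two strategy arms of the
#'   g-computation (variance reduction; see [gcompute()]).
#' @param refit_penalty ridge strength for retried bootstrap refits.
#' @param allow_nonadherence accept positive alcohol counts during the
#'   intervention period instead of raising an error.
#' @return an object of class `ucate` with components `series` (the
#'   [gcompute()] output, bootstrap-filled when requested), `aggregates`
#'   (overall and by time of day), `models` (the three fits), `initial_state`,
#'   `grid`, and `call`. Methods: `print`, `summary`, `coef`, `confint`,
#'   `plot`, `simulate`, `aggregate`.
#' @export
#' @examples
#' cfg <- default_config(tamed = TRUE, seed = 7)
#' cfg$study_end <- as.Date("2024-01-20") # desk-scale example
#' trial <- simulate_trial(cfg)
#' fit <- ucate(trial, n_reps = 200, seed = 7)
#' fit
ucate <- function(data, grid = attr(data, "grid"), n_reps = 800,
                  boot = FALSE, n_boot = 500, n_reps_inner = 800,
                  seed = 1L, coupled = TRUE, refit_penalty = 0.01,
                  allow_nonadherence = FALSE) {
  if (is.null(grid)) stop("a measurement grid is required", call. = FALSE)
  validate_trial_series(data, grid, allow_nonadherence = allow_nonadherence)
  models <- .fit_all(data, grid)
  initial_state <- list(social = data$social[1],
                        alcohol = data$alcohol_units[1],
                        mood = data$mood[1])
  series <- gcompute(models$social, models$alcohol, models$mood, grid,
                     initial_state, n_reps = n_reps,
                     seed = .sub_seed(seed, 0), coupled = coupled)
  if (boot)
    series <- parametric_bootstrap(models$social, models$alcohol, models$mood,
                                   grid, initial_state, point = series,
                                   n_boot = n_boot,
                                   n_reps_inner = n_reps_inner, seed = seed,
                                   coupled = coupled,
                                   refit_penalty = refit_penalty)
  structure(list(series = series,
                 aggregates = list(
                   overall = ucate_aggregate(series, "overall"),
                   time_of_day = ucate_aggregate(series, "time_of_day")),
                 models = models, initial_state = initial_state, grid = grid,
                 n_reps = n_reps, boot = boot, seed = seed,
                 call = match.call()),
            class = "ucate")
}

#' @export
print.ucate <- function(x, digits = 3, ...) {
  cat("Individual-specific effect of abstinence on mood (U-CATE)\n")
  cat(sprintf("  %d time points, g-computation with %d repetitions%s\n",
              nrow(x$series), x$n_reps,
              if (x$boot) sprintf(", %d bootstrap replicates",
                                  attr(x$series, "n_effective")) else ""))
  agg <- rbind(x$aggregates$overall, x$aggregates$time_of_day)
  agg[c("estimate", "se", "ci_low", "ci_high")] <-
    round(agg[c("estimate", "se", "ci_low", "ci_high")], digits)
  print.data.frame(agg, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ucate <- function(object, ...) {
  structure(list(
    aggregates = rbind(object$aggregates$overall, object$aggregates$time_of_day),
    models = lapply(object$models, fit_summary_table),
    separation = vapply(object$models, function(f)
      isTRUE(f$separation), logical(1)),
    n_points = nrow(object$series), n_reps = object$n_reps,
    boot = object$boot,
    n_effective = attr(object$series, "n_effective")),
    class = "summary.ucate")
}

#' @export
print.summary.ucate <- function(x, digits = 3, ...) {
  cat("U-CATE aggregates (mood-scale difference, abstain minus drink):\n")
  agg <- x$aggregates
  agg[-1] <- lapply(agg[-1], round, digits)
  print.data.frame(agg, row.names = FALSE)
  cat("\nConditional model coefficients (95% normal-approximation CIs):\n")
  for (nm in names(x$models)) {
    cat("--", nm, if (x$separation[[nm]]) " [quasi-separation]", "\n")
    tb <- x$models[[nm]]
    tb[-1] <- lapply(tb[-1], round, digits)
    print.data.frame(tb, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.ucate <- function(object, ...) lapply(object$models, stats::coef)

#' @export
confint.ucate <- function(object, parm = c("aggregates", "series"),
                          level = 0.95, ...) {
  parm <- match.arg(parm)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (parm == "aggregates") {
    agg <- rbind(ucate_aggregate(object$series, "overall", z = z),
                 ucate_aggregate(object$series, "time_of_day", z = z))
    return(agg[c("stratum", "estimate", "ci_low", "ci_high")])
  }
  s <- object$series
  data.frame(t = s$t, estimate = s$estimate,
             ci_low = s$estimate - z * s$se, ci_high = s$estimate + z * s$se)
}

#' @export
plot.ucate <- function(x, ...) plot(x$series, ...)

#' @export
aggregate.ucate <- function(x, by = "overall", ...) {
  ucate_aggregate(x$series, by = by, ...)
}

#' Simulate trials from a fitted U-CATE model
#'
#' Draws complete synthetic trials from the three fitted conditional models
#' under a chosen treatment strategy, starting from the fixed first time
#' point of the original data.
#'
#' @param object a `ucate` fit.
#' @param nsim number of trials.
#' @param seed integer seed.
#' @param strategy `"observed-schedule"`, `"always-abstain"` or
#'   `"never-abstain"`.
#' @param ... ignored.
#' @return a list of `trial_series` (a single `trial_series` when
#'   `nsim = 1`).
#' @export
simulate.ucate <- function(object, nsim = 1, seed = 1L,
                           strategy = "observed-schedule", ...) {
  grid <- object$grid
  intervene <- .intervene_rule(grid, strategy)
  set.seed(seed)
  sims <- .sim_engine(object$models$social$params, object$models$alcohol$params,
                      object$models$mood$params, grid, object$initial_state,
                      nsim, intervene)
  out <- lapply(seq_len(nsim), function(r) {
    structure(data.frame(
      index = grid$index, timestamp = grid$timestamp,
      time_of_day = grid$time_of_day, non_working = grid$non_working,
      intervention = intervene, social = sims$S[r, ],
      alcohol_units = sims$AU[r, ], mood = sims$Y[r, ]),
      class = c("trial_series", "data.frame"), grid = grid)
  })
  if (nsim == 1) out[[1]] else out
}
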