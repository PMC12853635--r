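## G-computation Monte Carlo estimator of the per-time-point U-CATE and its
## aggregates.

#' G-computation Monte Carlo estimate of the U-CATE series
#'
#' For each of `n_reps` repetitions, one complete trial is simulated from the
#' three conditional models under the static strategy "always abstain"
#' (alcohol forced to zero, the alcohol model never consulted) and one under
#' "never abstain" (alcohol always drawn from the fitted model, including
#' calendar-abstinence times, as licensed by conditional stationarity). Both
#' start from the fixed first time point and share the fixed non-working-day
#' and time-of-day sequences. The per-time U-CATE estimate is the mean over
#' repetitions of the mood difference between the two arms, reported for
#' every time point after the first.
#'
#' By default the two arms share common random numbers (the same uniform
#' draws per repetition, time point and variable), which reduces Monte Carlo
#' variance without biasing the mean difference; `coupled = FALSE` simulates
#' the arms independently.
#'
#' @param social,alcohol,mood parameter objects or fitted model objects
#'   (`*_fit`), in which case their `$params` are used.
#' @param grid a `measurement_grid` (its intervention column is ignored; the
#'   strategies override it).
#' @param initial_state list with `social`, `alcohol`, `mood` at the first
#'   time point.
#' @param n_reps number of Monte Carlo repetitions (>= 1).
#' @param seed integer seed.
#' @param coupled share random numbers across the two strategy arms?
#' @return a `ucate_series`: data.frame with columns `t` (1-based offset from
#'   the fixed first point), `timestamp`, `time_of_day`, `estimate`, `mc_se`
#'   (Monte Carlo standard error, SD across repetitions / sqrt(n_reps));
#'   `se`, `ci_low`, `ci_high` are `NA` until filled by
#'   [parametric_bootstrap()]. Attribute `n_reps` records the repetition
#'   count.
#' @export
#' @seealso [ucate_aggregate()], [parametric_bootstrap()], [ucate()]
gcompute <- function(social, alcohol, mood, grid, initial_state,
                     n_reps = 800, seed = 1L, coupled = TRUE) {
  if (n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  social <- .as_params(social); alcohol <- .as_params(alcohol)
  mood <- .as_params(mood)
  Tn <- nrow(grid)
  set.seed(seed)
  u1 <- .draw_uniforms(n_reps, Tn)
  u2 <- if (coupled) u1 else .draw_uniforms(n_reps, Tn)
  abstain <- .sim_engine(social, alcohol, mood, grid, initial_state, n_reps,
                         intervene = rep(TRUE, Tn), u = u1)
  drink <- .sim_engine(social, alcohol, mood, grid, initial_state, n_reps,
                       intervene = rep(FALSE, Tn), u = u2)
  diff <- abstain$Y[, -1, drop = FALSE] - drink$Y[, -1, drop = FALSE]
  est <- colMeans(diff)
  mc_se <- apply(diff, 2, stats::sd) / sqrt(n_reps)
  out <- data.frame(
    t = seq_len(Tn - 1),
    timestamp = grid$timestamp[-1],
    time_of_day = grid$time_of_day[-1],
    estimate = est,
    mc_se = mc_se,
    se = NA_real_, ci_low = NA_real_, ci_high = NA_real_
  )
  structure(out, class = c("ucate_series", "data.frame"),
            n_reps = n_reps, seed = seed, coupled = coupled)
}

.as_params <- function(x) {
  if (inherits(x, c("social_fit", "alcohol_fit", "mood_fit"))) x$params else x
}

#' Aggregate a U-CATE series
#'
#' Arithmetic means of the per-time-point estimates, either over the whole
#' series or within each time-of-day stratum. When bootstrap replicate-level
#' estimates are attached (by [parametric_bootstrap()]), aggregate standard
#' errors and normal-approximation confidence intervals are computed from the
#' bootstrap distribution of the corresponding aggregate.
#'
#' @param series a `ucate_series`.
#' @param by `"overall"` or `"time_of_day"`.
#' @param z normal quantile for the confidence interval.
#' @return data.frame with columns `stratum`, `n`, `estimate`, `se`,
#'   `ci_low`, `ci_high` (the latter three `NA` without bootstrap
#'   information).
#' @export
ucate_aggregate <- function(series, by = c("overall", "time_of_day"),
                            z = stats::qnorm(0.975)) {
  by <- match.arg(by)
  groups <- if (by == "overall") list(overall = seq_len(nrow(series)))
            else split(seq_len(nrow(series)), series$time_of_day)
  if (any(lengths(groups) == 0))
    stop("empty time-of-day stratum in U-CATE series", call. = FALSE)
  boot <- attr(series, "boot_estimates") # n_boot x (T-1) or NULL
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    est <- mean(series$estimate[idx])
    if (!is.null(boot)) {
      agg_b <- rowMeans(boot[, idx, drop = FALSE])
      se <- stats::sd(agg_b)
      data.frame(stratum = g, n = length(idx), estimate = est, se = se,
                 ci_low = est - z * se, ci_high = est + z * se)
    } else {
      data.frame(stratum = g, n = length(idx), estimate = est,
                 se = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' @export
aggregate.ucate_series <- function(x, by = "overall", ...) {
  ucate_aggregate(x, by = by, ...)
}

#' @export
print.ucate_series <- function(x, ...) {
  cat(sprintf("U-CATE series: %d time points (g-computation, %d repetitions)\n",
              nrow(x), attr(x, "n_reps")))
  agg <- ucate_aggregate(x)
  if (is.na(agg$se)) {
    cat(sprintf("  overall mean: %.3f (no bootstrap SE attached)\n",
                agg$estimate))
  } else {
    cat(sprintf("  overall mean: %.3f (95%% CI %.3f, %.3f)\n",
                agg$estimate, agg$ci_low, agg$ci_high))
  }
  invisible(x)
}

#' Plot a U-CATE series
#'
#' Per-time-point estimates with vertical 95% confidence bars (when a
#' bootstrap has been run), against calendar time.
#'
#' @param x a `ucate_series`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ucate_series <- function(x, ...) {
  has_ci <- !all(is.na(x$ci_low))
  ylim <- if (has_ci) range(x$ci_low, x$ci_high, 0) else range(x$estimate, 0)
  graphics::plot(x$timestamp, x$estimate, pch = 16, cex = 0.5, ylim = ylim,
                 xlab = "time", ylab = "U-CATE (mood difference)", ...)
  if (has_ci)
    graphics::segments(x$timestamp, x$ci_low, x$timestamp, x$ci_high,
                       col = "grey60")
  graphics::points(x$timestamp, x$estimate, pch = 16, cex = 0.5)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
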