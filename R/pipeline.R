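## Trial CSV input/output with strict validation, descriptive statistics,
## configuration round-trips and the end-to-end pipeline driver.

TRIAL_COLUMNS <- c("index", "timestamp", "time_of_day", "non_working",
                   "intervention", "social", "alcohol_units", "mood")

#' Validate a trial series against its grid
#'
#' Checks completeness (no missing values anywhere; the original trial had
#' none and nothing is imputed), ranges (mood in -2..2, alcohol a
#' non-negative integer, social 0/1) and, unless `allow_nonadherence`,
#' perfect adherence: zero alcohol at every intervention time point.
#' Errors name the offending column and rows.
#'
#' @param series a `trial_series`-shaped data.frame.
#' @param grid matching `measurement_grid`.
#' @param allow_nonadherence tolerate positive alcohol under intervention.
#' @return `series`, invisibly.
#' @export
validate_trial_series <- function(series, grid = attr(series, "grid"),
                                  allow_nonadherence = FALSE) {
  need <- c("social", "alcohol_units", "mood")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("series is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(grid) && nrow(series) != nrow(grid))
    stop("series and grid lengths differ", call. = FALSE)
  bad_rows <- function(ok, what) {
    if (!all(ok))
      stop(what, " at row(s) ", paste(utils::head(which(!ok), 10), collapse = ", "),
           call. = FALSE)
  }
  for (col in need)
    bad_rows(!is.na(series[[col]]), paste0("missing value in '", col, "'"))
  bad_rows(series$social %in% c(0, 1), "social must be 0/1")
  bad_rows(series$alcohol_units >= 0 & series$alcohol_units == floor(series$alcohol_units),
           "alcohol_units must be a non-negative integer")
  bad_rows(series$mood >= -2 & series$mood <= 2 & series$mood == floor(series$mood),
           "mood must be an integer in -2..2")
  if (!allow_nonadherence && !is.null(grid))
    bad_rows(!(grid$intervention & series$alcohol_units > 0),
             "positive alcohol units during the intervention period")
  invisible(series)
}

#' Read / write the trial CSV schema
#'
#' Columns: `index`, `timestamp` (ISO-8601), `time_of_day` (`T00`/`T08`/
#' `T16`), `non_working` (0/1), `intervention` (0/1), `social` (0/1),
#' `alcohol_units` (integer), `mood` (integer -2..2). Reading reconstructs
#' the measurement grid from the calendar columns, verifies the fixed
#' 8-hour spacing and time-of-day coding, and applies
#' [validate_trial_series()]. Write-then-read round-trips to an identical
#' series.
#'
#' @param path file path.
#' @param allow_nonadherence passed to [validate_trial_series()].
#' @return `read_trial_csv`: a `trial_series` with the grid attached.
#'   `write_trial_csv`: `path`, invisibly.
#' @export
read_trial_csv <- function(path, allow_nonadherence = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(miss))
    stop("trial CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(raw$timestamp))
    stop("missing timestamp at row(s) ",
         paste(utils::head(which(is.na(raw$timestamp)), 10), collapse = ", "),
         call. = FALSE)
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts)) stop("unparseable timestamp", call. = FALSE)
  if (nrow(raw) > 1 && !all(diff(as.numeric(ts)) == 8 * 3600))
    stop("timestamps must be strictly increasing in exact 8-hour steps",
         call. = FALSE)
  hh <- format(ts, "%H")
  tod_expect <- c("00" = "T00", "08" = "T08", "16" = "T16")[hh]
  if (anyNA(tod_expect) || !all(raw$time_of_day == tod_expect))
    stop("time_of_day must match the clock time (00->T00, 08->T08, 16->T16)",
         call. = FALSE)
  grid <- structure(
    data.frame(index = raw$index, timestamp = ts,
               time_of_day = factor(raw$time_of_day,
                                    levels = c("T00", "T08", "T16")),
               non_working = as.logical(raw$non_working),
               intervention = as.logical(raw$intervention)),
    class = c("measurement_grid", "data.frame"),
    study_start = as.Date(ts[1], tz = "UTC"),
    study_end = as.Date(ts[length(ts)], tz = "UTC"))
  series <- structure(
    data.frame(index = raw$index, timestamp = ts,
               time_of_day = grid$time_of_day,
               non_working = grid$non_working,
               intervention = grid$intervention,
               social = as.integer(raw$social),
               alcohol_units = as.integer(raw$alcohol_units),
               mood = as.integer(raw$mood)),
    class = c("trial_series", "data.frame"), grid = grid)
  validate_trial_series(series, grid, allow_nonadherence = allow_nonadherence)
  series
}

#' @rdname read_trial_csv
#' @param series a `trial_series`.
#' @export
write_trial_csv <- function(series, path) {
  out <- data.frame(
    index = series$index,
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%S"),
    time_of_day = as.character(series$time_of_day),
    non_working = as.integer(series$non_working),
    intervention = as.integer(series$intervention),
    social = as.integer(series$social),
    alcohol_units = as.integer(series$alcohol_units),
    mood = as.integer(series$mood)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive statistics by intervention period
#'
#' Per period (non-intervention / intervention): number of time points,
#' count and percentage of non-working-day and social-interaction points,
#' mean (SD) of alcohol units and of mood. A single-point stratum reports an
#' SD of 0 and raises a degenerate-stratum flag.
#'
#' @param series a `trial_series`.
#' @param grid matching `measurement_grid`.
#' @return data.frame, one row per period, with a logical `degenerate`
#'   column.
#' @export
descriptives <- function(series, grid = attr(series, "grid")) {
  if (is.null(grid)) stop("a measurement grid is required", call. = FALSE)
  one <- function(idx, label) {
    n <- length(idx)
    sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
    data.frame(
      period = label, n = n,
      non_working_n = sum(grid$non_working[idx]),
      non_working_pct = 100 * mean(grid$non_working[idx]),
      social_n = sum(series$social[idx]),
      social_pct = 100 * mean(series$social[idx]),
      alcohol_mean = mean(series$alcohol_units[idx]),
      alcohol_sd = sd0(series$alcohol_units[idx]),
      mood_mean = mean(series$mood[idx]),
      mood_sd = sd0(series$mood[idx]),
      degenerate = n < 2
    )
  }
  rbind(one(which(!grid$intervention), "non-intervention"),
        one(which(grid$intervention), "intervention"))
}

## configuration --------------------------------------------------------------

#' Round-trip a generator configuration through YAML
#'
#' @param config a `generator_config`.
#' @param path file path.
#' @return `read_config` returns a `generator_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  lst <- list(
    study_start = format(config$study_start),
    study_end = format(config$study_end),
    abstinence_start = if (!is.null(config$abstinence_start))
      format(config$abstinence_start),
    abstinence_end = if (!is.null(config$abstinence_end))
      format(config$abstinence_end),
    extra_non_working_days = as.character(format(config$extra_non_working_days)),
    social = as.list(unclass(config$social)),
    alcohol = list(zero = as.list(config$alcohol$zero),
                   count = as.list(config$alcohol$count)),
    mood = list(cutpoints = config$mood$cutpoints,
                slopes = as.list(config$mood$slopes)),
    initial_state = config$initial_state,
    seed = config$seed,
    treatment = config$treatment
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg$study_start <- as.Date(lst$study_start)
  cfg$study_end <- as.Date(lst$study_end)
  cfg$abstinence_start <- if (!is.null(lst$abstinence_start))
    as.Date(lst$abstinence_start)
  cfg$abstinence_end <- if (!is.null(lst$abstinence_end))
    as.Date(lst$abstinence_end)
  cfg$extra_non_working_days <- as.Date(unlist(lst$extra_non_working_days))
  cfg$social <- do.call(social_params, lst$social)
  cfg$alcohol <- alcohol_params(zero = unlist(lst$alcohol$zero),
                                count = unlist(lst$alcohol$count))
  cfg$mood <- do.call(mood_params, c(list(cutpoints = unlist(lst$mood$cutpoints)),
                                     lst$mood$slopes))
  cfg$initial_state <- lst$initial_state
  cfg$seed <- as.integer(lst$seed)
  cfg$treatment <- lst$treatment
  cfg
}

## pipeline -------------------------------------------------------------------

#' Run the full analysis pipeline
#'
#' End-to-end driver: load (or simulate) a trial, validate it, compute
#' descriptives, fit the three conditional models, estimate the U-CATE
#' series by g-computation, optionally run the parametric bootstrap, and
#' write all artifacts -- descriptives, the three coefficient tables, the
#' U-CATE series and aggregates, bootstrap diagnostics, a figure, and a
#' machine-readable run manifest -- into `out_dir`. Runs with the same
#' configuration and seed produce identical numeric outputs.
#'
#' @param input a `trial_series`, a path to a trial CSV, or a
#'   `generator_config` (in which case the trial is simulated).
#' @param out_dir output directory (created if needed).
#' @param n_reps,boot,n_boot,n_reps_inner,seed,coupled,allow_nonadherence
#'   passed to [ucate()].
#' @param plot also write a figure of the U-CATE series (PNG)?
#' @return the `ucate` fit, invisibly; artifact paths in attribute `paths`.
#' @export
run_pipeline <- function(input, out_dir, n_reps = 800, boot = FALSE,
                         n_boot = 500, n_reps_inner = 800, seed = 1L,
                         coupled = TRUE, allow_nonadherence = FALSE,
                         plot = TRUE) {
  if (inherits(input, "generator_config")) {
    series <- simulate_trial(input)
  } else if (is.character(input)) {
    series <- read_trial_csv(input, allow_nonadherence = allow_nonadherence)
  } else {
    series <- input
  }
  grid <- attr(series, "grid")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  fit <- ucate(series, grid, n_reps = n_reps, boot = boot, n_boot = n_boot,
               n_reps_inner = n_reps_inner, seed = seed, coupled = coupled,
               allow_nonadherence = allow_nonadherence)

  utils::write.csv(descriptives(series, grid), p("descriptives.csv"),
                   row.names = FALSE)
  for (nm in names(fit$models))
    utils::write.csv(fit_summary_table(fit$models[[nm]]),
                     p(paste0("model_", nm, ".csv")), row.names = FALSE)
  s <- fit$series
  utils::write.csv(
    data.frame(t = s$t, timestamp = format(s$timestamp, "%Y-%m-%dT%H:%M:%S"),
               time_of_day = as.character(s$time_of_day),
               estimate = s$estimate, mc_se = s$mc_se, se = s$se,
               ci_low = s$ci_low, ci_high = s$ci_high),
    p("ucate.csv"), row.names = FALSE)
  utils::write.csv(rbind(fit$aggregates$overall, fit$aggregates$time_of_day),
                   p("aggregates.csv"), row.names = FALSE)
  if (boot)
    utils::write.csv(attr(s, "diagnostics"), p("bootstrap_diagnostics.csv"),
                     row.names = FALSE)
  if (plot) {
    grDevices::png(p("ucate.png"), width = 900, height = 450)
    plot(fit)
    grDevices::dev.off()
  }
  manifest <- list(
    package = "ucate",
    version = tryCatch(as.character(utils::packageVersion("ucate")),
                       error = function(e) "unknown"),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, n_reps = n_reps, boot = boot,
    n_boot = if (boot) n_boot, n_reps_inner = if (boot) n_reps_inner,
    n_points = nrow(series), intervention_points = sum(grid$intervention),
    input = if (is.character(input)) input else class(input)[1]
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  attr(fit, "paths") <- vapply(
    c("descriptives.csv", "model_social.csv", "model_alcohol.csv",
      "model_mood.csv", "ucate.csv", "aggregates.csv", "manifest.json"),
    p, character(1))
  invisible(fit)
}
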