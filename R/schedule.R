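## Trial calendar: measurement grid, time-of-day coding, non-working days,
## intervention attribution.

#' Berlin public holidays
#'
#' Public holidays for the federal state of Berlin, computed from the Gaussian
#' Easter algorithm plus the fixed-date holidays (including International
#' Women's Day, a Berlin holiday since 2019).
#'
#' @param years integer vector of calendar years.
#' @return a `Date` vector, sorted, one entry per holiday.
#' @export
#' @examples
#' berlin_holidays(2024)
berlin_holidays <- function(years) {
  easter <- function(y) {
    a <- y %% 19; b <- y %/% 100; c <- y %% 100
    d <- b %/% 4; e <- b %% 4; f <- (b + 8) %/% 25
    g <- (b - f + 1) %/% 3
    h <- (19 * a + b - d - g + 15) %% 30
    i <- c %/% 4; k <- c %% 4
    l <- (32 + 2 * e + 2 * i - h - k) %% 7
    m <- (a + 11 * h + 22 * l) %/% 451
    month <- (h + l - 7 * m + 114) %/% 31
    day <- ((h + l - 7 * m + 114) %% 31) + 1
    as.Date(sprintf("%04d-%02d-%02d", y, month, day))
  }
  out <- lapply(years, function(y) {
    es <- easter(y)
    fixed <- as.Date(sprintf(
      "%04d-%s", y, c("01-01", "05-01", "10-03", "12-25", "12-26")
    ))
    if (y >= 2019) fixed <- c(fixed, as.Date(sprintf("%04d-03-08", y)))
    c(fixed,
      es - 2,    # Good Friday
      es + 1,    # Easter Monday
      es + 39,   # Ascension
      es + 50)   # Whit Monday
  })
  sort(unique(do.call(c, out)))
}

#' Default non-working days for a study window
#'
#' All Saturdays and Sundays in `[study_start, study_end]`, plus Berlin public
#' holidays falling in the window, plus any explicitly supplied extra days
#' (vacation days).
#'
#' @param study_start,study_end `Date` (or coercible) bounds, inclusive.
#' @param extra_days optional `Date` vector of additional non-working days
#'   (e.g. vacation); days outside the window are ignored.
#' @return sorted `Date` vector.
#' @export
default_non_working_days <- function(study_start, study_end, extra_days = NULL) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (study_start > study_end)
    stop("study_start must not be after study_end", call. = FALSE)
  days <- seq(study_start, study_end, by = "day")
  wk <- days[format(days, "%u") %in% c("6", "7")]
  hol <- berlin_holidays(unique(as.integer(format(days, "%Y"))))
  hol <- hol[hol >= study_start & hol <= study_end]
  extra <- if (is.null(extra_days)) as.Date(character()) else as.Date(extra_days)
  extra <- extra[extra >= study_start & extra <= study_end]
  sort(unique(c(wk, hol, extra)))
}

#' Attribute a measurement time to the intervention period
#'
#' A measurement time belongs to the intervention (abstinence) period when the
#' 8 hours preceding it fall entirely inside the scheduled abstinence window,
#' i.e. when the interval `(t - 8h, t]` is contained in
#' `[abstinence_start 00:00, 00:00 of the day after abstinence_end]`.
#' Consequently the midnight point of the first abstinence day is *not*
#' attributed to the intervention (its recall window reaches into the previous
#' day) while the midnight point of the day after the last abstinence day
#' *is*.
#'
#' @param timestamp `POSIXct` measurement time(s) on the 8-hour grid.
#' @param abstinence_start,abstinence_end first and last calendar day of the
#'   abstinence period (`Date` or coercible); both `NULL` means no
#'   intervention at all.
#' @return logical vector, `TRUE` for intervention time points.
#' @export
#' @examples
#' attribute_intervention(as.POSIXct("2024-02-01 00:00", tz = "UTC"),
#'                        "2024-01-01", "2024-01-31")
attribute_intervention <- function(timestamp, abstinence_start, abstinence_end) {
  if (is.null(abstinence_start) || is.null(abstinence_end))
    return(rep(FALSE, length(timestamp)))
  w0 <- as.POSIXct(paste(as.Date(abstinence_start), "00:00:00"), tz = "UTC")
  w1 <- as.POSIXct(paste(as.Date(abstinence_end) + 1, "00:00:00"), tz = "UTC")
  t <- as.POSIXct(timestamp, tz = "UTC")
  (t - 8 * 3600) >= w0 & t <= w1
}

#' Build the fixed measurement grid of the trial
#'
#' One measurement point at 00:00, 08:00 and 16:00 of every calendar day from
#' `study_start` to `study_end` inclusive, with time-of-day labels, the fixed
#' non-working-day sequence, and intervention attribution via
#' [attribute_intervention()]. Timestamps are naive local times stored as UTC;
#' the 8-hour spacing is nominal clock spacing.
#'
#' @param study_start,study_end first and last day of data collection.
#' @param abstinence_start,abstinence_end abstinence window (both `NULL` for
#'   a trial without intervention); must lie within the study window.
#' @param non_working_days `Date` vector of non-working days; defaults to
#'   [default_non_working_days()] over the study window.
#' @return a `measurement_grid`: a `data.frame` with columns `index` (0-based),
#'   `timestamp` (`POSIXct`), `time_of_day` (factor `T00`/`T08`/`T16`),
#'   `non_working`, `intervention` (logical), and attributes `study_start`,
#'   `study_end`, `abstinence_start`, `abstinence_end`.
#' @export
#' @examples
#' g <- build_grid("2023-12-06", "2024-03-02", "2024-01-01", "2024-01-31")
#' nrow(g)                 # 264
#' table(g$intervention)   # 171 FALSE, 93 TRUE
build_grid <- function(study_start, study_end,
                       abstinence_start = NULL, abstinence_end = NULL,
                       non_working_days = NULL) {
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (study_start > study_end)
    stop("invalid study window: study_start is after study_end", call. = FALSE)
  if (!is.null(abstinence_start) || !is.null(abstinence_end)) {
    if (is.null(abstinence_start) || is.null(abstinence_end))
      stop("abstinence_start and abstinence_end must be supplied together",
           call. = FALSE)
    abstinence_start <- as.Date(abstinence_start)
    abstinence_end <- as.Date(abstinence_end)
    if (abstinence_start > abstinence_end)
      stop("invalid abstinence window: abstinence_start is after abstinence_end",
           call. = FALSE)
    if (abstinence_start < study_start || abstinence_end > study_end)
      stop("abstinence window must lie within the study window", call. = FALSE)
  }
  if (is.null(non_working_days))
    non_working_days <- default_non_working_days(study_start, study_end)
  non_working_days <- as.Date(non_working_days)

  days <- seq(study_start, study_end, by = "day")
  hours <- c(0L, 8L, 16L)
  ts <- as.POSIXct(paste(rep(days, each = 3), sprintf("%02d:00:00", hours)),
                   tz = "UTC")
  tod <- factor(rep(c("T00", "T08", "T16"), length(days)),
                levels = c("T00", "T08", "T16"))
  grid <- data.frame(
    index = seq_along(ts) - 1L,
    timestamp = ts,
    time_of_day = tod,
    non_working = as.Date(ts, tz = "UTC") %in% non_working_days,
    intervention = attribute_intervention(ts, abstinence_start, abstinence_end)
  )
  structure(grid,
            class = c("measurement_grid", "data.frame"),
            study_start = study_start, study_end = study_end,
            abstinence_start = abstinence_start, abstinence_end = abstinence_end)
}

#' @export
print.measurement_grid <- function(x, ...) {
  cat(sprintf(
    "Measurement grid: %d points, %s .. %s (3 per day)\n",
    nrow(x), format(attr(x, "study_start")), format(attr(x, "study_end"))))
  if (!is.null(attr(x, "abstinence_start")))
    cat(sprintf("  abstinence: %s .. %s  (%d intervention points)\n",
                format(attr(x, "abstinence_start")),
                format(attr(x, "abstinence_end")), sum(x$intervention)))
  cat(sprintf("  non-working points: %d (%.1f%%)\n",
              sum(x$non_working), 100 * mean(x$non_working)))
  invisible(x)
}

#' Write / read a measurement grid as CSV
#'
#' Columns: `index`, `timestamp` (ISO-8601), `time_of_day`, `non_working`
#' (0/1), `intervention` (0/1).
#'
#' @param grid a `measurement_grid`.
#' @param path file path.
#' @return `write_grid_csv` returns `path` invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  out <- data.frame(
    index = grid$index,
    timestamp = format(grid$timestamp, "%Y-%m-%dT%H:%M:%S"),
    time_of_day = as.character(grid$time_of_day),
    non_working = as.integer(grid$non_working),
    intervention = as.integer(grid$intervention)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
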