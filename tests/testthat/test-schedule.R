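# The fixed trial calendar: grid construction, intervention attribution,
# non-working days.

test_that("the trial-period grid reproduces the design counts", {
  g <- build_grid("2023-12-06", "2024-03-02", "2024-01-01", "2024-01-31")
  expect_s3_class(g, "measurement_grid")
  expect_equal(nrow(g), 264)
  expect_equal(sum(!g$intervention), 171)
  expect_equal(sum(g$intervention), 93)
  expect_equal(100 * mean(g$intervention), 35.2, tolerance = 0.05)
  # consecutive points exactly 8 hours apart, strictly increasing
  expect_true(all(diff(as.numeric(g$timestamp)) == 8 * 3600))
  # time-of-day determined by the clock
  expect_equal(as.character(g$time_of_day),
               c("00" = "T00", "08" = "T08", "16" = "T16")[format(g$timestamp, "%H")],
               ignore_attr = TRUE)
})

test_that("grid size is three points per calendar day", {
  for (len in c(1, 2, 10, 88)) {
    g <- build_grid("2024-02-01", as.Date("2024-02-01") + len - 1)
    expect_equal(nrow(g), 3 * len)
    expect_false(any(g$intervention))
  }
})

test_that("intervention attribution follows the 8-hour recall rule", {
  ts <- function(x) as.POSIXct(x, tz = "UTC")
  # the midnight point of the first abstinence day reaches back into December
  expect_false(attribute_intervention(ts("2024-01-01 00:00:00"),
                                      "2024-01-01", "2024-01-31"))
  # the midnight point of February 1 covers the last January evening
  expect_true(attribute_intervention(ts("2024-02-01 00:00:00"),
                                     "2024-01-01", "2024-01-31"))
  expect_true(attribute_intervention(ts("2024-01-15 08:00:00"),
                                     "2024-01-01", "2024-01-31"))
  # a full-month window marks exactly one contiguous block of 3 x 31 points
  g <- build_grid("2023-12-06", "2024-03-02", "2024-01-01", "2024-01-31")
  r <- rle(g$intervention)
  expect_equal(r$values, c(FALSE, TRUE, FALSE))
  expect_equal(r$lengths[2], 3 * 31)
})

test_that("reversed or inconsistent date ranges are rejected by name", {
  expect_error(build_grid("2024-02-01", "2024-01-01"), "study_start")
  expect_error(build_grid("2024-01-01", "2024-03-01", "2024-02-10", "2024-02-01"),
               "abstinence_start")
  expect_error(build_grid("2024-01-01", "2024-01-31", "2024-01-20", "2024-02-05"),
               "within the study window")
  expect_error(default_non_working_days("2024-02-01", "2024-01-01"),
               "study_start")
})

test_that("default non-working days are weekends, holidays and extras", {
  nw <- default_non_working_days("2024-01-01", "2024-01-31")
  expect_true(as.Date("2024-01-06") %in% nw) # Saturday
  expect_true(as.Date("2024-01-07") %in% nw) # Sunday
  expect_true(as.Date("2024-01-01") %in% nw) # New Year public holiday
  expect_false(as.Date("2024-01-03") %in% nw) # ordinary Wednesday
  nw2 <- default_non_working_days("2024-01-01", "2024-01-31",
                                  extra_days = "2024-01-03")
  expect_true(as.Date("2024-01-03") %in% nw2)
  # Berlin keeps International Women's Day and Easter-derived holidays
  expect_true(as.Date("2024-03-08") %in% berlin_holidays(2024))
  expect_true(as.Date("2024-03-29") %in% berlin_holidays(2024)) # Good Friday
})

test_that("the default vacation calendar reproduces the reported non-working fractions", {
  cfg <- default_config()
  g <- config_grid(cfg)
  expect_equal(sum(g$non_working & !g$intervention), 73) # 42.7% of 171
  expect_equal(sum(g$non_working & g$intervention), 29)  # 31.2% of 93
})

test_that("grids serialize to the documented CSV schema", {
  g <- build_grid("2024-01-01", "2024-01-03", "2024-01-02", "2024-01-02")
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(g, path)
  back <- read.csv(path)
  expect_equal(names(back), c("index", "timestamp", "time_of_day",
                              "non_working", "intervention"))
  expect_equal(nrow(back), 9)
  expect_equal(back$intervention, as.integer(g$intervention))
  expect_match(back$timestamp[1], "^2024-01-01T00:00:00$")
})
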