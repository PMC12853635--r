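# G-computation estimator: oracle agreement, null invariance, aggregation,
# Monte Carlo behavior.

test_that("gcompute matches exact enumeration on a tiny grid", {
  g <- build_grid("2024-04-03", "2024-04-03") # 3 points
  init <- list(social = 0L, alcohol = 1L, mood = 0L)
  truth <- enumerate_ucate(tame_social(), tame_alcohol(), tame_mood(), g, init)
  res <- gcompute(tame_social(), tame_alcohol(), tame_mood(), g, init,
                  n_reps = 2e4, seed = 101)
  expect_equal(length(res$estimate), 2)
  expect_true(all(abs(res$estimate - truth) <= 3 * res$mc_se))
  # and with independent (uncoupled) arms
  res2 <- gcompute(tame_social(), tame_alcohol(), tame_mood(), g, init,
                   n_reps = 2e4, seed = 102, coupled = FALSE)
  expect_true(all(abs(res2$estimate - truth) <= 3 * res2$mc_se))
})

null_params <- function() {
  # remove every alcohol pathway into mood and social: the counterfactual
  # arms then differ only in a variable that influences nothing downstream
  social <- tame_social(); social["b_alcohol_prev"] <- 0
  mood <- tame_mood()
  mood$slopes[c("b_alcohol_now", "b_alcohol_prev")] <- 0
  list(social = social, mood = mood)
}

test_that("zeroed alcohol pathways give exactly null U-CATE under coupling", {
  np <- null_params()
  g <- build_grid("2024-04-01", "2024-04-20")
  init <- list(social = 0L, alcohol = 0L, mood = 0L)
  res <- gcompute(np$social, tame_alcohol(), np$mood, g, init,
                  n_reps = 300, seed = 8)
  expect_true(all(res$estimate == 0))
  expect_true(all(res$mc_se == 0))
})

test_that("aggregates are arithmetic means of the per-time estimates", {
  g <- build_grid("2024-04-01", "2024-04-10")
  init <- list(social = 0L, alcohol = 0L, mood = 0L)
  res <- gcompute(tame_social(), tame_alcohol(), tame_mood(), g, init,
                  n_reps = 200, seed = 12)
  agg <- ucate_aggregate(res, "overall")
  expect_equal(agg$estimate, mean(res$estimate))
  tod <- ucate_aggregate(res, "time_of_day")
  expect_equal(nrow(tod), 3)
  for (lv in tod$stratum)
    expect_equal(tod$estimate[tod$stratum == lv],
                 mean(res$estimate[res$time_of_day == lv]))
  # the overall mean is the stratum-size-weighted mean of the three strata
  expect_equal(agg$estimate, sum(tod$estimate * tod$n) / sum(tod$n))
  # a constant series aggregates to that constant
  res_c <- res; res_c$estimate <- 0.37
  expect_equal(ucate_aggregate(res_c, "overall")$estimate, 0.37)
  # an empty stratum is an error
  res_t00 <- res[res$time_of_day == "T00", ]
  attr(res_t00, "n_reps") <- 200
  expect_error(ucate_aggregate(res_t00, "time_of_day"), "empty")
})

test_that("Monte Carlo error shrinks as one over the square root of reps", {
  g <- build_grid("2024-04-01", "2024-04-03")
  init <- list(social = 0L, alcohol = 0L, mood = 0L)
  overall <- function(n_reps, seed)
    mean(gcompute(tame_social(), tame_alcohol(), tame_mood(), g, init,
                  n_reps = n_reps, seed = seed)$estimate)
  lo <- vapply(1:30, function(s) overall(200, 1000 + s), numeric(1))
  hi <- vapply(1:30, function(s) overall(3200, 2000 + s), numeric(1))
  ratio <- sd(lo) / sd(hi)
  expect_gt(ratio, 2.3) # expected 4 = sqrt(3200/200)
  expect_lt(ratio, 7.0)
})

test_that("a harmful lagged-alcohol effect yields positive abstinence benefit", {
  mood <- tame_mood()
  mood$slopes["b_alcohol_prev"] <- -2
  g <- build_grid("2024-04-01", "2024-04-14")
  init <- list(social = 0L, alcohol = 2L, mood = 0L)
  res <- gcompute(tame_social(), tame_alcohol(), mood, g, init,
                  n_reps = 500, seed = 44)
  agg <- ucate_aggregate(res, "overall")
  expect_gt(agg$estimate, 0.2)
  # estimates stay inside the logical range of a difference of moods
  expect_true(all(res$estimate >= -4 & res$estimate <= 4))
})

test_that("invalid repetition counts are rejected", {
  g <- build_grid("2024-04-01", "2024-04-02")
  expect_error(gcompute(tame_social(), tame_alcohol(), tame_mood(), g,
                        list(social = 0, alcohol = 0, mood = 0), n_reps = 0),
               "n_reps")
})
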