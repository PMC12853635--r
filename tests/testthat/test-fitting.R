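# Maximum-likelihood fitters: parameter recovery, degeneracies, equivalences.

sim_long <- function(n_days, seed = 1, tamed = TRUE) {
  simulate_trial(long_config(n_days, seed = seed, tamed = tamed))
}

test_that("fitters recover tame generating parameters at moderate length", {
  cfg <- make_config(start = "2020-01-01", end = "2021-10-27", seed = 21) # 666 days
  tr <- simulate_trial(cfg)
  expect_equal(nrow(tr), 1998)
  fs <- fit_social(tr)
  fa <- fit_alcohol(tr)
  fm <- fit_mood(tr)
  expect_true(all(abs(fs$coef - as.numeric(cfg$social)) <= 3.5 * fs$se))
  expect_true(all(abs(fa$coef - c(cfg$alcohol$zero, cfg$alcohol$count)) <=
                    3.5 * fa$se))
  expect_true(all(abs(fm$coef - cfg$mood$slopes) <= 3.5 * fm$se))
  expect_equal(fm$cutpoints, cfg$mood$cutpoints, tolerance = 0.25,
               ignore_attr = TRUE)
  expect_false(fs$separation)
  expect_true(all(vapply(list(fs, fa, fm), function(f) f$converged,
                         logical(1))))
})

test_that("fitted log-likelihood dominates the generating parameters", {
  cfg <- calib_config(seed = 5)
  tr <- simulate_trial(cfg)
  mf <- model_frame(tr)
  fs <- fit_social(tr); fa <- fit_alcohol(tr); fm <- suppressWarnings(fit_mood(tr))
  expect_gte(fs$loglik, social_loglik(cfg$social, mf) - 1e-6)
  expect_gte(fa$loglik, alcohol_loglik(cfg$alcohol, mf) - 1e-4)
  expect_gte(fm$loglik, mood_loglik(cfg$mood, mf) - 1e-4)
})

test_that("a constant social outcome raises the separation flag", {
  g <- build_grid("2024-04-01", "2024-04-20")
  set.seed(3)
  tr <- make_series(g, social = rep(0L, nrow(g)),
                    alcohol = rpois(nrow(g), 1),
                    mood = sample(-2:2, nrow(g), replace = TRUE))
  fs <- suppressWarnings(fit_social(tr, g))
  expect_true(fs$separation)
})

test_that("the zero-inflated fit agrees with glmmTMB on a fixture", {
  library(glmmTMB)
  tr <- sim_long(240, seed = 13)
  fa <- fit_alcohol(tr)
  mf <- model_frame(tr)
  tmb <- glmmTMB(
    alcohol_units ~ mood_prev + non_working + t08 + t16 + social_now,
    ziformula = ~ mood_prev + non_working + t08 + t16 + social_now,
    family = poisson, data = mf)
  expect_equal(unname(fa$params$count), unname(fixef(tmb)$cond),
               tolerance = 1e-4)
  expect_equal(unname(fa$params$zero), unname(fixef(tmb)$zi),
               tolerance = 1e-3)
  expect_equal(fa$loglik, as.numeric(logLik(tmb)), tolerance = 1e-6)
})

test_that("without structural zeros the count component matches plain Poisson", {
  prm <- tame_alcohol()
  prm$zero[] <- c(-30, 0, 0, 0, 0, 0) # never in the structural-zero state
  cfg <- make_config(alcohol = prm, start = "2020-01-01", end = "2021-10-27",
                     seed = 31)
  tr <- simulate_trial(cfg)
  fa <- fit_alcohol(tr)
  mf <- model_frame(tr)
  pois <- glm(alcohol_units ~ mood_prev + non_working + t08 + t16 + social_now,
              family = poisson, data = mf)
  expect_equal(unname(fa$params$count), unname(coef(pois)), tolerance = 0.02)
})

test_that("intervention rows are excluded from the alcohol fit", {
  cfg <- calib_config(seed = 9)
  tr <- simulate_trial(cfg)
  grid <- attr(tr, "grid")
  fa <- fit_alcohol(tr, grid)
  mf <- model_frame(tr, grid)
  mf_sub <- mf[!mf$intervention, , drop = FALSE]
  fa_sub <- fit_alcohol(tr, grid, mf = mf_sub)
  expect_equal(fa$coef, fa_sub$coef, tolerance = 1e-10)
  expect_equal(fa$nobs, sum(!mf$intervention))
})

test_that("two observed mood categories collapse to a logistic regression", {
  prm <- mood_params(cutpoints = rep(0.4, 4), b_alcohol_prev = -0.3,
                     b_mood_prev = 0.2, b_non_working = 0.5, b_social = 0.6)
  cfg <- make_config(mood = prm, start = "2023-01-01", end = "2023-06-30",
                     seed = 17)
  tr <- simulate_trial(cfg)
  expect_equal(sort(unique(tr$mood[-1])), c(-2L, 2L)) # index 0 is the fixed start
  fm <- fit_mood(tr)
  expect_true(fm$missing_categories)
  # interior probabilities vanish: the four cutpoints collapse to one value
  expect_equal(fm$cutpoints[1], fm$cutpoints[4], tolerance = 1e-6)
  mf <- model_frame(tr)
  lg <- glm(I(mood == 2) ~ alcohol_now + alcohol_prev + mood_prev +
              non_working + t08 + t16 + social_now, binomial, data = mf)
  expect_equal(unname(fm$params$slopes), unname(coef(lg)[-1]),
               tolerance = 1e-6)
})

test_that("null-slope mood data recovers cutpoints at empirical cumulative logits", {
  prm <- mood_params(cutpoints = qlogis(c(0.9, 0.65, 0.35, 0.1)))
  cfg <- make_config(mood = prm, start = "2022-01-01", end = "2022-12-31",
                     seed = 23)
  tr <- simulate_trial(cfg)
  fm <- fit_mood(tr)
  expect_true(all(abs(fm$params$slopes) <= 3.5 * fm$se))
  emp <- rev(cumsum(rev(table(factor(tr$mood[-1], levels = -2:2)))))[-1] /
    (nrow(tr) - 1)
  expect_equal(unname(fm$cutpoints), unname(qlogis(emp)), tolerance = 0.05)
})

test_that("fewer than two observed mood categories is an error", {
  g <- build_grid("2024-04-01", "2024-04-10")
  tr <- make_series(g, social = rep(0L, nrow(g)), alcohol = rep(0L, nrow(g)),
                    mood = rep(1L, nrow(g)))
  expect_error(fit_mood(tr, g), "fewer than 2")
  tr2 <- make_series(g, social = rep(0L, nrow(g)), alcohol = rep(0L, nrow(g)),
                     mood = rep(c(-2L, 2L), length.out = nrow(g)))
  expect_error(fit_alcohol(tr2, g), "all non-intervention alcohol counts")
})

test_that("ridge-penalized fits shrink toward zero but track the MLE", {
  cfg <- make_config(start = "2021-01-01", end = "2021-12-31", seed = 29)
  tr <- simulate_trial(cfg)
  fs0 <- fit_social(tr); fs1 <- fit_social(tr, ridge = 0.5)
  expect_true(fs1$converged)
  expect_lt(sum(fs1$coef[-1]^2), sum(fs0$coef[-1]^2))
  expect_equal(unname(fs1$coef), unname(fs0$coef), tolerance = 0.25)
  fm0 <- fit_mood(tr); fm1 <- fit_mood(tr, ridge = 0.5)
  expect_true(fm1$converged)
  expect_lt(sum(fm1$coef^2), sum(fm0$coef^2) + 1e-9)
  expect_equal(unname(fm1$coef), unname(fm0$coef), tolerance = 0.3)
})
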