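# Probability functions of the three conditional models and their samplers.

x_row <- function(alcohol_prev = 0, mood_prev = 0, non_working = 0,
                  t08 = 0, t16 = 0, social_now = 0, alcohol_now = 0) {
  list(alcohol_prev = alcohol_prev, mood_prev = mood_prev,
       non_working = non_working, t08 = t08, t16 = t16,
       social_now = social_now, alcohol_now = alcohol_now)
}

test_that("social_prob is the expit of its linear predictor", {
  expect_equal(social_prob(social_params(intercept = 1.3), x_row()),
               plogis(1.3))
  p <- social_prob(social_params(b_non_working = 1.49), x_row(non_working = 1))
  expect_equal(p, 0.8160, tolerance = 1e-4)
  expect_equal(social_prob(social_params(), x_row(alcohol_prev = 5,
                                                  mood_prev = -2)), 0.5)
  # huge predictors stay inside (0, 1) after clipping
  expect_lt(social_prob(social_params(intercept = 0, b_alcohol_prev = 100),
                        x_row(alcohol_prev = 50)), 1)
})

test_that("zip_pmf is the stated mixture of a point mass and a Poisson", {
  p1 <- alcohol_params(zero = c(intercept = 50, mood_prev = 0, non_working = 0,
                                t08 = 0, t16 = 0, social = 0))
  expect_equal(zip_pmf(p1, x_row(), 0), 1, tolerance = 1e-10)
  p2 <- alcohol_params(zero = c(intercept = -50, mood_prev = 0, non_working = 0,
                                t08 = 0, t16 = 0, social = 0),
                       count = c(intercept = 0, mood_prev = 0, non_working = 0,
                                 t08 = 0, t16 = 0, social = 0))
  expect_equal(zip_pmf(p2, x_row(), 0), exp(-1), tolerance = 1e-10)
  p3 <- alcohol_params(zero = c(intercept = 0, mood_prev = 0, non_working = 0,
                                t08 = 0, t16 = 0, social = 0),
                       count = c(intercept = log(2), mood_prev = 0,
                                 non_working = 0, t08 = 0, t16 = 0, social = 0))
  expect_equal(zip_pmf(p3, x_row(), 0), 0.5 + 0.5 * exp(-2), tolerance = 1e-10)
  expect_error(zip_pmf(p3, x_row(), -1), "non-negative")
})

test_that("zip_pmf sums to one over the effective support", {
  set.seed(41)
  for (i in 1:20) {
    prm <- alcohol_params(zero = c(intercept = rnorm(1), mood_prev = rnorm(1, 0, 0.3),
                                   non_working = rnorm(1), t08 = rnorm(1),
                                   t16 = rnorm(1), social = rnorm(1)),
                          count = c(intercept = rnorm(1, 0, 0.8), mood_prev = rnorm(1, 0, 0.2),
                                    non_working = rnorm(1, 0, 0.5), t08 = rnorm(1, 0, 0.5),
                                    t16 = rnorm(1, 0, 0.5), social = rnorm(1, 0, 0.5)))
    x <- x_row(mood_prev = sample(-2:2, 1), non_working = rbinom(1, 1, 0.5),
               social_now = rbinom(1, 1, 0.5))
    lam <- exp(sum(unlist(prm$count) * c(1, x$mood_prev, x$non_working,
                                         x$t08, x$t16, x$social_now)))
    K <- ceiling(lam + 12 * sqrt(lam) + 30)
    expect_lt(abs(1 - sum(zip_pmf(prm, x, 0:K))), 1e-8)
  }
})

test_that("mood_probs forms a simplex with the stated cumulative structure", {
  # equal-probability construction
  prm <- mood_params(cutpoints = qlogis(c(0.8, 0.6, 0.4, 0.2)))
  expect_equal(as.numeric(mood_probs(prm, x_row())), rep(0.2, 5),
               tolerance = 1e-12)
  # direct expit arithmetic
  prm2 <- mood_params(cutpoints = c(2, 0, -1, -3))
  expect_equal(as.numeric(mood_probs(prm2, x_row())),
               c(1 - plogis(2), plogis(2) - plogis(0), plogis(0) - plogis(-1),
                 plogis(-1) - plogis(-3), plogis(-3)), tolerance = 1e-12)
  # a strongly positive predictor pushes all mass to +2
  prm3 <- mood_params(cutpoints = c(2, 0, -1, -3), b_social = 40)
  p3 <- mood_probs(prm3, x_row(social_now = 1))
  expect_gt(p3[1, "2"], 1 - 1e-10)
  # random rows: non-negative, sum to 1, monotone in the linear predictor
  set.seed(7)
  for (i in 1:20) {
    cuts <- sort(rnorm(4, 0, 2), decreasing = TRUE)
    prm_i <- mood_params(cutpoints = cuts, b_alcohol_now = 0.2,
                         b_mood_prev = 0.5, b_social = 0.8)
    x_lo <- x_row(mood_prev = -2)
    x_hi <- x_row(mood_prev = 2, social_now = 1, alcohol_now = 2)
    p_lo <- mood_probs(prm_i, x_lo); p_hi <- mood_probs(prm_i, x_hi)
    expect_true(all(p_lo >= 0))
    expect_equal(sum(p_lo), 1, tolerance = 1e-12)
    # raising the predictor raises every P(Y >= j)
    expect_true(all(rev(cumsum(rev(p_hi[1, ])))[-1] >=
                      rev(cumsum(rev(p_lo[1, ])))[-1] - 1e-12))
  }
})

test_that("parameter constructors validate their invariants", {
  expect_error(mood_params(cutpoints = c(-1, 0, 1, 2)), "non-increasing")
  expect_error(mood_params(cutpoints = c(1, 0, -1)), "4 numeric")
  expect_error(social_params(intercept = Inf), "finite")
  expect_error(alcohol_params(zero = c(intercept = 1)), "complete")
})

test_that("samplers draw from the stated conditionals", {
  set.seed(11)
  prm <- tame_alcohol()
  # abstinence forces zero regardless of the model
  expect_true(all(sample_alcohol(prm, x_row(social_now = 1),
                                 intervention = TRUE, n = 200) == 0))
  # degenerate mood: all mass at +2
  prm_m <- mood_params(cutpoints = c(2, 0, -1, -3), b_social = 40)
  expect_true(all(sample_mood(prm_m, x_row(social_now = 1), n = 100) == 2L))
  # empirical frequencies match the closed-form pmf within 3 binomial SEs
  prm_m2 <- tame_mood()
  x <- x_row(mood_prev = 1, non_working = 1, social_now = 1)
  n <- 1e5
  draws <- sample_mood(prm_m2, x, n = n)
  p <- as.numeric(mood_probs(prm_m2, x))
  freq <- as.numeric(table(factor(draws, levels = -2:2))) / n
  expect_true(all(abs(freq - p) <= 3 * sqrt(p * (1 - p) / n) + 1e-12))
  # social draws match social_prob
  ps <- social_prob(tame_social(), x_row(non_working = 1))
  s_draws <- sample_social(tame_social(), x_row(non_working = 1), n = n)
  expect_lt(abs(mean(s_draws) - ps), 3 * sqrt(ps * (1 - ps) / n))
})
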