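# Shared fixtures: a well-behaved ("tame") parameter set for fast unit tests,
# a small-trial configuration for the bootstrap-calibration experiment, and
# constructors for hand-built grids and series.

tame_social <- function() {
  social_params(intercept = -0.8, b_alcohol_prev = 0.1, b_mood_prev = 0.2,
                b_non_working = 0.8, b_t08 = -0.5, b_t16 = -0.3)
}

tame_alcohol <- function() {
  alcohol_params(
    zero = c(intercept = -0.5, mood_prev = 0, non_working = -0.5,
             t08 = 0.5, t16 = 0.3, social = -1),
    count = c(intercept = 0.3, mood_prev = 0, non_working = 0.3,
              t08 = -0.3, t16 = -0.2, social = 0.5))
}

tame_mood <- function() {
  mood_params(cutpoints = c(2.5, 1.2, -1.2, -2.5),
              b_alcohol_now = 0.05, b_alcohol_prev = -0.3, b_mood_prev = 0.3,
              b_non_working = 0.5, b_t08 = -0.3, b_t16 = -0.2, b_social = 0.5)
}

# generator configuration from explicit parts; defaults give a short trial
# without intervention
make_config <- function(social = tame_social(), alcohol = tame_alcohol(),
                        mood = tame_mood(),
                        start = "2024-04-01", end = "2024-04-20",
                        abst_start = NULL, abst_end = NULL,
                        seed = 1L, treatment = "observed-schedule",
                        extra_nw = character()) {
  cfg <- default_config(seed = seed, treatment = treatment)
  cfg$study_start <- as.Date(start)
  cfg$study_end <- as.Date(end)
  cfg$abstinence_start <- if (!is.null(abst_start)) as.Date(abst_start)
  cfg$abstinence_end <- if (!is.null(abst_end)) as.Date(abst_end)
  cfg$extra_non_working_days <- as.Date(extra_nw)
  cfg$social <- social
  cfg$alcohol <- alcohol
  cfg$mood <- mood
  cfg
}

# the fixed configuration of the bootstrap-calibration experiment: a 20-day
# trial (60 points) with a 4-day abstinence block and tame coefficients
calib_config <- function(seed = 1L) {
  make_config(start = "2024-04-01", end = "2024-04-20",
              abst_start = "2024-04-09", abst_end = "2024-04-12", seed = seed)
}

# a long non-intervention calendar for parameter-recovery experiments
long_config <- function(n_days, seed = 1L, tamed = TRUE) {
  cfg <- default_config(tamed = tamed, seed = seed,
                        treatment = "never-abstain")
  cfg$study_start <- as.Date("2023-12-06")
  cfg$study_end <- cfg$study_start + n_days - 1
  cfg$abstinence_start <- cfg$abstinence_end <- NULL
  cfg$extra_non_working_days <- as.Date(character())
  cfg
}

# hand-built trial series on a given grid
make_series <- function(grid, social, alcohol, mood) {
  structure(data.frame(index = grid$index, timestamp = grid$timestamp,
                       time_of_day = grid$time_of_day,
                       non_working = grid$non_working,
                       intervention = grid$intervention,
                       social = social, alcohol_units = alcohol, mood = mood),
            class = c("trial_series", "data.frame"), grid = grid)
}

# exact counterfactual mood expectations on a tiny grid by dynamic
# programming over the joint state (S, AU, Y), enumerating alcohol support
# 0..k_max; written against plain plogis/dpois arithmetic, independent of the
# package's samplers
enumerate_ucate <- function(social, alcohol, mood, grid, init, k_max = 30) {
  expit <- stats::plogis
  nw <- as.numeric(grid$non_working)
  t08 <- as.numeric(grid$time_of_day == "T08")
  t16 <- as.numeric(grid$time_of_day == "T16")
  sp <- unclass(social); zo <- alcohol$zero; co <- alcohol$count
  ms <- mood$slopes; cuts <- mood$cutpoints

  mood_vec <- function(eta) {
    pge <- sapply(cuts, function(a) expit(a + eta))
    c(1 - pge[1], pge[1] - pge[2], pge[2] - pge[3], pge[3] - pge[4], pge[4])
  }
  one_arm <- function(abstain) {
    # state distribution over (s, au, y)
    states <- expand.grid(s = 0:1, au = 0:k_max, y = -2:2)
    prob <- as.numeric(states$s == init$social & states$au == init$alcohol &
                         states$y == init$mood)
    ey <- numeric(nrow(grid) - 1)
    for (t in 2:nrow(grid)) {
      newp <- numeric(nrow(states))
      for (i in which(prob > 0)) {
        ap <- states$au[i]; mp <- states$y[i]
        ps <- expit(sp[["intercept"]] + sp[["b_alcohol_prev"]] * ap +
                      sp[["b_mood_prev"]] * mp + sp[["b_non_working"]] * nw[t] +
                      sp[["b_t08"]] * t08[t] + sp[["b_t16"]] * t16[t])
        for (s in 0:1) {
          p_s <- if (s == 1) ps else 1 - ps
          if (abstain) {
            p_au <- c(1, rep(0, k_max))
          } else {
            pi0 <- expit(zo[["intercept"]] + zo[["mood_prev"]] * mp +
                           zo[["non_working"]] * nw[t] + zo[["t08"]] * t08[t] +
                           zo[["t16"]] * t16[t] + zo[["social"]] * s)
            lam <- exp(co[["intercept"]] + co[["mood_prev"]] * mp +
                         co[["non_working"]] * nw[t] + co[["t08"]] * t08[t] +
                         co[["t16"]] * t16[t] + co[["social"]] * s)
            p_au <- (1 - pi0) * stats::dpois(0:k_max, lam)
            p_au[1] <- p_au[1] + pi0
          }
          for (au in which(p_au > 1e-14) - 1L) {
            eta <- ms[["b_alcohol_now"]] * au + ms[["b_alcohol_prev"]] * ap +
              ms[["b_mood_prev"]] * mp + ms[["b_non_working"]] * nw[t] +
              ms[["b_t08"]] * t08[t] + ms[["b_t16"]] * t16[t] +
              ms[["b_social"]] * s
            p_y <- mood_vec(eta)
            for (yi in 1:5) {
              j <- (yi - 1) * (k_max + 1) * 2 + au * 2 + s + 1
              newp[j] <- newp[j] + prob[i] * p_s * p_au[au + 1] * p_y[yi]
            }
          }
        }
      }
      prob <- newp
      ey[t - 1] <- sum(prob * states$y)
    }
    ey
  }
  one_arm(TRUE) - one_arm(FALSE)
}
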