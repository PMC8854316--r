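aq_levels <- c("strongly agree", "slightly agree",
               "slightly disagree", "strongly disagree")

test_that("AQ scoring follows the 0/1 keyed rule", {
  key <- rep(c("agree", "disagree"), 25)
  all_keyed <- ifelse(key == "agree", "strongly agree", "slightly disagree")
  expect_equal(score_aq(all_keyed, key), 50)
  none_keyed <- ifelse(key == "agree", "slightly disagree", "strongly agree")
  expect_equal(score_aq(none_keyed, key), 0)

  # constructed sheet with exactly 17 keyed endorsements, mixed slight/strong
  set.seed(301)
  resp <- none_keyed
  keyed_items <- sample(50, 17)
  resp[keyed_items] <- ifelse(key[keyed_items] == "agree",
                              sample(c("strongly agree", "slightly agree"),
                                     17, replace = TRUE),
                              sample(c("strongly disagree", "slightly disagree"),
                                     17, replace = TRUE))
  expect_equal(score_aq(resp, key), 17)

  expect_error(score_aq(resp[1:49], key), "50")
  bad <- resp
  bad[3] <- "agree"
  expect_error(score_aq(bad, key), "invalid response level")
})

test_that("cohort AQ distribution is centred where configured", {
  set.seed(302)
  cohort <- sample_cohort(cohort_spec(n_subjects = 10000))
  aq <- vapply(cohort, `[[`, 0L, "aq")
  expect_true(all(aq >= 0 & aq <= 50))
  expect_lte(abs(median(aq) - 15), 2)
})

test_that("default cohort hits the published group-bias anchors", {
  set.seed(303)
  cohort <- sample_cohort(cohort_spec(n_subjects = 20000))
  tab <- cohort_table(cohort)
  low_g <- tab$aq < 15
  expect_equal(mean(tab$bias_low[low_g]), 0.27, tolerance = 0.03)
  expect_equal(mean(tab$bias_low[!low_g]), 0.13, tolerance = 0.03)
  expect_equal(mean(tab$bias_high[low_g]), 0.11, tolerance = 0.03)
  expect_equal(mean(tab$bias_high[!low_g]), 0.08, tolerance = 0.03)
})

test_that("a zero bias slope yields a bias independent of AQ", {
  set.seed(304)
  spec <- cohort_spec(n_subjects = 200, bias_slope_low = 0,
                      bias_slope_high = 0)
  tab <- cohort_table(sample_cohort(spec))
  expect_equal(var(tab$bias_low), 0)
  expect_equal(unique(tab$bias_low), spec$bias_intercept_low)
})

test_that("perceived numerosity applies the two-regime bias step", {
  obs <- list(id = "S01", aq = 10, bias_low = 0.27, bias_high = 0.08,
              weber = 0.25, lapse = 0, rt_meanlog = log(0.7), rt_sdlog = 0.4)
  class(obs) <- "observer_model"
  expect_equal(perceived_numerosity(obs, 15, "isolated"), 15)
  expect_equal(perceived_numerosity(obs, 100, "isolated"), 100)
  expect_equal(perceived_numerosity(obs, 15, "connected"), 10.95)
  expect_equal(perceived_numerosity(obs, 50, "connected"), 50 * 0.73)
  expect_equal(perceived_numerosity(obs, 100, "connected"), 92)
})

test_that("response probabilities follow the Weber-scaled decision model", {
  obs <- list(id = "S01", aq = 10, bias_low = 0, bias_high = 0,
              weber = 0.2, lapse = 0, rt_meanlog = log(0.7), rt_sdlog = 0.4)
  class(obs) <- "observer_model"
  set.seed(305)
  # at the indifference point
  p50 <- mean(replicate(20000, simulate_response(obs, 20, 20)$chose_probe))
  expect_equal(p50, 0.5, tolerance = 0.01)
  # at ref * (1 + weber * z75): analytic 75% point
  probe75 <- 20 * (1 + 0.2 * qnorm(0.75))
  p75 <- mean(replicate(100000, simulate_response(obs, probe75, 20)$chose_probe))
  expect_equal(p75, 0.75, tolerance = 0.005)
  # noiseless limit: deterministic by sign
  obs$weber <- 1e-9
  expect_true(simulate_response(obs, 21, 20)$chose_probe)
  expect_false(simulate_response(obs, 19, 20)$chose_probe)
})

test_that("sessions have the planned size, balance and determinism", {
  obs <- sample_cohort(cohort_spec(n_subjects = 2))[[1]]
  tiny <- simulate_session(obs, session_plan(reference_numerosities = 15,
                                             conditions = "connected",
                                             trials_per_cell = 10), seed = 306)
  expect_equal(nrow(tiny), 10)

  full <- simulate_session(obs, session_plan(), seed = 307)
  expect_equal(nrow(full), 1440)
  expect_equal(unname(table(full$condition)), c(720L, 720L),
               ignore_attr = TRUE)
  # left/right balance within binomial noise (4 sigma)
  n_left <- sum(full$reference_side == "left")
  expect_lt(abs(n_left - 720), 4 * sqrt(1440 * 0.25))
  # determinism
  again <- simulate_session(obs, session_plan(), seed = 307)
  expect_identical(as.data.frame(full), as.data.frame(again))
})

test_that("RT trimming removes a small fraction at default parameters", {
  obs <- sample_cohort(cohort_spec(n_subjects = 2))[[1]]
  tr <- simulate_session(obs, session_plan(), seed = 308)
  res <- trim_rt(tr)
  expect_lt(res$removed_fraction, 0.05)
  expect_gt(res$removed_fraction, 0)
})

test_that("an unbiased observer's fitted PSE lands on the reference", {
  spec <- cohort_spec(n_subjects = 2, bias_intercept_low = 0,
                      bias_slope_low = 0, bias_intercept_high = 0,
                      bias_slope_high = 0)
  set.seed(309)
  obs <- sample_cohort(spec)[[1]]
  tr <- simulate_session(obs, session_plan(reference_numerosities = 15),
                         seed = 310)
  for (cond in c("isolated", "connected")) {
    f <- fit_psychometric(tr[tr$condition == cond, ])
    # 2 SE in dots, approximated by sigma / sqrt(n) * sqrt(pi/2) for
    # near-PSE sampling; use a generous 1-dot criterion
    expect_lt(abs(f$pse - 15), 1)
  }
})

test_that("known biases are recovered within a dot at N = 15", {
  biases <- seq(0, 0.3, length.out = 20)
  set.seed(311)
  hits <- vapply(seq_along(biases), function(i) {
    obs <- list(id = "S01", aq = 10, bias_low = biases[i], bias_high = 0.08,
                weber = 0.25, lapse = 0.02,
                rt_meanlog = log(0.7), rt_sdlog = 0.4)
    class(obs) <- "observer_model"
    tr <- simulate_session(obs, session_plan(reference_numerosities = 15,
                                             conditions = "connected"))
    f <- fit_psychometric(tr)
    abs(f$pse - 15 * (1 - biases[i])) < 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
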