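make_trials <- function(probe, chose, subject = "S01", rt = NULL) {
  tibble::tibble(
    subject_id = subject,
    probe_n = probe,
    chose_probe = chose,
    rt_s = if (is.null(rt)) rep(1, length(probe)) else rt
  )
}

test_that("RT trimming matches hand computations and edge cases", {
  tr <- make_trials(rep(10, 5), rep(TRUE, 5), rt = c(1, 1, 1, 1, 10))
  # mean 2.8, sd 4.0249; 10 < 2.8 + 2 * 4.0249 so everything is kept
  expect_equal(sd(tr$rt_s), 4.024922, tolerance = 1e-6)
  res <- trim_rt(tr)
  expect_equal(nrow(res$kept), 5)
  expect_equal(nrow(res$removed), 0)

  # identical RTs: zero SD, defined as keep-all
  same <- make_trials(rep(10, 4), rep(TRUE, 4), rt = rep(0.8, 4))
  expect_equal(trim_rt(same)$removed_fraction, 0)

  # an actual outlier is removed
  out <- make_trials(rep(10, 30), rep(TRUE, 30),
                     rt = c(rep(1, 28), 1.2, 50))
  res2 <- trim_rt(out)
  expect_equal(nrow(res2$removed), 1)
  expect_equal(res2$removed$rt_s, 50)

  expect_error(trim_rt(make_trials(10, TRUE, rt = 1)), "at least 3 trials")
})

test_that("trimming a standard-normal RT sample removes the 2-sigma tails", {
  set.seed(401)
  tr <- make_trials(rep(10, 10000), rep(TRUE, 10000), rt = rnorm(10000))
  res <- trim_rt(tr)
  expect_lt(abs(res$removed_fraction - 0.0455), 0.005)
})

test_that("the fit recovers known psychometric parameters at large n", {
  set.seed(402)
  x <- sample(5:18, 10000, replace = TRUE)
  y <- runif(10000) < pnorm((x - 11) / 2)
  tr <- make_trials(x, y)
  f <- fit_psychometric(tr, reference_n = 15)
  expect_equal(f$pse, 11, tolerance = 0.1)
  expect_equal(f$sigma, 2, tolerance = 0.1)
  expect_true(f$converged)
  # jnd and wf derive from sigma and pse
  expect_equal(f$jnd / f$sigma, qnorm(0.75), tolerance = 1e-9)
  expect_equal(f$wf, f$jnd / f$pse, tolerance = 1e-12)
  expect_equal(f$bias_pct, 100 * (f$pse - 15) / 15, tolerance = 1e-12)

  # probit regression is an independent route to the same ML estimate
  glm_fit <- suppressWarnings(
    glm(y ~ x, family = binomial(link = "probit"))
  )
  pse_glm <- -coef(glm_fit)[1] / coef(glm_fit)[2]
  sigma_glm <- 1 / coef(glm_fit)[2]
  expect_equal(f$pse, unname(pse_glm), tolerance = 1e-3)
  expect_equal(f$sigma, unname(sigma_glm), tolerance = 1e-3)
})

test_that("separable step data put the PSE at the step", {
  x <- c(10:14, 16:20)
  y <- x > 15
  f <- suppressWarnings(fit_psychometric(make_trials(x, y), reference_n = 15))
  expect_equal(f$pse, 15, tolerance = 0.5)
  # the likelihood plateaus once every trial is saturated; sigma ends up
  # far below the probe spacing (an effective step)
  expect_lt(f$sigma, 0.5)
})

test_that("degenerate or underdetermined data raise errors", {
  expect_error(fit_psychometric(make_trials(rep(10, 8), rep(TRUE, 8)),
                                reference_n = 10),
               "distinct probe levels")
  expect_error(fit_psychometric(make_trials(8:15, rep(TRUE, 8)),
                                reference_n = 10),
               "degenerate")
})

test_that("bias_percent reproduces the worked percentage biases", {
  expect_equal(round(abs(bias_percent(11, 15))), 27)
  expect_equal(bias_percent(15, 15), 0)
  expect_equal(round(abs(bias_percent(13, 15))), 13)
  expect_equal(bias_percent(11, 15), -100 * 4 / 15, tolerance = 1e-12)
})

test_that("adding low-PSE-consistent trials never raises the fitted PSE", {
  set.seed(403)
  x <- sample(5:18, 2000, replace = TRUE)
  y <- runif(2000) < pnorm((x - 12) / 2)
  base <- make_trials(x, y)
  f0 <- fit_psychometric(base, reference_n = 15)
  extra <- make_trials(rep(c(9, 10), 50), rep(TRUE, 100))
  f1 <- fit_psychometric(rbind(base, extra), reference_n = 15)
  expect_lte(f1$pse, f0$pse + 1e-6)
})

test_that("pooling duplicates is idempotent and pooling subjects averages", {
  set.seed(404)
  x <- sample(5:18, 1500, replace = TRUE)
  y <- runif(1500) < pnorm((x - 11) / 2)
  one <- make_trials(x, y)
  f1 <- aggregate_curve(one, reference_n = 15)
  dup <- rbind(one, transform(one, subject_id = "S02"))
  f2 <- aggregate_curve(dup, reference_n = 15)
  expect_equal(f2$fit$pse, f1$fit$pse, tolerance = 1e-4)
  expect_equal(f2$fit$sigma, f1$fit$sigma, tolerance = 1e-4)
  expect_equal(f1$curve$prop_chose_probe, f2$curve$prop_chose_probe)

  # two subjects with PSEs 10 and 12, equal trials and slopes
  set.seed(405)
  xa <- sample(4:18, 20000, replace = TRUE)
  ya <- runif(20000) < pnorm((xa - 10) / 2)
  xb <- sample(4:18, 20000, replace = TRUE)
  yb <- runif(20000) < pnorm((xb - 12) / 2)
  pooled <- rbind(make_trials(xa, ya, subject = "A"),
                  make_trials(xb, yb, subject = "B"))
  fp <- aggregate_curve(pooled, reference_n = 15)
  expect_equal(fp$fit$pse, 11, tolerance = 0.2)
})
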