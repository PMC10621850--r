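test_that("censored log-likelihood has the expected closed-form values", {
  s <- censored_sample(0)
  expect_equal(loglik_censored(s, dist_spec("normal", mean = 0, sd = 1)),
               -0.5 * log(2 * pi))
  ## a censored term at an effectively infinite limit contributes nothing
  s2 <- censored_sample(numeric(0), limits = 1e6, counts = 3)
  expect_equal(loglik_censored(s2, dist_spec("exponential", rate = 1)), 0)
  ## censored mass where the model has none gives -Inf
  s3 <- censored_sample(numeric(0), limits = 0, counts = 2)
  expect_equal(loglik_censored(s3, dist_spec("exponential", rate = 1)), -Inf)
})

test_that("CS fits reproduce the published use-case point estimates", {
  u <- read_censored(usecase_path("uric_acid"), family = "normal")
  fu <- fit_cs(u, "normal")
  expect_equal(round(fu$mean, 3), 5.177)
  expect_lt(fu$score_residual, 1e-6)

  f <- read_censored(usecase_path("ferritin"), family = "exponential")
  ff <- fit_cs(f, "exponential")
  expect_equal(round(ff$mean, 3), 96.218)
  expect_lt(ff$score_residual, 1e-6)

  e <- read_censored(usecase_path("eosin"), family = "poisson")
  fe <- fit_cs(e, "poisson")
  expect_equal(round(fe$mean, 3), 3.430)
  expect_lt(fe$score_residual, 1e-6)
})

test_that("simple imputation reproduces the published use-case means", {
  u <- read_censored(usecase_path("uric_acid"), family = "normal")
  expect_equal(round(fit_si(u, "normal")$mean, 3), 4.250)
  f <- read_censored(usecase_path("ferritin"), family = "exponential")
  expect_equal(round(fit_si(f, "exponential")$mean, 3), 100.229)
  ## counts impute half the reported exclusive bound: 1.5 and 2.0
  e <- read_censored(usecase_path("eosin"), family = "poisson")
  expect_equal(round(fit_si(e, "poisson")$mean, 3), 3.417)
})

test_that("with no censoring every fit reduces to the complete-data MLE", {
  s <- censored_sample(c(1, 2, 3))
  fn <- fit_cs(s, "normal")
  expect_equal(fn$params$mean, 2, tolerance = 1e-8)
  expect_equal(fn$params$sd^2, 2 / 3, tolerance = 1e-8)

  se <- censored_sample(c(2, 4))
  expect_equal(fit_cs(se, "exponential")$params$rate, 1 / 3, tolerance = 1e-8)

  sp <- censored_sample(c(2, 4, 6))
  expect_equal(fit_cs(sp, "poisson")$params$rate, 4, tolerance = 1e-8)

  expect_equal(fit_si(s, "normal")$mean, 2)

  set.seed(7)
  x <- rnorm(25, 10, 2)
  f <- fit_cs(censored_sample(x), "normal")
  expect_equal(f$params$mean, mean(x), tolerance = 1e-8)
  expect_equal(f$params$sd, sqrt(mean((x - mean(x))^2)), tolerance = 1e-8)
})

test_that("degenerate samples raise the documented errors", {
  all_cens <- censored_sample(numeric(0), limits = 5, counts = 10)
  expect_error(fit_cs(all_cens, "normal"), "censored")
  expect_error(fit_cs(all_cens, "exponential"), "censored")
  expect_error(fit_cs(all_cens, "poisson"), "censored")
  expect_error(fit_cs(censored_sample(c(7)), "normal"), "at least 2")
  ## censored exponential mass at c = 0 is impossible under the model
  bad <- censored_sample(c(1, 2), limits = 0, counts = 1)
  expect_error(fit_cs(bad, "exponential"), "degenerate")
  ## all-zero counts with no censoring sit on the lambda = 0 boundary
  z <- fit_cs(censored_sample(c(0, 0, 0)), "poisson")
  expect_equal(z$params$rate, 0)
  expect_error(fit_si(censored_sample(numeric(0)), "normal"), "empty")
})

test_that("score residuals vanish at every converged solution", {
  set.seed(2024)
  for (fam in c("normal", "exponential", "poisson")) {
    for (i in 1:20) {
      smp <- random_censored_sample(fam, 40)
      if (!sample_fit_ok(smp, fam)) next
      f <- fit_cs(smp, fam)
      expect_true(f$converged)
      expect_lt(f$score_residual, 1e-6)
    }
  }
})

test_that("CS solutions beat a fine likelihood grid around themselves", {
  set.seed(31)
  for (fam in c("normal", "exponential", "poisson")) {
    for (i in 1:7) {
      smp <- random_censored_sample(fam, 30)
      if (!sample_fit_ok(smp, fam)) next
      f <- fit_cs(smp, fam)
      ll_fit <- loglik_censored(smp, do.call(dist_spec, c(list(family = fam), f$params)))
      best <- if (fam == "normal")
        grid_max_loglik(smp, fam, c(f$params$mean, f$params$sd), c(0.02, 0.02))
      else grid_max_loglik(smp, fam, f$params$rate,
                           max(0.02, 0.05 * f$params$rate))
      expect_gte(ll_fit, best - 1e-6)
    }
  }
})

test_that("dense-grid search confirms the Poisson rate estimate", {
  e <- read_censored(usecase_path("eosin"), family = "poisson")
  lam <- seq(1e-4, 20, by = 1e-4)
  ## vectorized brute-force scan of the censored log-likelihood over lambda
  ll <- -e$n * lam + sum(e$quantified) * log(lam) -
    sum(lgamma(e$quantified + 1)) +
    e$counts[1] * ppois(e$limits[1], lam, log.p = TRUE) +
    e$counts[2] * ppois(e$limits[2], lam, log.p = TRUE)
  expect_equal(fit_cs(e, "poisson")$params$rate, lam[which.max(ll)],
               tolerance = 1e-4)
})

test_that("exponential root matches an independent bisection to 1e-10", {
  set.seed(58)
  for (i in 1:10) {
    smp <- random_censored_sample("exponential", 40)
    if (!sample_fit_ok(smp, "exponential")) next
    f <- fit_cs(smp, "exponential")
    oracle <- bisect_exp_score(smp, 1e-6, 10)
    expect_lt(abs(f$params$rate - oracle), 1e-10)
  }
})

test_that("CS estimates are unbiased in large samples at 50% censoring", {
  set.seed(4242)
  R <- 60; N <- 10000
  for (fam in c("normal", "exponential", "poisson")) {
    spec <- switch(fam,
      normal = dist_spec("normal", mean = 5.8, sd = 1),
      exponential = dist_spec("exponential", rate = 0.095),
      poisson = dist_spec("poisson", rate = 4))
    lim <- switch(fam, normal = 5.8, exponential = qexp(0.5, 0.095),
                  poisson = 4)  # Poi(4): P(Z <= 4) = 0.63, the closest integer design
    est <- replicate(R, {
      smp <- censor_dataset(lloqci:::rdist(spec, N), lim,
                            discrete = fam == "poisson")
      fit_cs(smp, fam)$mean
    })
    bias <- mean(est) - dist_mean(spec)
    expect_lt(abs(bias), 3 * sd(est) / sqrt(R),
              label = sprintf("%s large-sample bias %.2g", fam, bias))
  }
})
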