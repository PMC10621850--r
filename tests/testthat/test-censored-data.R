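test_that("line dialect parses quantified and censored records", {
  s <- parse_censored(c("# comment", "", "6.3"))
  expect_equal(s$quantified, 6.3)
  expect_equal(s$k, 0)

  u <- read_censored(usecase_path("uric_acid"), family = "normal")
  expect_equal(u$N, 42)
  expect_equal(u$n, 19)
  expect_equal(u$k, 23)
  expect_equal(u$limits, c(5.0, 5.5))
  expect_equal(u$counts, c(9L, 14L))

  ## identical limits aggregate, limits come back sorted
  s2 <- parse_censored(c("<5.5", "<5.0", "<5.5", "7.0"))
  expect_equal(s2$limits, c(5.0, 5.5))
  expect_equal(s2$counts, c(1L, 2L))
})

test_that("malformed and out-of-domain tokens are rejected with context", {
  expect_error(parse_censored(c("1.0", "<abc")), "line 2")
  expect_error(parse_censored("<0"), "not valid")
  expect_error(parse_censored("-3.2"), "not valid")
  expect_error(parse_censored(c("# only comments")), "no observations")
})

test_that("CSV dialect round-trips against the line dialect", {
  s <- parse_censored(c("status,value", "censored,5.0", "quantified,6.1",
                        "censored,5.0", "quantified,5.4"))
  expect_equal(s$quantified, c(6.1, 5.4))
  expect_equal(s$counts, 2L)
  expect_error(parse_censored(c("status,value", "dubious,5.0")), "status")
  expect_error(parse_censored(c("status,value", "censored,5.0,9")), "malformed")
})

test_that("Poisson convention maps reported '<v' to model limit v-1", {
  e <- read_censored(usecase_path("eosin"), family = "poisson")
  expect_equal(e$printed, c(3, 4))
  expect_equal(e$limits, c(2, 3))
  expect_equal(e$counts, c(11L, 11L))
  expect_equal(e$N, 42)
  ## continuous reading of the same file keeps the printed limits
  e2 <- read_censored(usecase_path("eosin"))
  expect_equal(e2$limits, c(3, 4))
  expect_error(parse_censored(c("<2.5", "3"), family = "poisson"), "integer")
})

test_that("write/parse round-trip preserves values and censored counts", {
  set.seed(421)
  for (fam in c("none", "poisson")) {
    for (fmt in c("lines", "csv")) {
      smp <- if (fam == "poisson")
        censor_dataset(rpois(40, 4), c(2, 3), discrete = TRUE)
      else censor_dataset(rnorm(40, 5.8, 1), c(5.55, 6.05))
      if (fam == "poisson") {
        ## reported bounds are one above the inclusive model limits
        smp <- censored_sample(smp$quantified, smp$limits, smp$counts,
                               printed = smp$limits + 1)
      }
      f <- withr::local_tempfile()
      write_censored(smp, f, format = fmt)
      back <- read_censored(f, family = if (fam == "poisson") "poisson" else "none",
                            format = fmt)
      expect_equal(sort(back$quantified), sort(smp$quantified))
      nz <- smp$counts > 0
      expect_equal(back$limits, smp$limits[nz])
      expect_equal(back$counts, smp$counts[nz])
    }
  }
})

test_that("censor_dataset applies the half-split design and conserves N", {
  s <- censor_dataset(c(4.0, 6.0, 4.0, 6.0), c(5.0, 5.5))
  expect_equal(s$counts, c(1L, 1L))
  expect_equal(s$quantified, c(6.0, 6.0))

  s2 <- censor_dataset(c(7, 8, 9, 10), c(5.0, 5.5))
  expect_equal(s2$k, 0)
  expect_equal(sort(s2$quantified), c(7, 8, 9, 10))

  set.seed(99)
  for (i in 1:20) {
    x <- rnorm(50 * 2, 5.8, 1)
    s <- censor_dataset(x, c(5.55, 6.05))
    expect_equal(s$n + s$k, length(x))
  }

  expect_error(censor_dataset(1:3, c(1, 2)), "even")
  expect_error(censor_dataset(1:4, c(1, 2, 3)), "not supported")
  ## a value equal to a continuous limit stays quantified
  expect_equal(censor_dataset(c(5.0, 9.9), 5.0)$k, 0)
  ## ...but an equal count is censored under the inclusive convention
  expect_equal(censor_dataset(c(2, 9), 2, discrete = TRUE)$counts, 1L)
})

test_that("empirical censored fraction matches the Poisson design value", {
  set.seed(123)
  x <- rpois(1e5, 4)
  s <- censor_dataset(x, 2, discrete = TRUE)
  p <- ppois(2, 4)
  expect_lt(abs(s$k / s$N - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("theoretical censored proportions reproduce the design grid", {
  specs <- list(normal = dist_spec("normal", mean = 5.8, sd = 1),
                exponential = dist_spec("exponential", rate = 0.095),
                poisson = dist_spec("poisson", rate = 4))
  grid <- list(
    list("normal", 4.96, 0.200), list("normal", 5.80, 0.500),
    list("normal", 6.20, 0.6554),
    list("normal", c(4.52, 5.28), 0.200), list("normal", c(5.55, 6.05), 0.500),
    list("normal", c(5.94, 6.49), 0.6554),
    list("exponential", 2.35, 0.200), list("exponential", 7.29, 0.500),
    list("exponential", 11.21, 0.6554),
    list("exponential", c(1.11, 3.75), 0.200),
    list("exponential", c(5.38, 9.65), 0.500),
    list("exponential", c(8.53, 14.82), 0.6554),
    list("poisson", 2, 0.2381), list("poisson", 3, 0.4335),
    list("poisson", 4, 0.6288),
    list("poisson", c(2, 3), 0.3358), list("poisson", c(3, 4), 0.5311),
    list("poisson", c(4, 5), 0.7070))
  for (g in grid) {
    got <- theoretical_censored_proportion(specs[[g[[1]]]], g[[2]])$overall
    ## limits in the design table are printed rounded, which can shift the
    ## implied proportion by up to ~0.1 percentage points
    expect_lt(abs(got - g[[3]]), 1e-3,
              label = sprintf("%s limits %s: %.5f", g[[1]],
                              paste(g[[2]], collapse = ";"), got))
  }
  ## no limits means nothing is censored
  expect_equal(theoretical_censored_proportion(specs$normal, numeric())$overall, 0)
  ## Poisson entries with exact integer limits agree to the printed precision
  expect_equal(round(100 * theoretical_censored_proportion(specs$poisson, 2)$overall, 2), 23.81)
  expect_equal(round(100 * theoretical_censored_proportion(specs$poisson, c(2, 3))$overall, 2), 33.58)
})

test_that("sample and spec constructors validate their invariants", {
  expect_error(censored_sample(1, limits = c(5, 4), counts = c(1, 1)), "increasing")
  expect_error(censored_sample(1, limits = -1, counts = 1), "non-negative")
  expect_error(censored_sample(1, limits = 5, counts = -1), "non-negative")
  expect_error(censored_sample(4.0, limits = 5, counts = 1), "below the smallest")
  expect_error(dist_spec("normal", mean = 0, sd = 0), "positive")
  expect_error(dist_spec("exponential", rate = -1), "positive")
  expect_equal(dist_mean(dist_spec("exponential", rate = 0.095)), 1 / 0.095)
})
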