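## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: the BCa oracle is written straight from the
## endpoint formula with a hand-rolled inverse-ECDF quantile, and the grid
## oracles maximize the censored log-likelihood by brute force.

## type-6 quantile, coded independently of stats::quantile
q6_manual <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n + 1) * p
  lo <- max(min(floor(h), n), 1)
  hi <- max(min(lo + 1, n), 1)
  g <- h - floor(h)
  if (h < 1) return(x[1])
  if (h >= n) return(x[n])
  x[lo] + g * (x[hi] - x[lo])
}

## straight-from-formula BCa endpoints
oracle_bca <- function(theta_star, theta_hat, theta_jack, level = 0.95) {
  B <- length(theta_star)
  p <- (sum(theta_star < theta_hat) + 0.5 * sum(theta_star == theta_hat)) / B
  z0 <- qnorm(p)
  dm <- mean(theta_jack) - theta_jack
  a <- sum(dm^3) / (6 * sum(dm^2)^1.5)
  ends <- sapply(c((1 - level) / 2, 1 - (1 - level) / 2), function(al) {
    za <- qnorm(al)
    q6_manual(theta_star, pnorm(z0 + (z0 + za) / (1 - a * (z0 + za))))
  })
  ends
}

## brute-force grid maximization of the censored log-likelihood
grid_max_loglik <- function(smp, family, center, halfwidth, step = 1e-3) {
  if (family == "normal") {
    mus <- seq(center[1] - halfwidth[1], center[1] + halfwidth[1], by = step)
    sds <- seq(max(center[2] - halfwidth[2], step), center[2] + halfwidth[2],
               by = step)
    best <- -Inf
    for (s in sds) {
      ll <- vapply(mus, function(m)
        loglik_censored(smp, dist_spec("normal", mean = m, sd = s)),
        numeric(1))
      best <- max(best, max(ll))
    }
    best
  } else {
    rates <- seq(max(center - halfwidth, step), center + halfwidth, by = step)
    max(vapply(rates, function(r)
      loglik_censored(smp, dist_spec(family, rate = r)), numeric(1)))
  }
}

## bisection on the exponential censored score, independent of uniroot
bisect_exp_score <- function(smp, lo, hi, tol = 1e-12) {
  g <- function(l)
    sum(smp$counts * smp$limits / expm1(l * smp$limits)) +
    smp$n / l - sum(smp$quantified)
  stopifnot(g(lo) > 0, g(hi) < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## random censored sample generators for property tests
random_censored_sample <- function(family, n_target = 30) {
  if (family == "normal") {
    x <- rnorm(n_target, 5.8, 1)
    censor_dataset(x, c(5.3, 6.1))
  } else if (family == "exponential") {
    x <- rexp(n_target, 0.095)
    censor_dataset(x, c(5.38, 9.65))
  } else {
    x <- rpois(n_target, 4)
    censor_dataset(x, c(3, 4), discrete = TRUE)
  }
}

sample_fit_ok <- function(smp, family) {
  ## retry helper: resampled sets occasionally have < 2 quantified values
  smp$n >= 2 && sum(smp$quantified) > 0
}
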