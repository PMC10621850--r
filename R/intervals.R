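.new_ci <- function(lower, upper, level, method, diagnostics = NULL) {
  structure(
    list(lower = lower, upper = upper, level = level, method = method,
         width = upper - lower, diagnostics = diagnostics),
    class = "lloq_ci")
}

#' @export
print.lloq_ci <- function(x, ...) {
  cat(sprintf("%g%% %s CI: [%.6g, %.6g] (width %.6g)\n",
              100 * x$level, x$method, x$lower, x$upper, x$width))
  if (!is.null(x$diagnostics))
    cat(sprintf("  z0 = %.4g, acceleration = %.4g, replicates used = %d\n",
                x$diagnostics$z0, x$diagnostics$acceleration,
                x$diagnostics$B_eff))
  invisible(x)
}

#' Asymptotic parametric confidence interval for the mean
#'
#' Classical complete-data interval evaluated at the censored-data point
#' estimates, on the mean scale:
#' \deqn{\hat\mu \pm z_{1-\alpha/2}\,\hat\sigma/\sqrt N \quad (normal),}
#' \deqn{[\,(2N/\hat\lambda)/\chi^2_{2N;1-\alpha/2},\;
#'        (2N/\hat\lambda)/\chi^2_{2N;\alpha/2}\,] \quad (exponential,
#'        reported for the mean } 1/\lambda\mbox{),}
#' \deqn{\hat\lambda \pm z_{1-\alpha/2}\sqrt{\hat\lambda/N} \quad (Poisson).}
#' \eqn{N} is the total sample size including censored records. The interval
#' assumes complete data; under censoring it is an approximation whose
#' coverage degrades with the censored proportion (which is the point of the
#' package's simulation engine).
#'
#' @param fit an \code{\link{lloq_fit}}.
#' @param level nominal coverage, default 0.95.
#' @param N total sample size; defaults to the fitted sample's N.
#' @return An \code{"lloq_ci"} object.
#' @examples
#' s <- censored_sample(c(6.0, 6.2, 7.1), limits = 5.5, counts = 3)
#' ci_parametric(fit_cs(s, "normal"))
#' @export
ci_parametric <- function(fit, level = 0.95, N = fit$N) {
  stopifnot(inherits(fit, "lloq_fit"), level > 0, level < 1)
  if (!isTRUE(fit$converged)) stop("cannot build an interval from an unconverged fit")
  if (N < 2) stop("N must be at least 2")
  a <- 1 - level
  z <- stats::qnorm(1 - a / 2)
  switch(fit$family,
    normal = {
      hw <- z * fit$params$sd / sqrt(N)
      .new_ci(fit$params$mean - hw, fit$params$mean + hw, level, "parametric")
    },
    exponential = {
      s <- 2 * N / fit$params$rate
      .new_ci(s / stats::qchisq(1 - a / 2, 2 * N),
              s / stats::qchisq(a / 2, 2 * N), level, "parametric")
    },
    poisson = {
      hw <- z * sqrt(fit$params$rate / N)
      .new_ci(fit$params$rate - hw, fit$params$rate + hw, level, "parametric")
    })
}

## record-level representation used for resampling: each of the N records is
## either a quantified value (limit index 0) or a censored record at limit i
.as_records <- function(sample) {
  list(value = c(sample$quantified, rep(NA_real_, sample$k)),
       lim = c(rep(0L, sample$n), rep(seq_along(sample$limits), sample$counts)))
}

.records_to_vectors <- function(rec, idx, m) {
  lim <- rec$lim[idx]
  list(w = rec$value[idx][lim == 0L],
       counts = tabulate(lim, nbins = m))
}

.resolve_estimator <- function(sample, estimator, family, method) {
  if (is.function(estimator)) {
    fn <- function(w, counts) {
      s <- censored_sample(w, sample$limits, counts, sample$printed)
      estimator(s)
    }
  } else {
    method <- if (is.null(method)) match.arg(estimator, c("cs", "si")) else method
    kern <- .mean_kernel(family, method)
    cl <- sample$limits; pr <- sample$printed
    fn <- function(w, counts) kern(w, cl, counts, pr)
  }
  fn
}

#' Bootstrap distribution of a mean-scale estimator
#'
#' Draws \code{Rb} resamples of size \eqn{N} with replacement from the
#' original records — quantified and censored alike, unstratified with
#' respect to the LLOQ a censored record belongs to — and re-estimates the
#' mean on each. For the simple-imputation estimator resampling happens
#' first and imputation second. Resamples on which the estimator fails
#' (e.g. an all-censored resample) are dropped and counted; more than 50%
#' failures aborts, as the resulting interval would be untrustworthy.
#'
#' @param sample a \code{\link{censored_sample}}.
#' @param estimator either \code{"cs"} / \code{"si"} (fast path, with
#'   \code{family}) or a function taking a \code{censored_sample} and
#'   returning a mean-scale estimate.
#' @param Rb number of bootstrap replicates.
#' @param seed integer seed making the replicate vector reproducible.
#' @param family distribution family, used when \code{estimator} is a name.
#' @return numeric vector of replicate estimates with attribute
#'   \code{"n_failed"}.
#' @export
bootstrap_estimates <- function(sample, estimator = "cs", Rb = 5500, seed = 1,
                                family = c("normal", "exponential", "poisson")) {
  stopifnot(inherits(sample, "censored_sample"), Rb >= 1)
  family <- match.arg(family)
  fn <- .resolve_estimator(sample, estimator, family, NULL)
  rec <- .as_records(sample)
  m <- length(sample$limits)
  N <- sample$N
  set.seed(seed)
  out <- numeric(Rb)
  failed <- 0L
  for (r in seq_len(Rb)) {
    idx <- sample.int(N, N, replace = TRUE)
    v <- .records_to_vectors(rec, idx, m)
    est <- tryCatch(fn(v$w, v$counts), error = function(e) NA_real_)
    out[r] <- est
    if (!is.finite(est)) failed <- failed + 1L
  }
  if (failed > Rb / 2)
    stop("more than half of the bootstrap replicates failed; interval untrustworthy")
  res <- out[is.finite(out)]
  attr(res, "n_failed") <- failed
  res
}

#' Leave-one-out jackknife estimates
#'
#' Re-estimates the mean with each of the \eqn{N} original records (censored
#' records included) removed in turn; used for the BCa acceleration constant.
#'
#' @inheritParams bootstrap_estimates
#' @return numeric vector of length \eqn{N} (failed fits dropped).
#' @export
jackknife_estimates <- function(sample, estimator = "cs",
                                family = c("normal", "exponential", "poisson")) {
  stopifnot(inherits(sample, "censored_sample"))
  family <- match.arg(family)
  fn <- .resolve_estimator(sample, estimator, family, NULL)
  rec <- .as_records(sample)
  m <- length(sample$limits)
  N <- sample$N
  out <- numeric(N)
  for (i in seq_len(N)) {
    v <- .records_to_vectors(rec, -i, m)
    out[i] <- tryCatch(fn(v$w, v$counts), error = function(e) NA_real_)
  }
  out[is.finite(out)]
}

#' Bias-corrected accelerated (BCa) bootstrap interval
#'
#' Efron's BCa interval: the endpoints are empirical quantiles of the
#' bootstrap distribution at adjusted levels
#' \deqn{\alpha_{adj} = \Phi\!\left(z_0 + \frac{z_0 + z_\alpha}
#'   {1 - a\,(z_0 + z_\alpha)}\right),}
#' where the bias-correction \eqn{z_0 = \Phi^{-1}(G(\hat\theta))} is computed
#' from the fraction of replicates below the point estimate (ties counted as
#' half, which matters for discrete statistics) and the acceleration
#' \eqn{a = \sum d_i^3 / (6 (\sum d_i^2)^{3/2})} from the jackknife
#' deviations \eqn{d_i = \bar\theta_{(\cdot)} - \hat\theta_{(i)}}. With
#' \eqn{z_0 = a = 0} the interval reduces to the plain percentile interval.
#' Quantiles use type-6 inverse-ECDF interpolation, so endpoints never
#' extrapolate beyond the observed replicates.
#'
#' @param replicates numeric vector of bootstrap estimates.
#' @param estimate the point estimate on the original sample.
#' @param jackknife numeric vector of leave-one-out estimates.
#' @param level nominal coverage, default 0.95.
#' @return An \code{"lloq_ci"} object with diagnostics \code{z0},
#'   \code{acceleration} and \code{B_eff}.
#' @export
bca_interval <- function(replicates, estimate, jackknife, level = 0.95) {
  stopifnot(length(replicates) >= 1, level > 0, level < 1)
  B <- length(replicates)
  frac <- (sum(replicates < estimate) + 0.5 * sum(replicates == estimate)) / B
  if (frac <= 0 || frac >= 1) {
    warning("all bootstrap replicates on one side of the estimate; ",
            "bias correction clamped")
    frac <- min(max(frac, 1 / (B + 1)), B / (B + 1))
  }
  z0 <- stats::qnorm(frac)
  d <- mean(jackknife) - jackknife
  denom <- sum(d^2)^1.5
  a <- if (denom > 0) sum(d^3) / (6 * denom) else 0
  alpha <- (1 - level) / 2
  adj <- function(za) stats::pnorm(z0 + (z0 + za) / (1 - a * (z0 + za)))
  lv <- adj(stats::qnorm(alpha))
  uv <- adj(stats::qnorm(1 - alpha))
  q <- stats::quantile(replicates, c(lv, uv), type = 6, names = FALSE)
  .new_ci(q[1], q[2], level, "bca",
          diagnostics = list(z0 = z0, acceleration = a, B_eff = B,
                             adj_levels = c(lv, uv)))
}

#' BCa interval for a censored sample in one call
#'
#' Convenience wrapper: fits the requested estimator, draws the bootstrap
#' distribution, computes jackknife estimates and returns the
#' \code{\link{bca_interval}}.
#'
#' @inheritParams bootstrap_estimates
#' @param method \code{"cs"} or \code{"si"}.
#' @param level nominal coverage.
#' @return An \code{"lloq_ci"} object; diagnostics additionally carry the
#'   number of failed replicates.
#' @examples
#' s <- censored_sample(c(6.0, 6.2, 7.1, 6.6), limits = 5.5, counts = 4)
#' ci_bca(s, "normal", Rb = 199, seed = 42)
#' @export
ci_bca <- function(sample, family = c("normal", "exponential", "poisson"),
                   method = c("cs", "si"), Rb = 5500, seed = 1, level = 0.95) {
  family <- match.arg(family)
  method <- match.arg(method)
  fit <- if (method == "cs") fit_cs(sample, family) else fit_si(sample, family)
  reps <- bootstrap_estimates(sample, method, Rb = Rb, seed = seed,
                              family = family)
  jack <- jackknife_estimates(sample, method, family = family)
  ci <- bca_interval(reps, fit$mean, jack, level = level)
  ci$diagnostics$n_failed <- attr(reps, "n_failed")
  ci
}
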