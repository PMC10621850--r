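## ---- internal estimation kernels -------------------------------------------
## These operate on raw vectors (quantified values w, model limits cl, censored
## counts k, reported limits pr) so that bootstrap and Monte Carlo loops avoid
## object-construction overhead. The exported fit_cs()/fit_si() wrap them.

## inverse Mills ratio phi(a)/Phi(a), stable for a far in the left tail
.mills <- function(a) exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))

.si_moments <- function(w, pr, k) {
  imputed <- c(rep(pr / 2, k), w)
  if (length(imputed) == 0) stop("cannot fit an empty sample")
  m <- mean(imputed)
  list(mean = m, var = mean((imputed - m)^2))
}

## censored-normal ML: Newton iteration on (mu, log sigma) applied to the two
## score equations, analytic Jacobian; derivative-free fallback on failure
.fit_normal_kernel <- function(w, cl, k, pr,
                               max_iter = 200, tol_par = 1e-10, tol_score = 1e-8) {
  act <- k > 0
  cl <- cl[act]; k <- k[act]
  n <- length(w)
  if (n == 0) stop("all observations censored: normal CS fit undefined")
  if (n < 2) stop("normal CS fit needs at least 2 quantified observations")
  sw <- sum(w)
  if (length(k) == 0) {
    mu <- sw / n
    return(list(mean = mu, sd = sqrt(mean((w - mu)^2)), converged = TRUE,
                iterations = 0L, score_residual = 0))
  }
  score <- function(th) {
    mu <- th[1]; s <- exp(th[2])
    r <- .mills((cl - mu) / s)
    c(sw - n * mu - s * sum(k * r),
      -n * s^2 + sum((w - mu)^2) - s * sum(k * (cl - mu) * r))
  }
  ## damped Newton on the score: steps are halved until the score norm
  ## decreases, which keeps heavy-censoring fits from overshooting when the
  ## simple-imputation start is far from the optimum
  newton <- function(th, max_iter) {
    g <- score(th)
    it <- 0L; converged <- FALSE
    gn0 <- max(abs(g))
    while (it < max_iter) {
      it <- it + 1L
      if (gn0 < tol_score) { converged <- TRUE; break }
      mu <- th[1]; s <- exp(th[2])
      a <- (cl - mu) / s
      r <- .mills(a)
      kr <- k * r
      krp <- k * (-a * r - r * r)            # k * r'(a)
      J11 <- -n + sum(krp)
      J12 <- s * (sum(krp * a) - sum(kr))
      J21 <- -2 * (sw - n * mu) + s * sum(kr) + sum(krp * (cl - mu))
      J22 <- -2 * n * s * s - s * sum(kr * (cl - mu)) +
        s * sum(krp * (cl - mu) * a)
      det <- J11 * J22 - J12 * J21
      if (!is.finite(det) || det == 0) break
      d <- c(-(J22 * g[1] - J12 * g[2]) / det,
             -(J11 * g[2] - J21 * g[1]) / det)
      accepted <- FALSE
      for (h in 0:20) {
        thn <- th + d / 2^h
        gn <- score(thn)
        if (all(is.finite(gn)) && max(abs(gn)) < gn0) { accepted <- TRUE; break }
      }
      if (!accepted) break
      moved <- max(abs(thn - th))
      th <- thn; g <- gn; gn0 <- max(abs(gn))
      if (moved < tol_par || gn0 < tol_score) { converged <- TRUE; break }
    }
    list(th = th, it = it, converged = converged, resid = gn0)
  }
  si <- .si_moments(w, pr[act], k)
  th0 <- c(si$mean, 0.5 * log(max(si$var, 1e-12)))
  nt <- newton(th0, max_iter)
  th <- nt$th; it <- nt$it; converged <- nt$converged
  if (!converged || nt$resid > tol_score) {
    ## fall back to derivative-free maximization of the censored
    ## log-likelihood, then polish the optimum with damped Newton
    nll <- function(th) {
      mu <- th[1]; s <- exp(th[2])
      -(sum(k * stats::pnorm(cl, mu, s, log.p = TRUE)) +
          sum(stats::dnorm(w, mu, s, log = TRUE)))
    }
    o <- stats::optim(th0, nll, control = list(reltol = 1e-14, maxit = 5000))
    nt <- newton(o$par, 50L)
    th <- nt$th
    it <- it + o$counts[1] + nt$it
    converged <- nt$converged || nt$resid < tol_score
  }
  list(mean = th[1], sd = exp(th[2]), converged = converged,
       iterations = as.integer(it),
       score_residual = max(abs(score(th))))
}

## censored-exponential ML: the score
##   g(lambda) = sum_i k_i c_i / (exp(lambda c_i) - 1) + n/lambda - sum(y)
## is strictly decreasing, so a bracketed root is unique
.fit_exp_kernel <- function(w, cl, k, pr, tol = 1e-10) {
  act <- k > 0
  cl <- cl[act]; k <- k[act]
  n <- length(w)
  if (n == 0) stop("all observations censored: exponential CS fit undefined")
  if (any(cl == 0)) stop("degenerate limit: censored mass at c = 0")
  sw <- sum(w)
  if (sw <= 0) stop("exponential CS fit needs a positive quantified sum")
  if (length(k) == 0)
    return(list(rate = n / sw, converged = TRUE, iterations = 0L,
                score_residual = 0))
  g <- function(l) sum(k * cl / expm1(l * cl)) + n / l - sw
  si <- .si_moments(w, pr[act], k)
  l0 <- 1 / si$mean
  lo <- l0 / 2; hi <- l0 * 2
  it <- 0L
  while (g(lo) < 0 && it < 200) { lo <- lo / 4; it <- it + 1L }
  while (g(hi) > 0 && it < 200) { hi <- hi * 4; it <- it + 1L }
  r <- stats::uniroot(g, c(lo, hi), tol = 1e-13 * max(1, l0))
  list(rate = r$root, converged = TRUE, iterations = as.integer(it + r$iter),
       score_residual = abs(g(r$root)))
}

## censored-Poisson ML: root of
##   g(lambda) = -n + sum(z)/lambda - sum_i k_i P(Z = c_i)/P(Z <= c_i)
.fit_pois_kernel <- function(w, cl, k, pr, tol = 1e-10) {
  act <- k > 0
  cl <- floor(cl[act]); k <- k[act]
  n <- length(w)
  if (n == 0) stop("all observations censored: Poisson CS fit undefined")
  sw <- sum(w)
  if (sw == 0 && length(k) == 0)
    return(list(rate = 0, converged = TRUE, iterations = 0L,
                score_residual = 0, boundary = TRUE))
  if (length(k) == 0)
    return(list(rate = sw / n, converged = TRUE, iterations = 0L,
                score_residual = 0))
  if (sw == 0)
    return(list(rate = 0, converged = TRUE, iterations = 0L,
                score_residual = NA_real_, boundary = TRUE))
  g <- function(l) -n + sw / l - sum(k * stats::dpois(cl, l) / stats::ppois(cl, l))
  si <- .si_moments(w, pr[act], k)
  l0 <- max(si$mean, 0.5)
  lo <- l0 / 2; hi <- l0 * 2
  it <- 0L
  while (g(lo) < 0 && it < 200) { lo <- lo / 4; it <- it + 1L }
  while (g(hi) > 0 && it < 200) { hi <- hi * 4; it <- it + 1L }
  r <- stats::uniroot(g, c(lo, hi), tol = 1e-13 * max(1, l0))
  list(rate = r$root, converged = TRUE, iterations = as.integer(it + r$iter),
       score_residual = abs(g(r$root)))
}

## mean-scale estimate kernel used by bootstrap/jackknife/simulation loops
.mean_kernel <- function(family, method) {
  if (method == "si") {
    return(function(w, cl, k, pr) .si_moments(w, pr, k)$mean)
  }
  switch(family,
    normal = function(w, cl, k, pr) .fit_normal_kernel(w, cl, k, pr)$mean,
    exponential = function(w, cl, k, pr) 1 / .fit_exp_kernel(w, cl, k, pr)$rate,
    poisson = function(w, cl, k, pr) .fit_pois_kernel(w, cl, k, pr)$rate)
}

.new_fit <- function(method, family, params, mean, sample, converged,
                     iterations, score_residual) {
  structure(
    list(method = method, family = family, params = params, mean = mean,
         N = sample$N, n = sample$n, k = sample$k,
         converged = converged, iterations = iterations,
         score_residual = score_residual, sample = sample),
    class = "lloq_fit")
}

#' Censored-sample maximum likelihood fit
#'
#' Maximizes the censored likelihood (see \code{\link{loglik_censored}}) for
#' the requested family. The normal fit solves the two score equations for
#' \eqn{(\mu, \sigma)} by a Newton-type iteration on \eqn{(\mu, \log\sigma)}
#' initialized at the simple-imputation moments, with a derivative-free
#' likelihood maximization as fallback. The exponential and Poisson rates are
#' unique roots of their monotone score functions, found by bracketed
#' root-finding started from the simple-imputation mean. With no censored
#' observations every fit reduces to the closed-form complete-data MLE
#' (N-denominator variance for the normal family).
#'
#' @param sample a \code{\link{censored_sample}}.
#' @param family \code{"normal"}, \code{"exponential"} or \code{"poisson"}.
#' @return An object of class \code{"lloq_fit"}: a list with \code{method}
#'   (\code{"cs"}), \code{family}, \code{params} (natural parameters),
#'   \code{mean} (mean-scale estimate: \eqn{\hat\mu}, \eqn{1/\hat\lambda} or
#'   \eqn{\hat\lambda}), \code{converged}, \code{iterations},
#'   \code{score_residual} and the sample sizes.
#' @examples
#' s <- censored_sample(c(6.0, 6.2, 7.1), limits = 5.5, counts = 3)
#' fit_cs(s, "normal")
#' @export
fit_cs <- function(sample, family = c("normal", "exponential", "poisson")) {
  stopifnot(inherits(sample, "censored_sample"))
  family <- match.arg(family)
  w <- sample$quantified; cl <- sample$limits
  k <- sample$counts; pr <- sample$printed
  if (family == "normal") {
    f <- .fit_normal_kernel(w, cl, k, pr)
    .new_fit("cs", family, list(mean = f$mean, sd = f$sd), f$mean, sample,
             f$converged, f$iterations, f$score_residual)
  } else if (family == "exponential") {
    f <- .fit_exp_kernel(w, cl, k, pr)
    .new_fit("cs", family, list(rate = f$rate), 1 / f$rate, sample,
             f$converged, f$iterations, f$score_residual)
  } else {
    f <- .fit_pois_kernel(w, cl, k, pr)
    .new_fit("cs", family, list(rate = f$rate), f$rate, sample,
             f$converged, f$iterations, f$score_residual)
  }
}

#' Simple-imputation fit (half-LLOQ substitution)
#'
#' The ad hoc comparator: every censored observation is replaced by half its
#' reported LLOQ (\eqn{s_i = c_i/2}; for counts, half the exclusive reported
#' bound), then complete-data formulas are applied. The sample mean and the
#' N-denominator sample variance of the imputed data map to the natural
#' parameters: \eqn{(\hat\mu, \hat\sigma^2)} for normal,
#' \eqn{\hat\lambda = 1/\bar w} for exponential, \eqn{\hat\lambda = \bar w}
#' for Poisson. The mean-scale estimate is the imputed sample mean for every
#' family.
#'
#' @inheritParams fit_cs
#' @return An object of class \code{"lloq_fit"} with \code{method = "si"}.
#' @examples
#' s <- censored_sample(c(6.0, 6.2, 7.1), limits = 5.5, counts = 3)
#' fit_si(s, "normal")
#' @export
fit_si <- function(sample, family = c("normal", "exponential", "poisson")) {
  stopifnot(inherits(sample, "censored_sample"))
  family <- match.arg(family)
  si <- .si_moments(sample$quantified, sample$printed, sample$counts)
  params <- switch(family,
    normal = list(mean = si$mean, sd = sqrt(si$var)),
    exponential = {
      if (si$mean <= 0) stop("imputed mean must be positive for the exponential family")
      list(rate = 1 / si$mean)
    },
    poisson = list(rate = si$mean))
  .new_fit("si", family, params, si$mean, sample, TRUE, 0L, 0)
}

#' @export
print.lloq_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s family): mean estimate %.6g\n",
              toupper(x$method), x$family, x$mean))
  cat("  parameters:",
      paste(sprintf("%s = %.6g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  cat(sprintf("  N = %d (%d censored); converged: %s\n",
              x$N, x$k, x$converged))
  invisible(x)
}
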