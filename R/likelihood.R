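#' Censored-sample log-likelihood
#'
#' Log of the multiply left-censored likelihood
#' \deqn{L = \prod_i F(c_i)^{k_i} \prod_j f(w_j),}
#' where each observation below LLOQ \eqn{c_i} contributes the probability
#' \eqn{F(c_i)} of falling below it and each quantified value contributes its
#' density (normal, exponential) or probability mass (Poisson). For the
#' Poisson family \eqn{F(c) = P(Z \le c)} with the model-scale integer limit.
#'
#' @param sample a \code{\link{censored_sample}}.
#' @param spec a \code{\link{dist_spec}} giving family and parameters.
#' @return log-likelihood value; \code{-Inf} when a limit with censored mass
#'   has \eqn{F(c_i) = 0} (e.g. an exponential limit of 0).
#' @examples
#' s <- censored_sample(0)
#' loglik_censored(s, dist_spec("normal", mean = 0, sd = 1)) # log phi(0)
#' @export
loglik_censored <- function(sample, spec) {
  stopifnot(inherits(sample, "censored_sample"), inherits(spec, "dist_spec"))
  w <- sample$quantified
  cl <- sample$limits
  k <- sample$counts
  act <- k > 0
  ll <- switch(spec$family,
    normal = {
      mu <- spec$params$mean; s <- spec$params$sd
      sum(k[act] * stats::pnorm(cl[act], mu, s, log.p = TRUE)) +
        sum(stats::dnorm(w, mu, s, log = TRUE))
    },
    exponential = {
      r <- spec$params$rate
      if (any(w < 0)) return(-Inf)
      sum(k[act] * stats::pexp(cl[act], r, log.p = TRUE)) +
        sum(stats::dexp(w, r, log = TRUE))
    },
    poisson = {
      r <- spec$params$rate
      sum(k[act] * stats::ppois(floor(cl[act]), r, log.p = TRUE)) +
        sum(stats::dpois(w, r, log = TRUE))
    })
  ll
}
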