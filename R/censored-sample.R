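#' Multiply left-censored sample
#'
#' Container for a sample affected by one or more lower limits of
#' quantification (LLOQs). A sample of total size \eqn{N = n + k} consists of
#' \eqn{n} quantified values \eqn{w} and, for each limit \eqn{c_i}
#' (\eqn{c_1 < \dots < c_m}), a count \eqn{k_i} of observations reported only
#' as "below \eqn{c_i}".
#'
#' For continuous data a value equal to its LLOQ counts as quantified
#' (censoring is strict, \eqn{w < c}). For count data the model limit is
#' inclusive (\eqn{z \le c}); a printed token \code{"<v"} therefore
#' corresponds to model limit \eqn{c = v - 1}. The \code{printed} limits keep
#' the reported bounds, which drive the half-LLOQ imputation of
#' \code{\link{fit_si}}; the model-scale \code{limits} enter the censored
#' likelihood.
#'
#' @param quantified numeric vector of quantified observations.
#' @param limits numeric vector of model-scale LLOQs, strictly increasing,
#'   all non-negative. May be empty (no censoring).
#' @param counts integer vector of censored counts, one per limit.
#' @param printed reported limit values (defaults to \code{limits}); used for
#'   simple imputation. Same length and ordering as \code{limits}.
#' @return An object of class \code{"censored_sample"} with elements
#'   \code{quantified}, \code{limits}, \code{counts}, \code{printed} and the
#'   derived sizes \code{n}, \code{k}, \code{N}.
#' @examples
#' censored_sample(c(6.0, 6.2, 7.1), limits = c(5.0, 5.5), counts = c(2, 3))
#' @export
censored_sample <- function(quantified, limits = numeric(), counts = integer(),
                            printed = limits) {
  quantified <- as.numeric(quantified)
  limits <- as.numeric(limits)
  counts <- as.integer(counts)
  printed <- as.numeric(printed)
  if (length(limits) != length(counts))
    stop("'limits' and 'counts' must have the same length")
  if (length(printed) != length(limits))
    stop("'printed' must have one entry per limit")
  if (anyNA(quantified) || anyNA(limits) || anyNA(counts))
    stop("missing values are not allowed")
  if (any(limits < 0)) stop("limits must be non-negative")
  if (length(limits) > 1 && any(diff(limits) <= 0))
    stop("limits must be strictly increasing")
  if (any(counts < 0)) stop("censored counts must be non-negative")
  if (length(limits) && length(quantified) && any(quantified < limits[1]))
    stop("quantified values below the smallest limit are inconsistent ",
         "with the censoring scheme")
  structure(
    list(quantified = quantified, limits = limits, counts = counts,
         printed = printed,
         n = length(quantified), k = sum(counts),
         N = length(quantified) + sum(counts)),
    class = "censored_sample")
}

#' @export
print.censored_sample <- function(x, ...) {
  cat(sprintf("Censored sample: N = %d (%d quantified, %d censored, %.2f%%)\n",
              x$N, x$n, x$k, 100 * x$k / max(x$N, 1)))
  if (length(x$limits)) {
    cat("  LLOQs (model scale):\n")
    for (i in seq_along(x$limits))
      cat(sprintf("    c_%d = %g (reported < %g): k = %d\n",
                  i, x$limits[i], x$printed[i], x$counts[i]))
  } else cat("  no limits of quantification\n")
  invisible(x)
}

#' Distribution specification
#'
#' The three measurement models supported by the censored-sample likelihood:
#' normal (mean \code{mean}, standard deviation \code{sd}), exponential
#' (rate \code{rate}, mean \code{1/rate}) and Poisson (rate \code{rate},
#' mean \code{rate}).
#'
#' @param family one of \code{"normal"}, \code{"exponential"}, \code{"poisson"}.
#' @param mean,sd normal parameters (\code{sd > 0}).
#' @param rate exponential or Poisson rate (\code{rate > 0}).
#' @return A list of class \code{"dist_spec"}.
#' @examples
#' dist_spec("normal", mean = 5.8, sd = 1)
#' dist_spec("poisson", rate = 4)
#' @export
dist_spec <- function(family = c("normal", "exponential", "poisson"),
                      mean = NULL, sd = NULL, rate = NULL) {
  family <- match.arg(family)
  if (family == "normal") {
    if (is.null(mean) || is.null(sd)) stop("normal family needs 'mean' and 'sd'")
    if (!is.finite(sd) || sd <= 0) stop("'sd' must be positive")
    params <- list(mean = as.numeric(mean), sd = as.numeric(sd))
  } else {
    if (is.null(rate)) stop(sprintf("%s family needs 'rate'", family))
    if (!is.finite(rate) || rate <= 0) stop("'rate' must be positive")
    params <- list(rate = as.numeric(rate))
  }
  structure(list(family = family, params = params), class = "dist_spec")
}

#' Mean of a distribution specification
#'
#' The mean-scale value all estimators and intervals target: \eqn{\mu} for
#' normal, \eqn{1/\lambda} for exponential, \eqn{\lambda} for Poisson.
#'
#' @param spec a \code{\link{dist_spec}}.
#' @return numeric scalar.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
         normal = spec$params$mean,
         exponential = 1 / spec$params$rate,
         poisson = spec$params$rate)
}

## random draws from a dist_spec; relies on the caller having set the RNG state
rdist <- function(spec, n) {
  switch(spec$family,
         normal = stats::rnorm(n, spec$params$mean, spec$params$sd),
         exponential = stats::rexp(n, spec$params$rate),
         poisson = stats::rpois(n, spec$params$rate))
}

#' Apply lower limits of quantification to raw values
#'
#' Turns a vector of fully observed draws into a \code{\link{censored_sample}}
#' by comparing each value against its applicable LLOQ. With one limit every
#' value is compared against it; with two limits the half-split design is
#' used: the first \eqn{N/2} values are compared against \eqn{c_1} and the
#' second \eqn{N/2} against \eqn{c_2} (two laboratories with different
#' detection limits). Continuous values are censored when strictly below
#' their limit; counts (\code{discrete = TRUE}) when less than or equal to it.
#'
#' @param values numeric vector of raw draws.
#' @param limits 0, 1 or 2 model-scale LLOQs (ascending).
#' @param assignment \code{"auto"} (single limit for m = 1, half-split for
#'   m = 2), \code{"single"} or \code{"half-split"}.
#' @param discrete logical; use the inclusive censoring convention for counts.
#' @return A \code{\link{censored_sample}}; zero-count limits are retained so
#'   the scheme is preserved even when nothing is censored.
#' @examples
#' censor_dataset(c(4.0, 6.0, 4.0, 6.0), limits = c(5.0, 5.5))
#' @export
censor_dataset <- function(values, limits,
                           assignment = c("auto", "single", "half-split"),
                           discrete = FALSE) {
  assignment <- match.arg(assignment)
  values <- as.numeric(values)
  limits <- as.numeric(limits)
  m <- length(limits)
  if (m == 0) return(censored_sample(values))
  if (m > 2) stop("censoring schemes with more than 2 limits are not supported")
  if (assignment == "auto") assignment <- if (m == 2) "half-split" else "single"
  if (assignment == "single" && m != 1)
    stop("'single' assignment requires exactly one limit")
  if (assignment == "half-split") {
    if (m != 2) stop("half-split assignment requires exactly two limits")
    if (length(values) %% 2 != 0)
      stop("half-split assignment requires an even number of values")
  }
  applicable <- if (assignment == "single") rep(limits, length(values))
                else rep(limits, each = length(values) / 2)
  below <- if (discrete) values <= applicable else values < applicable
  counts <- vapply(seq_len(m),
                   function(i) sum(below & applicable == limits[i]), integer(1))
  censored_sample(values[!below], limits = limits, counts = counts)
}

#' Theoretical censored proportion of a censoring scheme
#'
#' Probability that an observation falls below its LLOQ, per limit and
#' averaged over the design. For the half-split two-limit design each limit
#' applies to half the sample, so the overall proportion is the unweighted
#' mean of the per-limit CDF values \eqn{F(c_i)}. For the Poisson family the
#' inclusive convention gives \eqn{F(c) = P(Z \le c)}.
#'
#' @param spec a \code{\link{dist_spec}}.
#' @param limits numeric vector of 0, 1 or 2 model-scale LLOQs.
#' @return list with \code{per_limit} (vector of \eqn{F(c_i)}) and
#'   \code{overall} (design-weighted mean; 0 when there are no limits).
#' @examples
#' theoretical_censored_proportion(dist_spec("poisson", rate = 4), 2)
#' @export
theoretical_censored_proportion <- function(spec, limits) {
  stopifnot(inherits(spec, "dist_spec"))
  limits <- as.numeric(limits)
  if (length(limits) == 0)
    return(list(per_limit = numeric(), overall = 0))
  if (any(limits < 0)) stop("limits must be non-negative")
  F <- switch(spec$family,
    normal = stats::pnorm(limits, spec$params$mean, spec$params$sd),
    exponential = stats::pexp(limits, spec$params$rate),
    poisson = stats::ppois(floor(limits), spec$params$rate))
  list(per_limit = F, overall = mean(F))
}
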