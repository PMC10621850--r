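---
title: "Estimating means under lower limits of quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating means under lower limits of quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lloqci)
```

## The problem

Every analytical assay has a lower limit of quantification (LLOQ): below a
threshold $c$ the analyte cannot be quantified with acceptable precision, and
the laboratory reports only "$< c$". When several laboratories with different
LLOQs contribute to one study, the data are left-censored at multiple fixed
thresholds (type I censoring): the sample of size $N = n + k$ consists of $n$
quantified values $w$ and, for each limit $c_1 < \dots < c_m$, a count $k_i$
of observations known only to lie below $c_i$.

`lloqci` estimates the distribution mean from such data for three measurement
models — normal, exponential and Poisson — and quantifies the precision of
the estimate with two kinds of 95% confidence intervals. A Monte Carlo engine
evaluates how both intervals behave as the censored proportion grows.

## The censored-sample likelihood

The censored-sample (CS) method treats unquantified observations as censored
contributions to the likelihood,

$$L = \prod_{i=1}^{m} \Big[ F(c_i)^{k_i} \prod_{j=1}^{n_i} f(w_{j,i}) \Big],$$

with family-specific $F$ and $f$. The density part does not depend on which
laboratory a quantified value came from, so only the pooled quantified values
and the per-limit censored counts enter the fit; the laboratory assignment of
quantified values is not stored.

Setting the derivative of $\log L$ to zero gives the score equations solved
by `fit_cs()`:

* **Normal.** Two coupled equations in $(\mu, \sigma)$ involving the inverse
  Mills ratio $\phi(a)/\Phi(a)$ at $a_i = (c_i - \mu)/\sigma$. They are
  solved by a damped Newton iteration on $(\mu, \log\sigma)$ — the log
  parameterization keeps $\sigma > 0$, and steps are halved until the score
  norm decreases, which prevents overshooting when the starting value is far
  from the optimum at heavy censoring. The start is the simple-imputation
  moment estimate, which is always computable. If the iteration still fails,
  the censored log-likelihood is maximized derivative-free (Nelder–Mead) and
  the result polished by damped Newton. Convergence is declared at score
  residual $< 10^{-8}$ or parameter change $< 10^{-10}$, within 200
  iterations.
* **Exponential.** The score
  $g(\lambda) = \sum_i k_i c_i / (e^{\lambda c_i} - 1) + n/\lambda - \sum y$
  is strictly decreasing with a sign change on $(0, \infty)$ whenever
  $n \ge 1$, so the MLE is the unique root. It is found by bracket expansion
  around $1/\bar w_{SI}$ followed by Brent root-finding; the bracket
  guarantees convergence. The mean-scale estimate is $1/\hat\lambda$.
* **Poisson.** The score
  $g(\lambda) = -n + \tfrac{1}{\lambda}\sum z - \sum_i k_i
  \, P(Z = c_i)/P(Z \le c_i)$ is solved the same way, started from the
  simple-imputation mean.

With no censored observations each fit reduces to the closed-form
complete-data MLE (the normal variance uses the $N$-denominator, as the
likelihood implies); the test suite checks this reduction to $10^{-8}$, and
checks on random instances that the solutions beat a fine likelihood grid
and that score residuals at the solution are below $10^{-6}$.

### Censoring conventions

For continuous data a value equal to its LLOQ is treated as quantified;
censoring is strict ($w < c$). For counts the likelihood sums the Poisson
mass up to and including the limit, so censoring is inclusive
($z \le c$) and a reported token "$< v$" corresponds to model limit
$c = v - 1$. `read_censored()` applies this mapping only when the data are
declared Poisson. A value exactly equal to a continuous LLOQ has probability
zero under the model, so the choice of convention there is immaterial for
inference but fixed for reproducibility.

## The simple-imputation comparator

Simple imputation (SI) replaces every unquantified observation by half its
reported LLOQ, $s_i = c_i/2$, and applies complete-data formulas. For counts
the reported exclusive bound is halved ("$< 3$" imputes 1.5); the imputed
value need not be an integer because only the mean is consumed. SI is
included deliberately as the widely used ad hoc reference: it is biased by
construction, and the simulation engine makes the size of that bias — and
its effect on interval coverage — measurable.

## Confidence intervals

`ci_parametric()` evaluates the classical complete-data intervals at the
censored-data estimates:

$$\hat\mu \pm z_{0.975}\,\hat\sigma/\sqrt N, \qquad
\Big[\tfrac{2N/\hat\lambda}{\chi^2_{2N;0.975}},
     \tfrac{2N/\hat\lambda}{\chi^2_{2N;0.025}}\Big], \qquad
\hat\lambda \pm z_{0.975}\sqrt{\hat\lambda/N},$$

for normal, exponential (on the mean scale $1/\lambda$) and Poisson data,
with $N$ the total sample size including censored records. These intervals
ignore the information loss from censoring; how fast their coverage degrades
is one of the package's main outputs.

`ci_bca()` builds Efron's bias-corrected accelerated (BCa) bootstrap
interval. Resamples of size $N$ are drawn with replacement from all $N$
records — censored records resample like any other, unstratified with
respect to their LLOQ — and the estimator is recomputed on each. For SI,
resampling happens first and imputation second. The interval endpoints are
empirical quantiles of the replicate distribution at levels adjusted by the
bias-correction $z_0$ and acceleration $a$:

$$\alpha_{adj} = \Phi\!\Big(z_0 + \frac{z_0 + z_\alpha}
  {1 - a (z_0 + z_\alpha)}\Big).$$

Numerical choices, fixed so that an independent straight-from-formula
implementation reproduces the endpoints exactly:

* $z_0 = \Phi^{-1}$ of the fraction of replicates strictly below the point
  estimate, with ties counted as half — ties occur routinely for discrete
  (Poisson) statistics, and halving avoids a systematic one-sided bias;
* $a$ from the standard jackknife third-moment formula over leave-one-out
  estimates on the $N$ original records;
* endpoints by type-6 inverse-ECDF quantile interpolation, so they are
  always (interpolated) order statistics of the replicates, never
  extrapolations;
* replicates on which the fit fails (for example an all-censored resample)
  are dropped and counted, never redrawn — redrawing until success would
  bias the bootstrap distribution. More than 50% failures aborts the
  interval. If all replicates fall on one side of the estimate, the counted
  fraction is clamped to $[1/(B'+1),\ B'/(B'+1)]$ with a warning.

With $z_0 = a = 0$ the construction reduces to the plain percentile
interval, which the tests verify, along with exact agreement with the
independent implementation and invariance under monotone transformation when
$a$ is fixed at zero.

## The Monte Carlo engine

`scenario()` describes one simulation cell: generating distribution,
assumed analysis family (these differ in misspecification runs), sample
size, censoring scheme, and replication counts. `scenario_registry()` holds
the full study design: N(5.8, 1), Exp(0.095) and Poi(4) at $N = 100$, with
one- and two-LLOQ schemes targeting censored proportions of 0%, ~20%, ~50%
and ~65.5% (for Poisson, the nearest proportions reachable with integer
limits: 23.81%–70.70%). Limits are fixed by the design; for the exponential
two-limit 20% cell the pair (1.11, 3.75) is used, whose average CDF value is
20.0%.

With two limits, generation uses the half-split design: the first $N/2$
draws are compared against $c_1$ and the second $N/2$ against $c_2$, with no
shuffling — two laboratories of equal size with different detection limits.
Bootstrap resampling remains unstratified, mimicking the pooled analysis.

Per replication the engine draws data, censors, fits CS and/or SI under the
assumed family, and builds the requested intervals.
`evaluate_metrics()` then reports coverage (share of intervals containing
the true mean), mean and SD of the interval width, bias, and
$\mathrm{RMSE} = \sqrt{\smash{(\bar{\hat\beta}-\beta)^2 +
\tfrac{1}{B-1}\sum_r (\hat\beta_r - \bar{\hat\beta})^2}}$, so that
$\mathrm{RMSE}^2 = \mathrm{bias}^2 + \widehat{\mathrm{var}}$ holds as an
identity (tested to $10^{-10}$). Coverage for exponential scenarios is
evaluated against the true mean $1/\lambda$, the scale on which the interval
is built.

Reproducibility: the master seed spawns one substream per replication (and a
second for its bootstrap), so any single replication can be reproduced in
isolation and results do not depend on execution order.

### Problem sizes

The published-scale study uses $B = R_b = 5500$, which is deliberate
overkill for stabilizing third-decimal summaries but makes
bootstrap-inclusive cells expensive ($\approx 3\times 10^7$ fits per cell).
The package's default verification profile therefore runs
bootstrap-inclusive properties at $B = 500$, $R_b = 999$ — enough to
separate coverage differences of a few percentage points by more than three
binomial standard errors — and reserves $B = 5500$ for the deterministic-fit
cells and the use-case bootstrap, where a single interval costs only
$R_b + N$ fits. Full-scale runs remain available through the scenario
configuration.

## What the generator does and does not emulate

The generator reproduces the study conditions exactly: i.i.d. draws from a
single common distribution, fixed known limits, equal laboratory sizes in
the two-LLOQ design. Real LLOQ data often violate these assumptions —
between-laboratory heterogeneity, uncertain or estimated LLOQs, unequal
batch sizes, non-i.i.d. structure. Passing tests therefore demonstrate
correctness of the estimators and intervals under the stated model, not
robustness to those violations; the misspecification facility (generating
family ≠ assumed family) probes only one kind of departure.

## Known limitations and design notes

* The exponential parametric interval is exact for complete data only;
  under censoring all three parametric intervals are approximations whose
  coverage the engine quantifies.
* Published normal-family parametric intervals for the bundled uric-acid
  data imply a dispersion estimate a few percent larger than the likelihood
  optimum $(\hat\mu, \hat\sigma) = (5.177, 1.135)$, which direct
  maximization of the censored likelihood confirms. The package reports the
  interval implied by the ML parameters; `cmd_usecase()` flags the caveat in
  a footnote. The same few-percent dispersion gap propagates to published
  normal-family simulation summaries (coverage and mean width), which sit
  slightly above what the exact ML solution yields; the package's own
  simulation output is internally consistent with its estimator, and the
  acceptance suite records the comparison against the published values at
  their stated tolerances.
* Estimation supports any number of limits $m$; the half-split *generator*
  supports at most two, as in the study design.
* Right- or interval-censoring, time-dependent censoring, Weibull and
  log-normal models, and laboratory heterogeneity are out of scope.

## A worked example

```{r example, eval = FALSE}
library(lloqci)
s <- read_censored(usecase_path("ferritin"), family = "exponential")
fit_cs(s, "exponential")          # mean 96.218 ng/ml
ci_parametric(fit_cs(s, "exponential"))  # [72.655, 133.504]
ci_bca(s, "exponential", "cs", Rb = 5500, seed = 1)
cmd_usecase(Rb = 5500)            # the full three-dataset table
```
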