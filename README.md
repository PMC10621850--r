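# lloqci

Maximum likelihood estimation of distribution means — with honest confidence
intervals — for measurements affected by one or more **lower limits of
quantification (LLOQ)**.

Assays cannot quantify an analyte below their LLOQ; such observations are
reported only as "< c". When several laboratories with different LLOQs
contribute to one study, the sample is left-censored at multiple fixed
thresholds: $N = n + k$ observations, of which $n$ are quantified values $w$
and $k_i$ are known only to lie below limit $c_i$ ($c_1 < \dots < c_m$).
`lloqci` is for biostatisticians and lab scientists who need defensible mean
estimates and interval estimates from such data instead of ad hoc
substitution.

## What it implements

**Censored-sample (CS) maximum likelihood** for normal, exponential and
Poisson data, maximizing

$$L = \prod_{i=1}^m \Big[F(c_i)^{k_i} \prod_{j=1}^{n_i} f(w_{j,i})\Big]$$

via the family-specific score equations (damped Newton for the normal
$(\mu,\sigma)$ system; guaranteed bracketed root-finding for the monotone
exponential and Poisson scores). The **simple-imputation (SI)** comparator —
replace each censored value by half its LLOQ, then use complete-data
formulas — is included to quantify how much that common shortcut costs.

**Two 95% confidence intervals for the mean**, on the mean scale
($\mu$, $1/\lambda$, $\lambda$):

- *parametric*: $\hat\mu \pm z_{0.975}\hat\sigma/\sqrt N$;
  $[\,(2N/\hat\lambda)/\chi^2_{2N;0.975},\ (2N/\hat\lambda)/\chi^2_{2N;0.025}\,]$;
  $\hat\lambda \pm z_{0.975}\sqrt{\hat\lambda/N}$;
- *BCa bootstrap*: Efron's bias-corrected accelerated interval from
  unstratified resamples of all $N$ records, with jackknife acceleration.

**A Monte Carlo engine** (`scenario()`, `run_study()`) that measures
coverage proportion, interval width, bias and RMSE of both estimators ×
both intervals under configurable censoring designs, including the
half-split two-LLOQ design and distributional misspecification.

## Worked example

```r
library(lloqci)
s <- read_censored(usecase_path("ferritin"), family = "exponential")
s
#> Censored sample: N = 42 (19 quantified, 23 censored, 54.76%)
#>   LLOQs (model scale):
#>     c_1 = 80 (reported < 80): k = 9
#>     c_2 = 100 (reported < 100): k = 14

fit_cs(s, "exponential")
#> CS fit (exponential family): mean estimate 96.218
#>   parameters: rate = 0.0103931
#>   N = 42 (23 censored); converged: TRUE

ci_parametric(fit_cs(s, "exponential"))
#> 95% parametric CI: [72.655, 133.504] (width 60.849)

ci_bca(s, "exponential", "cs", Rb = 5500, seed = 42)
#> 95% bca CI: [73.7605, 126.871] (width 53.1106)
#>   z0 = 0.02231, acceleration = 0.0195, replicates used = 5500
```

The CS mean (96.2 ng/ml) uses the censored records as probability mass below
their limits; half-LLOQ imputation (`fit_si()`) gives 100.2 ng/ml on the
same data, and the simulation engine shows that such imputation bias widens
with the censored fraction. `cmd_usecase()` prints the full table — both
estimators, both intervals, all three datasets — and
`cmd_fit()` does the same for your own file (one value per line, censored
records as `<c`). A thin command-line wrapper lives at
`inst/cli/lloq.R` (`fit`, `usecase`, `simulate` subcommands).

A coverage experiment in three lines:

```r
cfg <- scenario("normal", list(mean = 5.8, sd = 1), N = 100,
                limits = c(5.94, 6.49), B = 500, Rb = 999, seed = 1)
run_study(list(cfg))   # coverage/width/bias/RMSE per method x interval
```

At ~65% censoring the parametric normal interval covers the true mean in
only ~79% of replications, while the CS-based BCa interval stays close to
the nominal 95% — the package's central practical message.

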