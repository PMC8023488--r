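# wtexpd

Fitting and comparison of the **Weibull-truncated exponential distribution
(W-TEXPD)**, a left-truncated lifetime model for reliability and
environmental data that sit above a lower threshold — component failure
times, fatigue lives, contaminant concentrations above a detection limit,
losses above a deductible.

The model has density

```
g(x) = β (θ/α)^β (x − τ)^{β−1} exp[ −{θ(x − τ)/α}^β ],   x > τ,
```

with threshold `τ`, shape `β > 0` and scale components `α`, `θ` that are
identifiable only through the ratio `λ = α/θ`. It is a threshold Weibull:
`β < 1`, `= 1`, `> 1` give decreasing, constant and increasing hazards, and
the exponential (`τ = 0, θ = 1, β = 1`) and three-parameter Weibull
(`θ = 1`) are special cases. The package provides

* the analytic functions `dwtexpd`, `pwtexpd`, `swtexpd`, `qwtexpd`,
  `rwtexpd`, `hwtexpd`, `chwtexpd`, `dwtexpd_order`, raw/central moments,
  skewness, kurtosis and Shannon entropy;
* maximum-likelihood fitting (`fit_wtexpd`) with analytic score
  (`wtexpd_score`), observed Fisher information (`wtexpd_fisher_info`) and
  normal / log-normal Wald intervals (`wtexpd_confint`);
* baseline Weibull, Gamma, Exponential and threshold-exponential fits and a
  five-model comparison (`compare_models`) by AIC/BIC and the
  Kolmogorov-Smirnov, Cramér-von Mises and Anderson-Darling statistics;
* a Monte-Carlo bias/MSE study of the estimators (`wtexpd_sim_study`);
* five classical benchmark datasets (`wtexpd_data`, `wtexpd_datasets`) and
  a command-line interface (`inst/cli/wtexpd.R`).

See `vignettes/wtexpd-methods.Rmd` for the model's derivation, the
corrected quantile/moment forms, the identifiability reduction and all
numerical conventions.

## Worked example

Fit the W-TEXPD to the classic ball-bearing fatigue data (millions of
revolutions to failure of 23 bearings) with the threshold at 16.25, and
compare it with the four baselines:

```r
library(wtexpd)
bb <- wtexpd_data("ball_bearings")
fit <- fit_wtexpd(bb, tau = 16.25)
fit
#> W-TEXPD fit (n = 23)
#>            tau   alpha   beta theta  lambda
#> estimate 16.25 61.8873 1.5218     1 61.8873
#> se        0.00  8.9014 0.2494     0  8.9014
#> logLik -112.9061   AIC 231.81   BIC 235.22
#> theta pinned (scale pair identifiable only through alpha/theta); its SE is reported as 0
```

The shape estimate `β ≈ 1.52 > 1` says the failure hazard increases with
accumulated revolutions — wear-out — and `λ ≈ 61.9` is the Weibull scale of
the lifetime above the threshold. Log-normal 95% intervals for the free
parameters:

```r
wtexpd_confint(fit, level = 0.95, method = "lognormal", parm = c("lambda", "beta"))
#>         estimate        se     lower     upper
#> lambda 61.887278 8.9014179 46.684285 82.041208
#> beta    1.521819 0.2493532  1.103803  2.098138
```

```r
compare_models(bb, tau = 16.25)
#> Model comparison for 'ball_bearings' (n = 23), ranked by AIC
#>        model   loglik k     aic     bic    ks   cvm    ad rank
#>        Gamma -113.027 2 230.054 232.325 0.123 0.039 0.216    1
#>      Weibull -113.689 2 231.377 233.648 0.151 0.058 0.329    2
#>      W-TEXPD -112.906 3 231.812 235.219 0.110 0.034 0.240    3
#>        TEXPD -115.578 1 233.157 234.292 0.233 0.240 1.270    4
#>  Exponential -121.439 1 244.879 246.014 0.307 0.537 2.814    5
```

The W-TEXPD attains the largest log-likelihood and the smallest KS and CvM
discrepancies; with its extra parameter penalized, AIC narrowly prefers the
two-parameter Gamma on this sample. The exponential, with its constant
hazard, is clearly inadequate (KS = 0.307).

The same operations are available from a shell:

```sh
Rscript inst/cli/wtexpd.R compare --dataset ball_bearings --tau 16.25
Rscript inst/cli/wtexpd.R simulate --lam 2 --beta 1.5 --n-list 20,50 --reps 200 --seed 1 --out table.csv
Rscript inst/cli/wtexpd.R datasets
```

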