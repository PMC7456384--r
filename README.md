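# csAUC — time-dependent cause-specific AUC under competing risks

`csAUC` estimates how well a baseline marker discriminates, at each point
in follow-up time, the subjects about to fail from a *specific* cause from
the subjects still event-free — the incident/dynamic cause-specific
AUC(t) for right-censored survival data with competing risks:

$$\mathrm{AUC}^{(j)}_t = \Pr\left(M_i > M_k \mid T_i = t,\ \delta_i = j,\ T_k > t\right),$$

where subject *i* is an incident case failing from cause *j* exactly at
*t* and subject *k* is a dynamic control surviving beyond *t*.  It is
aimed at biostatisticians evaluating prognostic markers (lab values, risk
scores) when subjects can fail from several mutually exclusive causes —
for example graft-related versus unrelated death after transplantation —
where treating competing events as censoring, or pooling all causes, gives
distorted accuracy estimates.

Two estimators are provided, sharing the empirical observed rank AUC
$A^{(j)}(t)$ (the proportion of case–control pairs at *t* in which the
case outranks the control):

* **cWMR** (`cwmr()`) — a local, nonparametric smoother: the unweighted
  mean of $A^{(j)}(t_k)$ over the cause-*j* event times within a window
  $(t-h, t+h)$, with the bandwidth chosen by leave-one-out
  cross-validation and an analytic variance based on a normal
  approximation of rank-transformed marker scores.
* **cFPL** (`cfpl()`) — a global, parametric-in-time model:
  $\mathrm{logit}\,\mathrm{AUC}^{(j)}_t = \beta_0 + \sum_l \beta_l t^{(p_l)}$
  with the full fractional-polynomial power set
  $\{-2,-1,-\tfrac12,\ln,\tfrac12,1,2\}$, fitted by maximising a binomial
  partial likelihood over the concordant/discordant pair counts at each
  event time, with a pairwise sandwich covariance
  $\hat\Sigma_1^{-1}\hat\Sigma_2\hat\Sigma_1^{-1}/n$ and delta-method
  intervals.

A simulation engine (`scenario_config()`, `simulate_crs()`,
`run_study()`) generates competing-risks data with bivariate-normal and
mixture marker–time dependence and exact numerically integrated truth
curves (`true_auc()`), so bias, bootstrap/analytic standard errors and
coverage can be studied end to end.  See the methods vignette
(`vignettes/cause-specific-auc.Rmd`) for the model details and design
choices.

## Worked example

```r
library(csAUC)

s <- simulate_crs(scenario_config("S1"), n = 400, seed = 2024)
s
#> Competing-risks sample: 400 subjects, J = 2 causes
#>   censored: 127 (31.8%)
#>   cause 1 events: 125
#>   cause 2 events: 148
#>   follow-up: 0.03784 .. 2.522
#>   marker:    -2.861 .. 3.058

curve_w <- cwmr(s, cause = 1, times = exp(seq(-1.5, 0, 0.3)),
                ci_level = 0.9)
curve_w
#> cWMR estimate of cause-1 incident/dynamic AUC(t)  [n = 400]
#>   bandwidth h = 0.1591
#>   6 time point(s), 90% pointwise CIs
#>
#>    time estimate      se  lower  upper
#>  0.2231   0.8454 0.02448 0.8051 0.8857
#>  0.3012   0.8324 0.02561 0.7903 0.8746
#>  0.4066   0.8194 0.02612 0.7764 0.8624
#>  0.5488   0.7997 0.03165 0.7476 0.8518
#>  0.7408   0.7198 0.04659 0.6431 0.7964
#>  1.0000   0.7290 0.05478 0.6389 0.8191

fit <- cfpl(s, cause = 1)
predict(fit, times = exp(seq(-1.5, 0.3, 0.6)), se.fit = TRUE,
        ci_level = 0.9)
#> cFPL estimate of cause-1 incident/dynamic AUC(t)  [n = 400]
#>   4 time point(s), 90% pointwise CIs
#>
#>    time estimate      se  lower  upper
#>  0.2231   0.8488 0.03077 0.7910 0.8928
#>  0.4066   0.8134 0.03076 0.7574 0.8588
#>  0.7408   0.7223 0.03967 0.6526 0.7826
#>  1.3499   0.6532 0.11495 0.4498 0.8127

true_auc(scenario_config("S1"), exp(seq(-1.5, 0.3, 0.6)))
#> [1] 0.8334903 0.7714038 0.7161988 0.6716905
```

Under this scenario the marker is negatively correlated with the log event
time of cause 1 ($\rho = -0.7$), so discrimination is strong early
(true AUC 0.833 at $t = e^{-1.5}$) and decays toward 0.67 by
$t = e^{0.3}$; both estimators track that decay within their standard
errors, and the intervals widen as risksets thin out.  For cause 2 the
marker is independent of the event time and both estimated curves sit near
the null value 0.5.

Data files are plain delimited tables with header columns for time,
status (0 = censored, 1..J = cause) and marker: `read_crs()` /
`write_crs()`.  The same workflows are scriptable from a shell:

```sh
Rscript inst/cli/csauc.R estimate --input data.csv --method both \
    --cause all --ci 0.95 --out results/
Rscript inst/cli/csauc.R simulate --scenario S1 --n 500 --reps 100 \
    --boot 100 --method cwmr --seed 7 --out simdir/
```

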