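---
title: "Estimating time-dependent cause-specific AUC under competing risks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating time-dependent cause-specific AUC under competing risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The estimation problem

A baseline marker $M$ (a lab value, a fibrosis score, a model-based risk
score) is measured once, and subjects are then followed until one of $J$
mutually exclusive causes of failure occurs or follow-up is censored.  The
observed data per subject are $Z = \min(T, C)$, the event indicator
$\delta \in \{0, 1, \dots, J\}$ ($0$ = censored), and $M$.  The question
this package answers is *how well the marker discriminates, at each time
$t$, the subjects about to fail from a specific cause from the subjects
still event-free*.  The estimand is the incident/dynamic cause-specific
AUC,
$$
\mathrm{AUC}^{(j)}_t \;=\;
\Pr\!\left(M_i > M_k \mid T_i = t,\ \delta_i = j,\ T_k > t\right),
$$
where case $i$ fails from cause $j$ exactly at $t$ (incident case) and
control $k$ survives beyond $t$ (dynamic control).  Treating competing
events as ordinary censoring, or merging all causes into a composite
endpoint, distorts this quantity; stratifying the riskset by cause keeps
it interpretable.

The empirical building block is the observed rank AUC at an event time,
$$
A^{(j)}(t) \;=\; \frac{1}{d_t^{(j)} n_t}
\sum_{i \in \text{cases}} \sum_{k \in \text{controls}} 1\{M_i > M_k\},
$$
the proportion of case–control pairs at $t$ in which the case outranks the
control.  With continuous follow-up there is usually a single case per
event time, so $A^{(j)}$ jumps wildly between adjacent times and needs
smoothing.  The package offers two smoothers.

## The local estimator (cWMR)

`cwmr()` averages $A^{(j)}(t_k)$ over the cause-$j$ event times in an open
window $(t-h,\, t+h)$:
$$
\widehat{\mathrm{AUC}}^{(j)}_t \;=\;
\frac{1}{|N_t^{(j)}(h)|} \sum_{t_k \in N_t^{(j)}(h)} A^{(j)}(t_k).
$$
All members are weighted equally; the bandwidth $h$ is on the raw time
scale (e.g. years), so a neighbourhood is "everything within $h$ of $t$".

**Bandwidth selection.** `select_bandwidth()` minimises a leave-one-out
cross-validation criterion over a candidate grid: every cause-$j$ event
time is predicted by the neighbourhood average with itself removed, and
squared prediction errors are combined.  Two choices here were genuinely
open and are the package's own:

* *Weighting.* The squared errors are weighted by the riskset size
  $n_{t_k}$ (the binomial denominator of $A^{(j)}(t_k)$) and averaged.
  The unweighted criterion is dominated by the variance of the erratic
  small-riskset tail values, which makes it nearly flat in $h$; the
  selected bandwidth then jitters over an order of magnitude between
  replicates, which both biases mid-range estimates (occasional heavy
  oversmoothing against a skewed event-time density) and inflates their
  dispersion.  Precision weighting stabilises the minimiser without
  touching the estimator itself.
* *Unreachable event times.* A candidate bandwidth too small to give some
  isolated tail event a leave-one-out neighbour is scored only on the
  event times it can predict (hence the averaging, which keeps candidates
  comparable).  Requiring every event time to be predictable would force
  $h$ above the largest inter-event gap — i.e. tie the global bandwidth to
  the single sparsest tail event and oversmooth everywhere.

The default candidate grid is 15 log-spaced values between the 2nd and
50th percentile of the pairwise gaps of the cause-$j$ event times, which
spans clear under- to clear over-smoothing; ties in the criterion break
toward the smaller bandwidth.

**Variance.** The sampling variance of the neighbourhood mean combines a
per-time variance and cross-time covariances,
$$
V \;=\; \frac{1}{m^2}\Big[\textstyle\sum_i \mathrm{var}\,A^{(j)}(t_{(i)})
 + \sum_{i \ne k} \mathrm{cov}\big(A^{(j)}(t_{(i)}), A^{(j)}(t_{(k)})\big)\Big],
$$
with
$\mathrm{var}[A^{(j)}(t)] = \frac{n_t-1}{n_t}(P_1 - P_0^2) +
\frac{1}{n_t}P_0(1-P_0)$ and
$\mathrm{cov} = \frac{1}{n_t}[(P_2 - P_{2.0}) + (P_3 - P_{3.0})]$.
The placement probabilities are evaluated under a normal approximation:
marker values in each riskset are rank-transformed to normal scores
($\Phi^{-1}(\mathrm{rank}/(n+1))$, which cannot produce infinite scores),
case and control score distributions are summarised by empirical means and
SDs, and the probabilities are computed by 40-node Gauss–Hermite
quadrature.  $P_0$ and $P_1$ are the single- and double-control placement
probabilities at one time; across two times $t < s$, $P_2$ couples the two
cases through one shared control, and $P_3$ accounts for the case at $s$
serving as a dynamic control at $t$; $P_{2.0}, P_{3.0}$ are the matching
independence products.  When a time holds a single case its score SD is
unidentified; `cwmr()` substitutes the spread of the case scores across
the smoothing neighbourhood (the local case population), falling back to 1
(the score scale's own SD) when the neighbourhood is a singleton.  A
negative assembled $V$ (possible because the covariance sum is not forced
positive) is floored at zero with a warning.  Confidence intervals are
Wald on the AUC scale, clipped to $[0,1]$.

Two caveats are inherited from the estimator's theory: the smoothing bias
term is *not* estimated or corrected (intervals are centred at the
estimate), and the variance is conditional on the selected bandwidth, so
intervals do not reflect bandwidth-selection randomness.  In simulations
this shows up as mild undercoverage (high 70s to low 80s percent for
nominal 90%) at time points where the selected bandwidth is unstable.

## The global estimator (cFPL)

`cfpl()` models the whole trajectory parametrically on the logit scale
with a degree-7 fractional polynomial in $t$,
$$
\mathrm{logit}\,\mathrm{AUC}^{(j)}_t(\beta) \;=\; \beta_0 +
\sum_{l=1}^{7} \beta_l\, t^{(p_l)},\qquad
(p_1,\dots,p_7) = (-2, -1, -\tfrac12, 0, \tfrac12, 1, 2),
$$
with $t^{(0)} \equiv \ln t$.  All seven powers enter simultaneously —
there is no best-subset search — and the link is the logit, so predictions
are always strictly inside $(0,1)$.  At each cause-$j$ event time the
number of controls outranked by the case, $n_1(t_{(H)})$, is binomial with
success probability $\mathrm{AUC}^{(j)}_{t_{(H)}}(\beta)$ given the
riskset, which yields the partial likelihood
$$
L(\beta) \;=\; \prod_{H}
\mathrm{AUC}_{t_{(H)}}^{n_1(t_{(H)})}
\left(1 - \mathrm{AUC}_{t_{(H)}}\right)^{n_2(t_{(H)})}.
$$
Marker ties count as discordant (the concordance indicator is strict),
matching the estimand's strict inequality; a half-credit variant is
available for the rank-AUC primitives via `ties = "half"`.

**Fitting.** The log partial likelihood is concave in $\beta$ (it has the
form of a binomial logistic likelihood in a fixed basis), and is maximised
by Newton–Raphson with the analytic score, warm-started by BFGS, from a
deterministic ladder of starts.  Convergence is declared when the maximum
absolute score component *per case–control pair* falls below $10^{-6}$.
Numerical safeguards: the raw basis spans $t^{-2}$ to $t^{2}$ and is
catastrophically ill-conditioned when event times sit far from 1, so time
is internally divided by the geometric mean event time and the
coefficients (and their covariance) are mapped back exactly through the
linear relation between the two bases; the linear predictor is clamped at
$\pm 35$ inside the likelihood and score so no logarithm of zero can
occur.

**Inference.** The partial likelihood is built from overlapping
case–control pairs, so it is not a regular likelihood and the inverse
information is invalid.  The coefficient covariance is the pairwise
sandwich $\widehat\Sigma_1^{-1}\widehat\Sigma_2\widehat\Sigma_1^{-1}/n$,
where $\widehat\Sigma_1$ is the averaged derivative of the per-pair score
contribution and $\widehat\Sigma_2$ the U-statistic covariance of the
symmetrised contributions $g_{ik} = (f_{ik}+f_{ki})/2$ over pair triples.
Because the active-pair condition $Z_k > Z_i$ is strict, both halves of
$g_{ik}$ are never active at once, which collapses the $O(n^3)$ definition
of $\widehat\Sigma_2$ to an exact $O(n h_j)$ computation.  The $1/n$
placement in the covariance follows the $\sqrt{n}$ rate of the coefficient
estimator; it was verified against bootstrap standard errors (analytic
0.029 vs bootstrap ~0.028 at the earliest study grid time, n = 500).
Pointwise variance for the curve uses the delta method,
$[\mathrm{AUC}(1-\mathrm{AUC})]^2\, x(t)^\top \widehat V x(t)$; intervals
are built on the linear-predictor scale and back-transformed by default
(always inside $(0,1)$), with AUC-scale Wald intervals as an option.
Curves are best read up to roughly the 90th percentile of the observed
times — `cfpl_curve()`'s default grid stops there — because the tail is
dominated by oversmoothing of the polynomial basis and risksets of a
handful of subjects.

# The synthetic-data generator

`simulate_crs()` draws from the three study conditions used throughout
the package's tests (`scenario_config()`):

* **S1**: $(\log T^{(1)}, M)$ bivariate normal with means 0, SDs 1 and
  correlation $\rho = -0.7$ — a marker monotonically predictive of the
  first cause (higher marker, earlier failure).
* **S2a / S2b**: two-component mixtures of bivariate normals with a
  latent class $G \sim \mathrm{Bernoulli}(0.2)$ in which the marker is
  uninformative for one subgroup, producing a non-monotone marginal
  marker–time relation (S2a's true curve rises to about $\log t = 0$ and
  then falls).
* In all presets $\log T^{(2)} \sim N(0,1)$ and $\log C \sim N(0,1)$,
  independent of the marker, so the competing-cause AUC is exactly 0.5 at
  every time — a built-in null.  Three exchangeable lognormal minima give
  about one third censored and one third events of each cause.

`true_auc()` computes the implied true curves exactly: the case marker law
at $t$ is $M \mid \log T^{(1)} = \log t$ (mixture components weighted by
their density at $\log t$), the control law is $M \mid T^{(1)} > t$
(components weighted by survival; within a component the conditional is a
closed-form normal times a normal tail factor), and the single remaining
integral over the marker is evaluated adaptively to absolute tolerance
$10^{-8}$.  The independent competing and censoring times cancel from the
truth.  `run_study()` wraps generation, estimation, bootstrap and
aggregation into table-style reports (Monte-Carlo mean, absolute relative
bias, bootstrap SE, analytic SE, coverage), with a master seed spawning
independent per-replicate and per-bootstrap streams.

What the generator does *not* emulate — and therefore what passing tests
do not certify for real data: covariate-dependent or informative
censoring, time-varying markers, discrete or heavily tied event times,
left truncation, and marker measurement error.  The estimators assume
censoring independent of the survival time and a baseline marker; on data
violating these, calibration results from the synthetic study do not
transfer.

# Problem sizes and reproducibility choices

The package's simulation checks run at a desk scale chosen to make the
Monte-Carlo error of each asserted quantity small relative to its
tolerance while keeping the default test run in minutes: 100 replicates of
$n = 500$ for the Scenario-1 table reproduction and coverage summaries
(the published study used 500 replicates with 200 bootstrap draws; the
full scale remains available through `run_study()` arguments), 40
replicates with 80 bootstrap draws for the analytic-vs-bootstrap SE
comparison, and $10^5$-subject draws for generator moment checks.  At 100
replicates the MC standard error of a mean AUC is about 0.003 at the
earliest grid time and 0.015–0.022 at the two largest times (where the
per-replicate SD reaches 0.15–0.22), which is worth remembering when
comparing small mean deviations at the tail.

Other numerical choices, in one place: rank ties get average ranks before
the normal-scores transform; dynamic controls require $Z_k > t$ strictly
(a subject censored exactly at $t$ is not a control); tied cause-$j$ event
times form one neighbourhood member whose $A^{(j)}$ already averages the
tied cases; event times whose riskset has no controls (only possible at
the sample maximum) are dropped from smoothing and contribute empty
records to the partial likelihood; empty neighbourhoods yield `NA` curve
points with a warning rather than silently widened windows; and all
Monte-Carlo utilities restore the caller's RNG state.

# Known limitations

* cWMR intervals ignore bandwidth-selection variability and smoothing
  bias; expect mild undercoverage where the criterion is flat (sparse
  mid/late follow-up).
* cFPL oversmooths at both ends of the time range; tail intervals are
  honest about this mainly through their width.
* The cross-time covariance components $P_2, P_{2.0}, P_3, P_{3.0}$ rest
  on the bivariate-normal score approximation; they are validated
  empirically against the bootstrap, not derived exactly.
* No missing-data handling: rows with missing outcome or marker are
  rejected at input, by design.
* Eight coefficients need a reasonable number of distinct event times;
  `cfpl()` warns below eight, and sparse-tail fits can fail to reach the
  score tolerance (flagged on the object, with the best state returned).
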