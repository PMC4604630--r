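# misens

Sensitivity analysis for multiple imputation when the outcome may be
**missing not at random (MNAR)**, via the selection-model
delta-weighting approach — together with the Monte-Carlo machinery to
evaluate how (and how badly) that approach behaves.

The package is aimed at biostatisticians and epidemiologists who have
imputed a single partially observed outcome $Y$ under the standard MAR
assumption and want to probe how their estimates move under departures
from MAR, and at methodologists studying the weighting estimator itself.

## The method in brief

Missingness is modelled by a logistic selection model,

$$\operatorname{logit} \Pr(R = 1 \mid X, Y) = \alpha + \gamma X + \delta Y,$$

with $R = 1$ when $Y$ is observed. The sensitivity parameter $\delta$
is the log-odds change in the probability of observing $Y$ per unit of
$Y$ given the covariate $X$; $\delta = 0$ is MAR. After ordinary MAR
imputation ($m$ completed datasets, proper Bayesian draws), each
per-imputation estimate $\hat\theta_j$ gets an importance weight

$$\tilde w_j(\delta) = \exp\!\Big(-\delta \textstyle\sum_{i \in I_Y} y_{ij}\Big),
\qquad w_j = \tilde w_j \big/ \textstyle\sum_k \tilde w_k,$$

built from the sum of that imputation's imputed values, and the MNAR
estimate is $\hat\theta^{MNAR}(\delta) = \sum_j w_j \hat\theta_j$ with a
weighted within-plus-between variance. Weight diagnostics and a
graphical rule for choosing a plausible range of $\delta$ (max
normalised weight at most 0.5; at least five weights at or above $1/m$)
are included, as is a scenario-driven simulation framework that
reproduces the published evaluation of the estimator: the MAR-MI
estimate is stable in $m$, while the weighted estimate drifts with $m$
and single imputations come to dominate the weighting. See the
`delta-weighting` vignette for the full account.

## Worked example

Simulate a dataset of 500 subjects with a weakly MNAR outcome
($\delta = 0.2$, about 50% missing), then run the sensitivity analysis
at the generating $\delta$ with 100 imputations:

```r
library(misens)
d <- apply_mnar(sim_bivnorm(500, seed = 11), alpha = 0.12, gamma = 1,
                delta = 0.2, seed = 12)
fit <- misens(y ~ x, d, m = 100, delta = 0.2, seed = 13)
summary(fit)
#> m = 100 imputations; MNAR delta = 0.2; max normalised weight = 0.282
#>       estimand mechanism estimate     se   lower  upper within between
#>  marginal_mean       MAR   0.1237 0.0631 -0.0001 0.2475 0.0018  0.0022
#>  marginal_mean      MNAR   0.0420 0.0447 -0.0456 0.1295 0.0018  0.0001
#>   linear_slope       MAR   0.4304 0.0603  0.3122 0.5486 0.0015  0.0022
#>   linear_slope      MNAR   0.4941 0.0460  0.4039 0.5844 0.0014  0.0007
```

The data were generated with true marginal mean 0 and true slope 0.5.
The MAR-MI estimates are biased (mean 0.124, slope 0.430, as expected
when imputing under MAR from MNAR data); reweighting at the true
$\delta$ pulls both back towards the truth (mean 0.042, slope 0.494).
The maximum normalised weight, 0.28 against a uniform reference of
0.01, already shows the weighting concentrating — `plot(fit)` draws the
two weight diagnostics. The graphical $\delta$-range rule applied to
the same imputations:

```r
delta_range(fit)
#> delta-range selection (m = 100, max weight <= 0.5, >= 5 weights above 1/m)
#>   selected range: [-0.08, 0.42]
```

a range that here contains the generating value 0.2 — though on
regenerated datasets this containment is unreliable, which is part of
the point.

Simulation studies are driven by scenario objects (or YAML/JSON
configs via `read_scenario()`; `inst/cli/misens.R` wraps the same
functions for shell use):

```r
res <- run_scenario(scenario("continuous", n = 100, delta_gen = 1,
                             m_list = c(5, 10, 50), n_sims = 200, seed = 1))
res$summary   # mean estimate and Monte-Carlo SE per method x m x estimand
```

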