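---
title: "Methods: person-specific prediction intervals for repeated metabolite measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: person-specific prediction intervals for repeated metabolite measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaboScreen)
```

## The problem and the model

Repeated measurements of the same individuals let us ask whether a single
observation is unusual *for that person*, rather than unusual for the
population. MetaboScreen formalises this with a Gaussian random-intercept
model fitted independently to each metabolite. For individual $i$ at time
point $t$,

$$y_{it} = \beta_0 + \sum_{l=1}^{L} \beta_{1,l}\, x_{il} + s_i +
\epsilon_{it}, \qquad s_i \sim N(0, \sigma^2), \qquad
\epsilon_{it} \sim N(0, \sigma^2_\epsilon).$$

The covariates $x_{il}$ (sex, age, BMI, ...) absorb systematic cohort
structure; $s_i$ is a per-individual intercept shift, so $\sigma^2$ is the
between-individual variance and $\sigma^2_\epsilon$ the within-individual
fluctuation around the person's own level. Metabolites are modelled one at
a time: cross-metabolite correlation is deliberately out of scope, as is
any non-Gaussian response.

A modelling choice worth making explicit: the random effect is indexed by
individual only, constant over time. An effect drawn independently per
(individual, time point) would be statistically indistinguishable from the
residual $\epsilon_{it}$ — the sum $s_{it} + \epsilon_{it}$ of two
zero-mean Gaussians per cell is non-identifiable — so the per-individual
intercept is the only coherent reading, and it is what makes "this
person's typical level" a meaningful quantity.

## Priors and inference

Coefficients get independent $N(0, 10^{10})$ priors — flat for any
realistic concentration scale. Both variance components get independent
inverse-gamma priors with shape = scale = 0.001, a conventional weakly
informative choice (in one dimension it corresponds to an inverse-Wishart
with unit scale matrix and tiny degrees of freedom). All four
hyperparameters are exposed through `priorSpec()`.

With these priors every full conditional is conjugate, so the posterior is
sampled by a blocked Gibbs sampler (implemented in C++):

1. $(\beta_0, \beta_1)$ jointly from their multivariate-Gaussian
   conditional;
2. each $s_i$ from its univariate Gaussian conditional;
3. $\sigma^2$ and $\sigma^2_\epsilon$ from inverse-gamma conditionals.

A Metropolis–Hastings sampler targeting the same posterior would give the
same answers; the Gibbs form is tuning-free and fast. Draws use R's RNG
stream, so results are bit-reproducible from `mcmcConfig()$seed`, and the
implementation processes individuals and cells in a canonical sorted order
so that permuting input rows changes nothing.

Chains start overdispersed (coefficients from $N(0, 10 \cdot
\mathrm{var}(y))$, variances drawn from the prior), which the Gelman–Rubin
diagnostic requires to be meaningful. Because draws from
inverse-gamma(0.001, 0.001) occasionally land at astronomically large or
small values that would cause floating-point overflow in the first few
updates, initial variances are clamped to
$[10^{-4}, 10^{4}] \times \mathrm{var}(y)$ — a numerical guard only; the
window is far wider than any posterior mass.

Missing time points are simply absent from the likelihood; the design can
be unbalanced. Individuals need at least two observed time points per
metabolite (enforced at load time), otherwise "their own typical level" is
undefined.

## Cross-validated posterior-predictive flagging

Using a cell's own value to build the interval that judges it would
overfit, so prediction is done under hold-out. The observed cells of a
metabolite are split into `nFolds = 25` sub-datasets (4% of cells each for
a complete 150 × 4 panel). Two properties of the partition matter, and
both are enforced by construction in `makeFolds()`:

* **balance** — fold sizes differ by at most one cell (a greedy
  least-loaded assignment maintains this invariant exactly);
* **stratification by individual** — one individual's cells go to distinct
  folds, so when a cell is held out the individual's remaining time points
  stay in the training set and keep the posterior of $s_i$ informed.
  Without stratification the method would degrade toward a population
  interval, losing exactly the intra-individual character it is built for.

For each fold the model is refitted without the held-out cells, and each
held-out cell receives one predictive draw per retained posterior draw:
$\tilde y = \beta_0 + \sum_l \beta_{1,l} x_{il} + s_i + \epsilon$ with
$\epsilon \sim N(0, \sigma^2_\epsilon)$ drawn fresh per posterior draw.
The number of draws per cell is therefore exactly
`nChains × floor((nIter − burnIn)/thin)`.

Two intervals are computed from the draws and both are stored: the **W%
HPD interval** (the flagging boundary) and the equal-tailed **central
interval** (useful for display, e.g. scaling bars in a circos-style
figure). The HPD interval is found by exhaustive shortest-window search
over the sorted draws with window size $k = \lceil W/100 \cdot n \rceil$;
width ties are broken by the leftmost window so the result is
deterministic. A cell is flagged iff its observed value lies strictly
outside its HPD interval; cells with missing observations are never
flagged. De-duplication of individuals flagged at several time points
happens only in `summariseFlags()`, never in the cell-level table.

## Convergence monitoring

`psrf()` implements the classic univariate Gelman–Rubin statistic,
$\hat R = \sqrt{\{(n-1)/n \cdot W_v + B_v/n\}/W_v}$, computed on the
retained (thinned) draws, with $n{-}1$-denominator variances, no
split-chain step and no degrees-of-freedom correction — the plain form
that the conventional 0.9–1.05 acceptance window refers to.
`chainAutocorrelation()` supports the choice of thinning interval (the
default `thin = 2` is adequate for this conjugate sampler at cohort
sizes around 150).

Mixing slows as the cohort shrinks: the intercept and the mean of the
random effects are strongly coupled, and at $N \approx 25$ the default
iteration counts that converge instantly at $N = 150$ can leave
$\hat R > 1.1$. The PSRF report is the designed guard — if it fails,
increase `nIter` (the 24-individual example in the README needs
12000 iterations) rather than trusting the flags.

## The synthetic-cohort generator

`simulateCohort()` emulates a repeated-measures amino-acid cohort: 150
individuals, 4 monthly time points, age $\sim N(35, 12.6^2)$ years,
BMI $\sim N(24.1, 3.07^2)$ kg/m², sex $\sim$ Bernoulli(53/164), and
metabolite levels generated from the model above. The covariate
coefficients default to the reported plasma-alanine estimates
(sex $-4.41$, age $-0.57$, BMI $2.65$). The intercept and variance
components were never published, so the defaults —
$\beta_0 = 350$ µM, $\sigma^2 = 1600$, $\sigma^2_\epsilon = 900$
(i.e. between-individual sd 40 µM, within-individual sd 30 µM) — are this
package's own choices on a plasma-alanine-like scale, picked once as
physiologically plausible and documented as such. They are configurable
but deliberately not re-tuned.

What the generator does **not** emulate: missing-visit patterns,
non-Gaussian (skewed or heavy-tailed) concentration distributions, assay
batch effects, and correlation between metabolites. Passing simulation
benchmarks therefore demonstrates correct behaviour of the statistical
machinery under its own assumptions, not robustness to the full mess of
real assay data.

`injectInflation()` plants ground truth: `round(αN)` individuals (half-up
rounding; 10% and 20% of 150 are exact) each get one uniformly chosen time
point perturbed by an additive draw from $N(0, \sigma^2 \nu)$. The draw is
redrawn until the perturbed level lies outside the empirical [1%, 99%]
interval of all non-perturbed levels of that replicate — the perturbation
is meant to be detectable in principle, and this constraint defines
"detectable". With $\nu$ near zero the constraint is unsatisfiable and the
injector errors out after a bounded number of redraws (10000) rather than
looping forever.

`runScenario()` scores recovery at the individual level: a perturbed
individual counts as correctly flagged if flagged at *any* time point,
matching how flagged individuals are counted in cohort summaries; the
per-cell hit rate and the false-flag rate among unperturbed cells are also
reported. Replicate seeds are derived from the scenario master seed by a
fixed offset (`seed + 1009·r`), so any replicate can be reproduced in
isolation, bit-identically.

## Numerical and design notes

* **Sensitivity grid calibration.** Under the default generator, the
  measured sensitivity runs roughly 0.89–0.95 at α = 10% and 0.84–0.91 at
  α = 20%, *increasing* in ν. A generator with a larger
  $\sigma^2/\sigma^2_\epsilon$ ratio would saturate detection already at
  ν = 5 and show the opposite, slightly decreasing trend; since the
  variance components behind the published alanine fit are unknown, the
  defaults here were fixed a priori and kept. The α-direction
  (sensitivity degrades as the perturbed fraction grows, because
  perturbed cells contaminate the training folds and widen everyone's
  intervals) is reproduced robustly.
* **Problem sizes.** The bundled checks run the grid at 10 replicates
  with 2 chains × 2000 iterations and assess convergence on 4-chain fits
  of one replicate per scenario; these sizes were chosen as the smallest
  at which the Monte-Carlo error of a scenario mean (≈ 0.02) is clearly
  below the effects being checked. The definitive configuration remains
  30 replicates with 4 chains × 5000 iterations, 2500 burn-in, thin 2.
* **Quantiles.** The [1%, 99%] detectability band and the central
  intervals use R's default (type 7) empirical quantiles.
* **HPD preconditions.** At least $k \ge 2$ draws must fit in the window;
  in practice intervals are computed from hundreds to thousands of draws
  (the configuration floor is 100 retained draws per chain).
* **Collinear designs** (a constant covariate, or an exact linear
  combination) are rejected before sampling with an error naming the
  offending column, via a rank check of the per-observation design
  matrix.
* **Fold-assignment determinism.** `makeFolds()` is a deterministic
  function of (panel observedness pattern, `nFolds`, seed); it does not
  depend on the measured values, which is what makes the hold-out
  integrity property testable by corrupting a held-out value.

## Known limitations

* One metabolite at a time; a multivariate extension would borrow strength
  across correlated metabolites and is future work.
* Gaussian likelihood only; strongly skewed metabolites should be
  transformed before fitting.
* No multiplicity control across cells or metabolites: at W = 95 about 5%
  of null cells are flagged by construction. Raise `W` for stricter calls,
  or treat the `summariseFlags()` ≥ k-metabolites criterion as the
  cohort-level filter.
* The random-intercept model assumes a stable personal level plus
  exchangeable noise; slow drifts (ageing, seasonal diet) are absorbed
  partly into $\sigma^2_\epsilon$ rather than modelled.
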