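---
title: "Integrating aerial and ground waterfowl counts in a state-space model with conditional detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating aerial and ground waterfowl counts in a state-space model with conditional detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waterfowlSSM)
```

## The problem

Long-term waterfowl monitoring schemes rarely satisfy the protocol
requirements of formal detection-probability models such as N-mixture
models: replicate visits within a closed period, no double counting, stable
observers. What such schemes often do have is *two independent count
protocols* covering the same wetlands — here, monthly aerial surveys and
monthly ground counts of wintering ducks and coots over 40 wetland sites in
four protected areas, September to March, across more than four decades.
Because the two protocols constitute spatially and temporally replicated
counts of the same birds, their joint analysis can separate changes in true
abundance from changes in detection caused by observer turnover and protocol
changes.

`waterfowlSSM` implements a hierarchical Bayesian state-space model that
performs this integration, together with a synthetic-data generator that
reproduces the survey's structure so every stage of the pipeline is
testable without access to the count database itself.

## The model

**State process.** The abundance index $N_{s,t}$ of site $s$ in year $t$
(anchored to September) follows stochastic exponential growth,

$$N_{s,t} = N_{s,t-1}\, e^{r_{s,t}}, \qquad
  r_{s,t} \sim \mathrm{Normal}(r_{s,t-1}, \sigma^2_{\mathrm{year}}),$$

a first-order random walk on the growth rate expressing temporal
autocorrelation in waterfowl dynamics, with no density dependence. The
initial state is $\log N_{s,1} \sim \mathrm{Normal}(\mu,
\sigma^2_{\mathrm{site}})$. The walk is anchored at $r_{s,1} \sim
\mathrm{Normal}(0, \sigma^2_{\mathrm{year}})$; the first-year growth-rate
anchor is a package choice (the distribution of $r_{s,1}$ is not dictated by
the model's recursions) and is documented here once.

**Seasonality.** Within-winter variation enters through month effects
$\delta_m$ on the log scale, a random walk
$\delta_m \sim \mathrm{Normal}(\delta_{m-1}, \sigma^2_{\mathrm{month1}})$
with $\delta_1 = 0$ (September) fixed for identifiability, and year-specific
seasonal offsets $\alpha_{m,t} \sim \mathrm{Normal}(\delta_m,
\sigma^2_{\mathrm{month2}})$ capturing interannual variability of the
bell-shaped wintering pattern.

**Observation process.** Transformed counts carry heavy-tailed error,

$$\log(\mathrm{count}_{i,m,s,t}+1) \sim
  \mathrm{Student}\!\left(\log N_{s,t} + \alpha_{m,t} + \log p_{i,s,t},\;
  \sigma_i,\; \nu = 4\right),$$

with a separate scale $\sigma_i$ per method $i$ (aerial, ground). The low,
fixed degrees of freedom absorb the occasional gross counting error — a
missed roosting flock, double counts of flushed birds — that would distort a
log-Normal fit. $\sigma_i$ is parametrized as the *scale* of the Student
distribution (the standard parametrization in MCMC software), not its
variance.

**Conditional detection.** Detection enters as a logit-linear index
$p_{i,s,t} = \mathrm{logit}^{-1}(\beta_i + \gamma_{i,s,t})$ over eight
design cells: three aerial observer periods (years 1–27, 28–37, 38–44 at
full scale), four estimated ground cells (Marais de la Palissade, RNN
Camargue, and Tour du Valat before/after its 2006 switch from vantage-point
to flushing counts), and the fixed anchor — the Marais du Vigueirat ground
cell, whose linear predictor is exactly $\beta_2 = 0$, i.e. an index of
$0.5$. Only contrasts to this anchor are identified, so $p$ is a
*conditional* detection index, not an absolute detection probability; the
abundance index it corrects is likewise relative, which is sufficient for
trend inference. `ground_vigueirat` aside, aerial cells depend only on the
year and ground cells only on the protected area.

## Priors

The package ships weakly informative defaults: $\mathrm{Normal}(\log(\tilde
c + 1), 1.5^2)$ for $\mu$, where $\tilde c$ is the median observed count;
half-Normal(1) for every SD (on the log scale, innovation SDs above ~2 are
ecologically implausible); $\mathrm{Normal}(0, 1.5^2)$ for $\beta_1$ and all
$\gamma$, covering detection indices of roughly 0.05–0.95. A prior
predictive check (`priorPredictive()`) confirms these imply day-roost count
magnitudes from single birds to flocks of tens of thousands. Point-mass
priors (`pointMassPriors()`) reduce prior-predictive simulation to the plain
generator, which the tests exploit.

## Inference

The joint density is implemented twice, deliberately. `jointLogDensity()`
and the per-term functions (`growthRateLogpdf()`, `seasonalLogpdf()`,
`observationLogpdf()`, ...) are plain R and serve as the reference density;
`fitModel()` passes an independently written BUGS-language formulation of
the same model to JAGS (the seasonal walk in innovation form, which is the
identical density). The centred parametrization is used for sampling:
JAGS updates conditionals by Gibbs/slice steps, for which centring is
natural; funnel pathologies are a concern for gradient-based samplers, not
here, and the density is unchanged either way.

Chains follow the usual configuration semantics: `nIterations` per
chain with `nBurnin` discarded, every `thin`-th draw retained, at least two
(default three) chains with *dispersed initial values* — top-level initials
drawn from the prior with its spread inflated by `initDispersion` (default
2), latent states from the crude data-implied index (mean transformed count
per site-year at the anchor detection value 0.5). The full-scale
configuration (40,000 iterations, 1,500 burn-in, thinning 10, 3 chains) is
available as `fullMcmcConfig()`; the default test profile uses far fewer
iterations, which suffices at fixture scale. Convergence is assessed by the
split-chain Brooks–Gelman–Rubin statistic (`splitRhat()`, threshold 1.1),
implemented in the package; a parameter with zero within-chain variance
reports `NA` (undefined) rather than a spuriously perfect 1.0, or `Inf`
when chains sit at distinct constants. Missing observations are simply
omitted from the likelihood, which is exact marginalisation under a fully
latent state process; multiple species are handled by fitting one model per
species.

## The synthetic-data generator

`generateTruth()` runs the state and seasonal processes forward;
`generateCounts()` adds Student-t observation noise and the survey's
missingness. The generator *is* the model run generatively, plus the
observational structure of the study: 40 sites split 7/21/10/2 across the
four protected areas, 44 years, 7 months, aerial observer periods of
27/10/7 years, the Tour du Valat protocol change at year 32, ground
missingness of 40–58% per area (Bernoulli per cell, missing completely at
random), near-complete aerial coverage, and late aerial introduction of
eight sites. Fixture scales `tiny` (6 sites, 10 years) and `small` (12
sites, 20 years) preserve every design feature. Generating parameter values
(`fixtureParameters()`) were chosen once as ecologically plausible —
initial site abundances around 300 birds, growth-rate innovation SD 0.12,
detection logits implying the third aerial observer and flushing ground
protocols detect most — and are not tuned thereafter.

Zero counts are handled by the $\log(\mathrm{count}+1)$ convention
throughout (generation draws the continuous log-scale observation and maps
back via $\mathrm{count} = \max(0, \mathrm{round}(e^y - 1))$); whether the
original analysis used an offset is unstated, so the offset is a documented
package constant. Ground-observer identity is not simulated (it was never
recorded). One master seed splits deterministically into truth, noise and
missingness substreams (`splitSeed()`).

What the generator does *not* emulate: spatial geometry and site areas,
weather and disturbance covariates, inter-site movement, availability
differences between methods, or any non-random missingness. Passing tests
therefore demonstrate correct inference *under the model's own assumptions*
(parameter recovery, calibrated predictive checks, anchor invariance) — not
robustness to the violations real count data may contain.

## Result machinery

`detectionSummary()` gives posterior means, SDs and equal-tailed 95%
credible intervals per detection cell, plus pairwise posterior ratios
("times more individuals detected", the natural multiplicative comparison
under the observation model) and exceedance probabilities — the fraction of
one cell's draws above the other's upper 97.5% quantile limit (quantile, not
HPD, is assumed and documented; equal-tailed quantile intervals are used
everywhere for their invariance under monotone transforms).
`abundanceIndex()` summarises $\exp(\log N_{s,t} + \alpha_{m,t})$ per site
and year for a chosen month, with area series formed by per-draw sums over
member sites. `correlateWithCounts()` reports Spearman rank correlations
between the posterior-mean index and raw counts. `sensitivityScan()` refits
the model over a grid of fixed $\beta_2$ anchors (the study range is 0–1.4)
and reports logit-scale cell differences, which should be invariant to the
anchor. One subtlety is worth knowing: raising the anchor by $c$ is
likelihood-invariant only along the ridge $p'_k = p_k \,
\mathrm{logit}^{-1}(c)/\mathrm{logit}^{-1}(0)$ (the latent $\log N$ absorbs
the common factor), so when the detection cells sit high enough that this
ridge approaches saturation ($p' \to 1$), the offset priors start to bind
and logit-scale differences widen and drift. The scan's consistency check
(mutually overlapping 95% intervals of the differences across anchors) is
the robust diagnostic; anchors should be chosen so that cells stay clearly
below 1 along the ridge. `posteriorFitCheck()` simulates replicated observations per
posterior draw and reports posterior-predictive p-values for per-method
mean, SD and maximum discrepancy statistics plus 95% predictive-interval
coverage; the three statistics are package choices (no canonical choice of
discrepancy statistic exists for this model) and the
maximum targets outlier blocks.

## Numerical choices and test-scale decisions

* Densities are computed on the log scale throughout; the joint density
  errors out (naming the component) rather than silently returning
  `-Inf`/`NaN`.
* Sampler initialisation failures at dispersed starting points are retried
  with the dispersion halved (at most three times) before failing loudly.
* The test and acceptance profiles use the tiny fixture with chains of
  1,600–4,000 iterations, 20 simulate–refit replicates for parameter
  recovery (pooled 95%-interval coverage over the detection offsets,
  $\sigma_{\mathrm{year}}$ and both $\sigma_i$, threshold 90%), 20
  replicate predictive-check calibrations (pooled p-value band 0.05–0.95,
  threshold 90%), and anchor values $\{0, 0.7, 1.4\}$ for the sensitivity
  scan. Pooling coverage across parameters and replicates is the
  statistically coherent reading of a 90% criterion at 20 replicates: a
  perfectly calibrated model fails stricter per-parameter-and-replicate
  readings with high probability at this replicate count.
* Problem sizes were chosen so the whole suite runs on a single CPU at
  desk scale; they are package defaults, not assertions about the full
  study, whose 40 × 44 structure is available as `studyStructureOf("full")`
  and `fullMcmcConfig()`.

## Known limitations

Absolute abundance and absolute detection probabilities are not estimable —
everything is conditional on the Vigueirat anchor. The model assumes
detection cells constant within their design blocks; residual observer or
site heterogeneity is absorbed by the Student-t error. Low-abundance
species may not support the full latent structure (the latent random walks
are poorly informed when counts are sparse and small), and no multi-species
hierarchy is provided. Extrapolation beyond the jointly monitored sites is
out of scope.
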