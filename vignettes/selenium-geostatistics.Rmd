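---
title: "Geostatistical modelling of plasma selenium status: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geostatistical modelling of plasma selenium status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Population selenium (Se) status is usually assessed from plasma Se
concentration, a biomarker measured in national micronutrient surveys.
Such surveys have a nested design: individuals are sampled within
households, households within georeferenced clusters (enumeration areas).
Plasma Se is strongly spatially structured — soil type and proximity to
lakes and rivers drive dietary Se supply — so the interesting questions
are geographic: where is an individual *likely* to fall below the
concentration thresholds associated with selenoprotein activity
(glutathione peroxidase 3 at 84.9 ng/mL, iodothyronine deiodinase at
64.8 ng/mL) or Keshan-disease risk (30 ng/mL)?

`segeostat` implements the full model-based geostatistical workflow for
this problem: a synthetic survey generator, REML estimation of the nested
spatial linear mixed model, ordinary kriging of individual-level
concentrations, exceedance probability mapping on a verbal scale,
cross-validation diagnostics, and prevalence tables.

## The model

Let $z_{ijk}$ be the natural log of plasma Se for individual $k$ in
household $j$ of cluster $i$ at location $x_i$ (projected km). The model
is

$$ z_{ijk} = \mu + S(x_i) + H_{ij} + E_{ijk} $$

with a constant mean $\mu$ as the only fixed effect;
$S$ a zero-mean, stationary, isotropic Gaussian random field with
covariance $\sigma^2_c\,\rho(h)$; $H_{ij} \sim N(0, \sigma^2_h)$
independent household effects; and $E_{ijk} \sim N(0, \sigma^2_e)$
independent individual effects that also absorb analytical error. The
spatial correlation is Matérn,

$$ \rho(h) = \frac{1}{2^{\nu-1}\Gamma(\nu)}
  \left(\frac{h}{\phi}\right)^{\nu} K_\nu\!\left(\frac{h}{\phi}\right), $$

in the convention where $\nu = 1/2$ reduces exactly to
$\exp(-h/\phi)$. We deliberately do not use the alternative
$\sqrt{2\nu}$-scaled convention: with the published fitted values
$\nu = 0.5$ and $\phi = 39.4$ km, the distance at which correlation falls
to 0.05 (our definition of the effective range) is $\phi\ln 20 \approx
3\phi \approx 118$ km, consistent with the reported "about 120 km" limit
of spatial dependence — the consistency that pins down the convention.

The log transform matters twice. First, plasma Se is right-skewed and the
Gaussian machinery applies on the log scale. Second, back-transforming a
log-scale prediction by plain exponentiation returns the *median* of the
lognormal prediction distribution — a median-unbiased central value —
not the mean (which would need the factor $e^{s^2/2}$).
`back_transform_median()` is named for exactly this property.

## Estimation

All parameters $(\mu, \sigma^2_c, \sigma^2_h, \sigma^2_e, \phi)$ are
estimated by residual maximum likelihood (REML), which removes the bias
that profiling out the mean would induce in the variance components. The
smoothness $\nu$ is poorly identified by typical survey geometries, so it
is estimated on a grid by profile likelihood: the model is refitted at
each grid value and the maximized residual log-likelihoods compared.

Numerical choices:

* **Likelihood form.** We use the Harville residual likelihood
  $-\tfrac12[(n-1)\log 2\pi + \log|V| + \log(\mathbf 1^\top V^{-1}
  \mathbf 1) + z^\top P z]$. The additive constant is irrelevant for
  estimation but fixed so that independent evaluation paths agree
  exactly.
* **Exact fast path.** For designs whose households within a cluster
  share a common size (all our generated designs, and any balanced
  survey), the residual likelihood decomposes exactly into orthogonal
  contrast blocks: within-household contrasts (iid, variance
  $\sigma^2_e$), between-household contrasts within cluster (variance
  $k\sigma^2_h + \sigma^2_e$ after orthonormal scaling), and a
  cluster-mean block that carries all the spatial structure and the mean.
  Only the last requires a dense solve, of dimension equal to the number
  of clusters (102) rather than the number of individuals (1,836). The
  equality of the two paths is asserted in the tests to 1e-8; the dense
  path remains available (`method = "dense"`) and is used automatically
  for unbalanced data.
* **Optimization.** The surface can be multimodal in $\phi$, so the
  search runs on log-transformed parameters (log variances, log $\phi$)
  with a Nelder–Mead simplex from three deterministic starting points
  (a moment-based start plus fixed perturbations of it; no RNG, so data
  seeds fully determine the fit). Variances are floored at $10^{-10}$ to
  keep the covariance positive definite; the profile search warm-starts
  each grid point from the previous optimum.
* **Smoothness grid.** The published analysis does not state its grid;
  the default is $\{0.1, 0.25, 0.5, 1, 1.5, 2\}$ and the acceptance
  experiments use $\{0.25, 0.5, 1, 2\}$. Ties within $10^{-6}$
  log-likelihood break toward smaller $\nu$ (parsimony).
* **Identifiability.** With a single individual per household,
  $\sigma^2_h$ and $\sigma^2_e$ are confounded; the generator therefore
  defaults to 2 individuals per household. When the fitted spatial share
  $\hat\sigma^2_c$ is below 1% of the total variance, $\phi$ is flagged
  non-identifiable (the likelihood is flat in it) rather than reported
  as meaningful.
* **No standard errors** of the variance components are computed; the
  original analysis reports none, and profile-based intervals would
  suggest more precision than the 102-cluster geometry supports.

## Prediction

Mapping uses ordinary kriging (OK) of an *unobserved individual's* value
at each node of a square grid (cell-centre convention): the prediction
target is $\mu + S(x_0) + H' + E'$ with fresh household and individual
effects. Consequently the target variance is the full
$\sigma^2_c + \sigma^2_h + \sigma^2_e$, while the covariance between the
target and any observation contains only the spatial term
$\sigma^2_c\rho(\|x_0 - x_i\|)$. This is what makes the exceedance map
answer the question a nutrition planner asks — "would a woman at this
location measure below the threshold?" — rather than the smoother
question about the local mean.

The OK weights solve the bordered system (weights summing to one, unknown
constant mean), with one factorization reused for every node (global
kriging; with at most a few thousand observations a moving neighbourhood
is unnecessary and would only add a discontinuity parameter). The OK
prediction is the mean and the OK variance the variance of the
conditional distribution of log concentration, from which

$$ p(x_0; T) = \Phi\!\left(\frac{\ln T - m(x_0)}{s(x_0)}\right) $$

is the probability of falling below threshold $T$. A degenerate
$s^2 = 0$ (exact interpolation with zero nugget) is treated as a point
mass with the strict-inequality convention $p = 1[e^m < T]$, matching the
strict counting used in the prevalence tables.

Probabilities are classified on a five-bin verbal scale (default edges
0.10/0.33/0.66/0.90; labels "very unlikely" … "very likely") with
half-open bins $[l, u)$; the numerical edges are always written next to
the labels in the legend artifact because the bins are a communication
device, not a statistical one. The published analysis cites a calibrated
verbal scale without printing its bins; the defaults here are the
conventional calibrated-language values and are fully configurable.

## Validation

Leave-one-out cross-validation predicts each observation from the rest
with plug-in REML parameters (no per-fold refit — standard practice, and
a mild optimism source, which we document rather than correct). The
standardized squared prediction error
$\theta_i = (z_i - \hat z_i)^2 / s^2_i$ should have mean near 1, and
median near the $\chi^2_1$ median 0.455 when kriging errors are nearly
independent. Because they are not independent in clustered geometries,
the package simulates the reference distribution of the *median* SSPE on
the observed support (`median_sspe_interval()`), which is the
correlation-aware interval an observed median should be compared with.
All folds share one factorization via the exact bordered-inverse
identity ($s^2_i = 1/H_{ii}$, $z_i - \hat z_i = (H\tilde z)_i / H_{ii}$),
verified against brute-force per-fold solves in the tests.

## The synthetic world

The generator is a stated world, fixed once:

* 102 clusters (18 urban, 84 rural — the analysed survey's realised
  counts), uniform over a 160 km × 850 km rectangle, a Malawi-like
  aspect ratio in arbitrary planar km.
* 9 households per cluster and 2 individuals per household. The survey
  targeted 20–22 households per cluster, but plasma data were analysed
  for roughly 1,233 households and 2,761 individuals across all
  demographic groups; 102 × 9 × 2 = 1,836 reproduces the order of
  magnitude of the single-group (WRA) analysis while keeping a REML fit
  to a few seconds.
* Outcomes from the generative model at the published fitted values:
  $\mu = \ln 80$ (the pooled cohort mean concentration is near
  80 ng/mL), $\sigma^2_c = 0.15$, $\sigma^2_h = 0.018$,
  $\sigma^2_e = 0.028$, $\nu = 0.5$, $\phi = 39.4$ km.
* Wealth quintiles independently uniform on 1–5, with an optional
  monotone log-scale shift (`quintile_effect`) for exercising the
  socioeconomic summaries.

What the generator does **not** emulate: probability-proportional-to-size
cluster selection and sampling weights, household replacement rules, DHS
coordinate displacement, demographic-group mixtures of means, and any
covariate structure (soil, water) in the outcome itself — proximity
effects enter only if the user constructs them. A green test therefore
establishes that the machinery is correct and calibrated under the
stated model, not that the model describes any particular country's
data.

Reproducibility contract: the generator consumes random numbers in a
fixed, documented order (design, then spatial effects, then household,
then individual effects), so a seed identifies a dataset across
versions.

## Degenerate inputs and conventions

* Duplicate cluster coordinates are rejected (resampled at generation;
  an error at simulation) rather than jittered — covariance matrices are
  positive definite by construction.
* A single cluster cannot support the between-cluster component and is
  an error in `fit_variance_components()`.
* Empty strata yield `n = 0` rows with missing statistics, never silent
  drops; single-record strata report `SD` as missing (n−1 divisor).
* Prevalence counts are strictly below threshold; a value exactly at
  84.9 ng/mL is not deficient. Proportions are unweighted (the published
  tables state no weighting); a `weight` column, if present, produces
  weighted columns alongside, not instead.
* Kriging at a support point with zero nugget returns the observed value
  with zero variance (exactitude); with a positive nugget it does not,
  by design.

## Known limitations

* The Matérn smoothness is weakly identified at the national design
  scale: in the replicate recovery experiment run by the acceptance
  suite, profile likelihood selects the generative $\nu = 0.5$ in about
  two-thirds of replicates, with genuine (0.3–1.2 unit) log-likelihood
  preferences for a neighbouring grid value in the rest. Variance
  components and $\phi$ are nevertheless recovered within a few percent
  on average.
* $O(n^3)$ dense linear algebra bounds the support at a few thousand
  observations; the 500 m national production grid is supported but slow
  at desk scale (the workflow default is 10 km).
* Plug-in kriging and cross-validation ignore parameter uncertainty; the
  exceedance probabilities are conditional on the fitted model.
* The abstract of the source analysis quotes a GPx3 threshold of
  86.9 ng/mL while its methods and tables use 84.9; the package defaults
  to 84.9 and leaves 86.9 one argument away.
* Geometry is planar and hand-rolled (no spatial dependencies): suitable
  for projected km, not for lon/lat.
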