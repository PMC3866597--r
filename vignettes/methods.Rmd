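---
title: "Methods: from pollen counts to climate, and the choices behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pollen counts to climate, and the choices behind them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenclim)
```

pollenclim implements the quantitative chain from a dated sediment core with
pollen counts to an ecosystem ordination and to Bayesian pollen-based
climate reconstructions. This vignette documents the models, the tunable
parameters, and every place where the design was genuinely open and a
choice had to be made.

## Radiocarbon calibration and the age-depth model

A date $y \pm \sigma_{lab}$ (¹⁴C yr BP) is calibrated against a curve
$(\mu(t), \sigma_{curve}(t))$ by evaluating
$p(t) \propto N\!\big(y;\, \mu(t), \sqrt{\sigma_{lab}^2 +
\sigma_{curve}(t)^2}\big)$ on a uniform calendar grid and normalizing to
unit mass. The grid step is 1 yr from 0 to the curve maximum — well below
lab-error resolution, so discretization error is negligible against
$\sigma_{lab} \geq 30$ yr. Curve values between knots are linearly
interpolated in both the ¹⁴C age and the error, the convention of the
classic calibration programs.

Interval summaries are highest-posterior-density (HPD) sets at 68.3% and
95.4%: grid cells are ranked by density and accumulated until the target
mass is reached, including the cell that crosses it, so the returned mass
matches the level to within one cell.

*Point estimate.* Calibration software historically reported an
"intercept": the calendar age at which the curve crosses the measured ¹⁴C
age. Whether legacy intercept columns are true curve intercepts or rounded
probability-weighted means is not recoverable in general, so the package
emits all three candidates (`intercept`, `median`, `wmean`). The intercept
rule is made deterministic for wiggly curves: among all crossings, take the
one with the highest posterior density inside the 95.4% interval that
carries the most mass; with no crossing at all (possible only at curve
plateau edges) the posterior mode is used.

The age-depth model is piecewise-linear through the (depth, intercept)
knots — no outlier rejection, an age reversal is a hard error naming the
offending pair. Deposition rates are $\Delta depth / \Delta age$ in cm/kyr
times a per-segment compaction factor. No compaction model is built in
(default factor 1): inventing an unstated sediment-physics model would
create false precision, so correction factors are user-supplied per
segment. Depths outside the dated span raise an error unless extrapolation
is explicitly enabled.

## Pollen sums and diversity

Percentages use the terrestrial pollen sum (wetland hygrophytes-hydrophytes
and cryptogam spores excluded from the denominator); aquatic taxa are
quoted by adding hygrophytes-hydrophytes to the sum. Micro-charcoal and
dinocysts are counted but never enter any denominator. Diversity (richness
$S$, Margalef $(S-1)/\ln N$, Shannon $-\sum p_i \ln p_i$) is computed on
terrestrial **counts**, not percentages, with natural logarithms: counts
are the sufficient statistic, the natural-log convention is the
palynological default, and the $\ln S$ upper bound for Shannon makes the
implementation crisply testable. Zero-count taxa do not contribute to $S$
(richness means observed taxa); $N < 2$ is an error because Margalef's
denominator degenerates.

## Ecosystems and ordination

Taxon time series are compared by midrank Spearman correlation $\rho$
(ties get average ranks). A constant series has no rank information; its
similarity is defined as 0 with a warning rather than `NA`, so degenerate
taxa cannot poison the matrix. Clustering on abundances is the default; a
presence/absence mode is provided because either reading of "pollen-type
time-series" is defensible.

UPGMA (paired-group, unweighted average linkage) runs on $d = 1 - \rho$ —
the conventional similarity-to-dissimilarity transform. Equal-distance
merges are broken by the lexicographically smallest pair of original leaf
indices, making the tree fully deterministic. The tree is cut at the lowest
height giving exactly $k = 9$ groups, the number of pollen-derived
ecosystems carried through the rest of the pipeline.

The PCA of the samples × 9 ecosystem-percentage matrix is covariance-mode
(centred, unscaled) by default: ecosystems are already on a common
percentage scale, and unstandardized analysis lets abundant ecosystems
carry the variance, which is what loadings of visibly different magnitudes
per ecosystem imply; a correlation-mode switch exists. A principal axis is
defined only up to sign, so axis 1 is oriented with the Mediterranean
open-forest (natural) pole positive — natural ecosystems score positive,
urban-adapted ones negative — and other axes get their largest loading
positive. The 2-D kernel density of the ordination cloud uses isotropic
Gaussian kernels with $\sigma$ = "radius" = 3 plane units; density software
disagrees on whether a "radius" is a standard deviation or a cutoff, so
$\sigma$ is configurable, and the surface is normalized to integrate to
the number of points.

## The vegetation forward model

The forward model is deliberately **not** a full dynamic vegetation model.
The inversion only requires a continuous, ecologically monotone,
deterministic map from the 36 monthly climate variables to relative
abundances of 13 plant functional groups; the package therefore ships a
fully specified envelope-and-ramp surrogate with every constant in one
versioned parameter table (`pft_params_v1.tsv`):

* bioclimatic indices: MAT, MTCO, MTWA, PANN, growing degree-days above
  5 °C (Gregorian month lengths, no leap years), and a moisture index
  $\alpha = P/(P + PET)$ where PET is a Thornthwaite-style temperature term
  (5 mm per °C per 30-day month above 0 °C) scaled by $(1 - cloud/200)$ —
  this scaling is what makes the cloud block of the 36-dimensional
  parameterization consequential;
* per group: trapezoidal membership over MTCO and over GDD5, a
  piecewise-linear moisture ramp (non-decreasing for moist-forest groups,
  so they vanish at $\alpha = 0$; decreasing for desert/steppe groups), and
  a multiplicative CO₂ scalar $1 + \beta \ln(\mathrm{CO}_2/280)$ with
  $\beta$ near zero for C4-grass groups;
* raw scores are normalized to sum to 1; an all-zero climate (outside every
  envelope) returns a uniform profile with a warning rather than NaN.

Trapezoids and ramps keep the map continuous and piecewise-differentiable,
which the random-walk sampler needs to mix well. Envelope constants were
chosen once to give ecologically plausible Mediterranean-to-boreal
behaviour; they are a model definition, not a fit. CO₂ per sample epoch
comes from a small built-in late-Holocene lookup (`co2_at_age()`),
overridable per analysis.

## The inversion

The 36 monthly variables are reduced to the scores $\theta$ of the first
four principal components of a modern climate grid (mean-centred;
covariance by default, since temperature, precipitation and cloud blocks on
raw units let precipitation variability dominate realistically — a
per-block standardization option documents the ambiguity). Candidate
climate is $baseline + \sum_k \theta_k s_k v_k$ with monthly precipitation
clamped at 0 and cloud at [0, 100]; $s_k$ is the standard deviation of the
modern scores, so the prior $\theta \sim N(0, I)$ is a weakly-informative
"within modern spatial variability" prior. The likelihood is isotropic
Gaussian on the 13 observed group proportions with a single shared
$\sigma_{obs}$ (default 0.05, roughly the combined counting and model error
for proportions from a few-hundred-grain count); nothing in the data
motivates a per-group error model.

Sampling is random-walk Metropolis. During burn-in (default the first 20%
of iterations) the proposal scale may adapt every 50 iterations toward an
acceptance rate of ~0.3 and is then frozen, so retained draws come from a
valid fixed-kernel chain. Reported intervals are equal-tailed 5–95%
quantiles of the derived MAT/MTCO/MTWA/PANN draws: equal-tailed is
deterministic and simple; HPD intervals would be narrower for skewed
posteriors but depend on density estimation. For production reconstructions
at least 10,000 post-burn-in draws are recommended; the packaged tests and
acceptance script use 5,000 post-burn-in draws per sample (and 50,000 for
the conjugate harness), sizes chosen so the whole verification suite runs
in minutes while Monte-Carlo error stays well inside the asserted
tolerances.

Verification runs the inversion on modern surface spectra with co-located
observed climate; bias (mean reconstructed − observed) and RMSE are
reported per variable, reconstructions are corrected by subtracting the
bias, and down-core series are finally anchored by
$x_v(t) - \hat{x}_v(\text{top core}) + x_v^{\text{modern obs}}$ applied to
medians and both interval bounds. Posterior summaries of different samples
are treated as independent; no joint constraint across depths is imposed.

## The synthetic-data generator

`make_truth()` + `simulate_core()` + `make_modern_climate_grid()` generate
every pipeline input with known truth: a strictly monotone (optionally
wiggle-free) calibration curve; a 48-cell modern grid with a July-peaking
sinusoidal seasonal cycle, cross-cell gradients in mean temperature,
precipitation total, seasonal amplitude and cloud, winter-weighted rainfall
and Gaussian noise; a smooth 4-component climate trajectory pushed through
the forward model to taxon probabilities over a fixed 30-taxon flora
(9 ecosystems × 13 functional groups), multinomially sampled into counts;
and dated horizons made by pushing true ages through the curve with
Gaussian lab error (±30 ¹⁴C yr, the standard AMS convention). Default
condition sizes — 70 samples, 5 dates, a 0–6000 cal BP span over 215 cm —
mirror a typical late-Holocene harbour core. The free-mixture mode
(`mixture_mode = "free"`) replaces the climate driver with nine independent
smooth ecosystem trajectories, making the clustering stage's generating
partition sharply identifiable.

What the generator does **not** emulate: real calibration-curve wiggles and
plateaus, spatially correlated climate fields, taxa shared between
ecosystems, differential pollen productivity and dispersal, taphonomic
loss, or count-total variation between samples (the per-sample total is a
single exposed parameter, since real totals vary with counting effort).
Passing tests therefore demonstrate the correctness and calibration of the
*machinery* under a well-specified generative model — multinomial counting
noise, Gaussian observation error, a known forward map — not the fidelity
of any particular real-world reconstruction, where forward-model
misspecification dominates and is exactly what the bias-correction stage
is for.

## Degenerate inputs and numerical conventions

* Dates outside the curve's ¹⁴C range, zero/negative lab errors,
  non-monotone curves, age reversals, zero pollen sums, $k$ larger than the
  leaf count, constant PCA matrices, rank-deficient climate grids and empty
  chains are all hard errors with specific messages.
* Constant Spearman series → similarity 0 (warning); all-zero forward
  scores → uniform profile (warning); acceptance rates outside (0.02, 0.9)
  → warning, not failure.
* All generators and the sampler are pure functions of their integer seed
  (`with_seed()` isolates and restores the global RNG state; `derive_seed()`
  gives each pipeline stage an independent stream), so every result is
  bit-reproducible from one master seed.
* Pipeline outputs are plain TSV with `#` metadata headers and an md5
  manifest; reruns with the same configuration are byte-identical.

## Known limitations

The forward model's 13 groups and envelope constants are a surrogate:
reconstructions from real assemblages inherit its biases and should lean on
the modern-spectra verification. The intercept point estimate is kept for
comparability with legacy chronologies, but the posterior median is the
better-behaved summary on wiggly curves. Single-chain sampling with an
acceptance-rate check and the package's seeded determinism stand in for
full multi-chain convergence diagnostics. The 9-ecosystem cut assumes the
chosen $k$; no stratigraphic constraint is imposed on the clustering.
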