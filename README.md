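# pollenclim

Quantitative paleoecology from a single dated sediment core: **pollenclim**
turns a table of fossil pollen counts into (i) a chronology, (ii) diversity
and ecosystem time series with an urban-versus-natural ordination axis, and
(iii) Bayesian reconstructions of past climate obtained by inverting a
vegetation model with Markov chain Monte Carlo.

It is written for palynologists and paleoclimatologists who have, for one
site: pollen counts per depth with ecological classes per taxon, a handful
of AMS radiocarbon dates, an IntCal-format calibration curve, and a gridded
modern monthly climatology. A seeded synthetic-data generator emulates all
of these inputs with known ground truth, so the entire pipeline is testable
without any external data.

## What it computes

**Chronology.** Each radiocarbon date is calibrated on a uniform calendar
grid, `p(t) ∝ N(y; μ(t), √(σ_lab² + σ_curve(t)²))`, with 68.3%/95.4%
highest-posterior-density interval sets and a legacy intercept point
estimate (the calendar age where the curve crosses the measured ¹⁴C age).
An age–depth model interpolates linearly between the dated intercepts and
reports per-segment deposition rates in cm/kyr (optionally
compaction-corrected).

**Pollen.** Percentages under the terrestrial pollen sum (hygrophytes and
cryptogam spores excluded) or the terrestrial-plus-aquatic sum; per-sample
richness *S*, Margalef index `(S−1)/ln N` and Shannon index `−Σ pᵢ ln pᵢ`.

**Ecosystems.** Taxa are clustered by UPGMA (paired-group, average linkage)
on the distance `1 − ρ`, where ρ is the midrank Spearman correlation of
taxon time series; the tree is cut into 9 pollen-derived ecosystems whose
member percentages are summed. A covariance-mode PCA of the
samples × ecosystems matrix yields the axis-1 score series, oriented so the
natural (Mediterranean open forest) pole loads positively; a 2-D Gaussian
kernel density (σ = 3 plane units) summarizes the ordination cloud.

**Climate inversion.** A simplified bioclimatic vegetation model maps the
36 monthly climate variables (12 temperature, 12 precipitation, 12 cloud)
plus CO₂ to relative abundances of 13 plant functional groups via
trapezoidal envelopes over (MTCO, GDD5) times a moisture ramp in
α = P/(P+PET). Climate is parameterized by the scores **θ** of the first
four principal components of a modern climate grid; a random-walk
Metropolis sampler explores

  p(θ | y) ∝ N(θ; 0, I) · Π_g N(y_g − f_g(θ); 0, σ_obs²)

and posterior medians with 90% equal-tailed credible intervals are reported
for MAT, MTCO, MTWA and PANN. Modern surface spectra provide RMSE/bias
verification; reconstructions are bias-corrected and anchored to observed
modern climate through the top-core sample.

## Worked example

```r
library(pollenclim)

# calibrate one of the core's AMS dates against a calibration curve
curve <- make_calibration_curve("identity")   # or read_calcurve("intcal09.14c")
calibrate_c14(1000, 50, curve)
#> Calibrated 14C date: 1000 +/- 50 14C BP
#>   intercept 1000 cal BP | median 1000 | weighted mean 1000.0
#>   68.3% HPD: 1050-950
#>   95.4% HPD: 1099-900

# age-depth model through the five dated intercepts of the Akko core
t1 <- read_tsv_meta(system.file("extdata", "akko_c14_dates.tsv",
                                package = "pollenclim"))
am <- build_age_model(t1$depth_cm, t1$intercept_cal_bp)
am
#> Age-depth model: 5 knots, 80-215 cm, 170-5930 cal BP
#>  from_cm to_cm rate_cm_kyr compaction
#>       80   101       19.09          1
#>      101   133       20.13          1
#>      133   173       20.00          1
#>      173   215       39.25          1
predict(am, 90.5)
#> [1] 720

# invert one pollen spectrum for climate
grid  <- make_modern_climate_grid(48, seed = 3)
basis <- build_climate_pc_basis(grid)
y     <- forward_model(theta_to_climate(c(0.5, -0.3, 0.2, 0.1), basis), 280)
fit   <- invert_climate(y + rnorm(13, 0, 0.05), basis, sigma_obs = 0.05,
                        n_iter = 6250, seed = 2)
fit
#> Climate inversion: 5000 retained draws, acceptance 0.30
#> 90% credible intervals:
#>  variable median ci_lo ci_hi
#>       MAT   18.2  17.1  19.4
#>      MTCO   11.9  11.0  12.8
#>      MTWA   24.7  22.3  27.2
#>      PANN  613.7 569.9 666.8
```

The rates are cm of sediment per thousand years between dated horizons
(e.g. 32 cm over 1.59 kyr ≈ 20.13 cm/kyr); the inversion's credible
intervals here bracket the generating climate (MAT 18.1 °C, PANN 636 mm).
`run_pipeline(pipeline_config(outdir, seed))` chains every stage on
synthetic inputs and writes TSV outputs plus a checksum manifest.

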