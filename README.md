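# covtrace

Covariate-conditional covariance estimation and two-group comparison.

## What it does

Clinical two-group comparisons usually ask whether a set of correlated
markers differs between outcomes — for example cerebrospinal-fluid
biomarkers between dementia and non-dementia cohorts. covtrace compares the
groups' *covariance structure* as a **function of covariates** instead of
regressing the covariates away: for a standardized response vector
`x ∈ R^p` and covariates `u` it estimates each group's conditional
covariance function

    Σ̂(u) = Σ_i K_h(U_i − u) (x_i − m̂(U_i))(x_i − m̂(U_i))′ / Σ_i K_h(U_i − u)

(Nadaraya-Watson weighting of residual outer products around a local linear
mean fit; product kernels for several continuous covariates, an
Aitchison-Aitken kernel for factors) and tests

    H0 : Σ0(u) = Σ1(u)

at any covariate value through the largest eigenvalue `λ1` of the combined
matrix

    Z(u) = (n0 S0(u) + n1 S1(u))⁻¹ n1 S1(u),

whose spectrum lies in [0, 1] and sits at `n1/(n0+n1)` under H0. Three
p-value routes are provided — a parametric Tracy-Widom largest-root test on
`logit λ1`, a Gaussian-reference bootstrap (Forkman-style) test on the
eigenvalue share `λ1/Σλk`, and a residual permutation test — plus
*significance traces* (p-value curves along the covariate), a CSV-driven
analysis workflow, and a reproducible simulation lab for type-I error,
power and eigenvalue-accuracy studies. Bandwidths are selected by
leave-one-out criteria (squared error for the mean, Gaussian log-likelihood
for the covariance).

Audience: biostatisticians comparing dependence structures across cohorts
while conditioning on age, sex or other covariates, and anyone needing a
PSD-by-construction conditional covariance smoother with calibrated
equality tests.

## Worked example

```r
library(covtrace)

# two groups whose response correlation is theta * u, u ~ Unif(-1, 1):
# identical structure at u = 0, increasingly different toward |u| = 1
g0 <- simulate_group_1d(400, theta = 0.5, seed = 1)
g1 <- simulate_group_1d(400, theta = 1.0, seed = 2)

fit0 <- condcov(sample = g0, bandwidth = 0.6, mean_bandwidth = 0.8)
fit0
#> Conditional covariance fit (Nadaraya-Watson)
#>   n = 400, responses p = 2, continuous covariates q = 1
#>   mean estimator: local_linear (h = 0.8)
#>   covariance bandwidth h = 0.6, kernel = gaussian

predict(fit0, u = 0.5)$sigma
#>           x1        x2
#> x1 1.0437033 0.1823115
#> x2 0.1823115 1.1599063
```

The true covariance of group 0 at `u = 0.5` has unit diagonal and
off-diagonal `0.5 × 0.5 = 0.25`; the kernel estimate (0.18 here) carries
smoothing bias and sampling noise at `n = 400`. Comparing the groups along
the covariate:

```r
fit1 <- condcov(sample = g1, bandwidth = 0.6, mean_bandwidth = 0.8)
tr <- significance_trace(fit0, fit1, grid_u = seq(-0.9, 0.9, by = 0.3),
                         B = 199, seed = 7)
head(tr, 6)
#>      u level      method statistic p_value   B flag
#> 1 -0.9  <NA> tracy_widom     1.163  0.0384   0   ok
#> 2 -0.9  <NA>     forkman     0.624  0.0000 199   ok
#> 3 -0.9  <NA> permutation     0.624  0.0000 199   ok
#> 4 -0.6  <NA> tracy_widom     0.604  0.0827   0   ok
#> 5 -0.6  <NA>     forkman     0.599  0.0000 199   ok
#> 6 -0.6  <NA> permutation     0.599  0.0000 199   ok
```

At `u = -0.9` the group correlations are −0.45 vs −0.90 and all three
tests flag the difference (the resampling p-values of 0 sit on the 1/B
lattice; `add_one = TRUE` gives the conservative `(1+#)/(B+1)` version);
near `u = 0` the traces rise well above 0.05, as they should where the two
structures coincide. `plot(tr)` draws the traces with a reference line at
α = 0.05.

For tabular data, `analysis_config()` + `run_analysis()` drive the same
pipeline from a CSV (optional per-response log transform, per-group
standardization, grid clipped to the shared covariate range, per-factor-level
traces) and `write_results()` emits a results CSV and a JSON manifest that
reproduces the table bit-exactly. A thin command-line front end with
`analyze` / `simulate` / `study` subcommands lives in
`inst/cli/covtrace-cli.R`.

The simulation lab exposes the study harness directly:

```r
des <- sim_design(dim = 1, theta2 = 1, preset = "ci", grid_u = c(-1, 0, 1),
                  h_grid = 1)
run_rejection_study(des)   # tidy rates: type_I_error rows at u = 0, power elsewhere
```

## Documentation

The methods vignette
(`vignettes/conditional-covariance-comparison.Rmd`) describes the
estimator, the three tests, the bandwidth criteria, the simulation designs
and the package's numerical conventions and limitations.
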