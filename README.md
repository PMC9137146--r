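# copulaAM — bivariate animal-model REML under non-Gaussian residual copulas

Quantitative geneticists estimate variance components of multi-trait
animal models by REML and breeding values by BLUP, both of which assume
the phenotype vector is jointly Gaussian.  That assumption can fail in a
subtle way: each trait may be perfectly normal on its own while the
*dependence structure* between traits — the copula of the residual pair —
is asymmetric or heavy-tailed.  copulaAM is a simulation laboratory for
measuring what that kind of misspecification does to REML estimates and
to selection response in a closed breeding population.

The package is aimed at animal breeders and quantitative geneticists who
want to stress-test multi-trait evaluation pipelines, and at
statisticians interested in the robustness of Gaussian restricted
likelihood under copula misspecification.

## What it implements

**Model.** The bivariate animal model

y_j = X β_j + a_j + ε_j,  j = 1, 2,

with additive genetic covariance Σ_a ⊗ A (A the pedigree relationship
matrix) and i.i.d. residual pairs with standard normal margins and a
normal, Frank, Clayton or Joe copula (270°-rotated for negative
dependence), calibrated on Kendall's τ so families are compared at equal
rank correlation.  Narrow-sense heritability is
h²_j = σ²_aj / (σ²_aj + σ²_ej).

**Components.**

* `copula_spec()`, `copula_cdf()`, `copula_sample()`, `kendall_tau()`,
  `tau_to_theta()`, `copula_pearson()`, `tail_dependence()` — the four
  copula families, conditional-inversion sampling, and the τ ↔ θ ↔
  Pearson-ρ calibration by numerical integration.
* `mardia()`, `normal_scores()` — multivariate normality diagnostics
  (bivariate Gaussian reference: skewness 0, kurtosis 8).
* `sim_population()` — a closed pig-type breeding scheme: 216 founders,
  17 dams per sire, 12 or 24 offspring per dam (the latter with half of
  the animals missing trait 2), 3 generations of random selection then
  5 of within-family truncation on a 50/50 EBV index (selected
  fractions 1/34 of males, 17/170 of females).
* `am_reml()` — REML for the bivariate animal model by direct
  maximisation of the exact restricted likelihood on sparse mixed-model
  equations (canonical two-trait decomposition for complete records,
  observed-subvector equations for missing trait-2 records), with
  `print`, `summary`, `coef`, `logLik`, `predict`, `residuals` and
  `simulate` methods; `am_blup()` for BLUP at known components.
* `run_study()` / `summarize_study()` — Monte-Carlo orchestration over
  the 24 parameter sets (τ_a ∈ {0.2, 0.4}, τ_e ∈ {±0.4, ±0.7}, genetic
  variances (0.18, 0.18)/(0.18, 0.67)/(0.67, 0.67)): bias, empirical SE,
  t-tests and genetic gains, with seeds paired across copula families.

## Worked example

Simulate a quarter-scale population with Joe-copula residuals at
τ_e = 0.7 (upper-tail dependent, strongly non-Gaussian), unbalanced
heritabilities (0.153, 0.401) and genetic correlation 0.59, run three
random-selection generations, and fit REML on all data:

```r
library(copulaAM)

pop <- sim_population(
  design = "complete",
  copula = copula_spec("joe", tau = 0.7),
  tau_a = 0.4, sigma2_a = c(0.18, 0.67),
  n_generations = 3, scale = 1/4, seed = 42)

fit <- am_reml(pop$phen, pop$ped)
fit
#> Bivariate animal model fit by REML (canonical path)
#>   1890 animals (1890 with both traits), 5 fixed-effect columns per trait
#>   restricted log-likelihood: -4829.7576 (converged, 182 evaluations)
#>   genetic covariance:
#>        [,1]   [,2]
#> [1,] 0.0807 0.1070
#> [2,] 0.1070 0.5562
#>   residual covariance:
#>        [,1]   [,2]
#> [1,] 0.9899 0.8727
#> [2,] 0.8727 1.0500
#>   h2 = (0.075, 0.346), r_g = 0.505, r_e = 0.856
```

A single quarter-scale replicate is noisy — the empirical SE of each
heritability estimate is about 0.04–0.05, and this particular draw sits
low on both traits.  Averaged over replicates (see `run_study()` and the
acceptance script below) the estimates are unbiased under *random*
selection even though the residual copula is far from Gaussian.  Note
the residual correlation estimate, 0.856: it approaches the Pearson
correlation implied by the Joe copula at τ = 0.7,

```r
copula_pearson(copula_spec("joe", tau = 0.7))
#> [1] 0.8504393
```

not the Gaussian value sin(0.35π) = 0.891 — equal Kendall correlation
deliberately does not mean equal linear correlation across families.
Biases appear once truncation selection starts and the copula has an
upper tail: re-running the same configuration to generation 8 with
selection on the 50/50 EBV index (see `run_study()`) overestimates the
moderate heritability for Joe residuals and underestimates it for
Clayton residuals, while the Frank and normal copulas stay close to
truth.

Mardia diagnostics of the residual construction itself:

```r
set.seed(1)
mardia(gaussian_margins(copula_sample(copula_spec("joe", tau = 0.7), 1000)))
#> Mardia diagnostics (n = 1000, p = 2)
#>   skewness: 2.1767  (normality test p = 3.05e-77)
#>   kurtosis: 11.4524  (normality test p = 2.11e-42; Gaussian value 8)
```

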