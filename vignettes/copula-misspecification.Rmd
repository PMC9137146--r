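---
title: "Copula misspecification in bivariate animal-model REML: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copula misspecification in bivariate animal-model REML: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copulaAM)
```

## The question the package addresses

Multi-trait genetic evaluation estimates variance components by restricted
maximum likelihood (REML) and breeding values by BLUP under a joint
Gaussian model.  Even when every single trait is marginally Gaussian, the
*dependence structure* between traits — their copula — may not be: the
joint distribution can be radially asymmetric or heavy-tailed while both
margins stay perfectly normal.  copulaAM provides the machinery to ask,
by simulation, what such a misspecified residual dependence does to REML
estimates and to selection response in a closed breeding population:
it simulates populations whose residual pairs have standard normal
margins but a chosen copula, runs BLUP-based truncation selection, re-fits
REML generation after generation, and summarises bias, empirical
standard errors and genetic gain over Monte-Carlo replicates.

## Model

Phenotypes follow the bivariate animal model
$$
y_{j} = X\beta_j + a_j + \varepsilon_j,\qquad j = 1,2,
$$
with a common fixed-effect design $X$ (three categorical factors with 3,
2 and 2 levels), additive genetic values with covariance
$\Sigma_a \otimes A$ where $A$ is the pedigree numerator relationship
matrix, and i.i.d. residual pairs
$(\varepsilon_{i,1}, \varepsilon_{i,2})$.  The residual pair has standard
normal margins and copula $C$; its joint distribution is
$F(z_1, z_2) = C(\Phi(z_1), \Phi(z_2))$ (Sklar).  Narrow-sense
heritabilities are $h^2_j = \sigma^2_{a_j}/(\sigma^2_{a_j} +
\sigma^2_{e_j})$.

### Copula families

Four families cover the qualitative axes "symmetric vs. asymmetric" and
"tail dependent vs. not":

| family  | symmetry          | tail dependence                       |
|---------|-------------------|---------------------------------------|
| normal  | radially symmetric| none                                   |
| Frank   | radially symmetric| none                                   |
| Clayton | asymmetric        | lower: $\lambda_L = 2^{-1/\theta}$     |
| Joe     | asymmetric        | upper: $\lambda_U = 2 - 2^{1/\theta}$  |

Clayton and Joe cannot express negative dependence, so for negative
Kendall correlation the 270°-rotated copula
${}^rC_\theta(u_1, u_2) = u_1 - C_\theta(u_1, 1 - u_2)$ is used, which is
equivalent to negating the second residual.  Dependence strength is
always specified through Kendall's tau so that families are compared at
equal rank correlation; the family parameter $\theta$ is resolved from
$\tau$ by closed forms (normal $\rho = \sin(\pi\tau/2)$, Clayton
$\theta = 2\tau/(1-\tau)$) or by inverting the generator integral
$\tau = 1 + 4\int_0^1 \varphi(t)/\varphi'(t)\,dt$ numerically to 1e-8
(Frank, Joe).  Because equal $\tau$ does not mean equal Pearson
correlation, the linear correlation implied by each family under normal
margins is computed by Hoeffding's identity
$$
\rho = \int\!\!\int \left\{ C(\Phi(x), \Phi(y)) - \Phi(x)\Phi(y)\right\}
\,dx\,dy
$$
on a 256×256 Gauss–Legendre grid over $[-8.5, 8.5]^2$; this is accurate
well beyond the three decimals at which the calibration values are
quoted, e.g.

```{r pearson}
copula_pearson(copula_spec("frank", tau = 0.4))
copula_pearson(copula_spec("joe", tau = 0.7))
```

Sampling uses conditional inversion: $U$ uniform, then
$V = C^{-1}_{V|U}(W)$.  The inverse conditional is analytic for the
normal, Clayton and Frank families; for Joe it is found by bisection on
$[10^{-12}, 1-10^{-12}]$ (60 halvings, i.e. resolution far below the
1e-10 target), chosen over derivative-based root finding for robustness
at extreme $\theta$.

### Normality diagnostics

Mardia's multivariate skewness and kurtosis are used both to
characterise the simulated residual distributions and as a data
diagnostic.  With $m_{ij} = (x_i - \bar x)^\top S^{-1}(x_j - \bar x)$
(maximum-likelihood $S$), skewness is the mean of $m_{ij}^3$ over all
pairs and kurtosis the mean of $m_{ii}^2$; a bivariate Gaussian has
values 0 and 8.  The implementation expands the pairwise cube into
multinomial moments, so it is $O(n)$ rather than $O(n^2)$ and handles
large samples.  The skewness test refers $n b_{1,2}/6$ to $\chi^2_4$;
the kurtosis test uses the asymptotic normal with variance $8p(p+2)/n$
($64/n$ for $p=2$) — the literature also contains finite-sample
corrected variants, but the asymptotic forms are standard and are what
the package reports.  Rank-based normal scores
$\Phi^{-1}(r_i/(n+1))$ (ties averaged, relevant only for real data)
support copula scatter plots free of marginal effects.

## The simulated breeding scheme

The synthetic-data generator emulates a closed pig-type nucleus:

* founders: 216 unrelated animals, 12 males and 204 females;
* each sire mated to 17 dams; full/half sibs are never mated;
* complete design: 12 offspring per dam (2 M, 10 F), 2448 per
  generation, all candidates; 19,800 animals over 8 generations;
* missing design: 24 offspring per dam (4 M, 20 F), half of each sex
  missing trait 2, 4896 per generation, 39,384 in total; only the 2448
  animals per generation lacking trait 2 are candidates;
* generations 1–3 bred from randomly drawn reproducers, generations 4–8
  by truncation on a 50/50 EBV index, within paternal half-sib family:
  the best 1 of 34 male candidates (2.9%) and 17 of 170 female
  candidates (10%) per family.

Founder breeding values are $N_2(0, \Sigma_a)$; offspring get the parent
average plus a Mendelian term $N_2(0, \Sigma_a/2)$.  The Mendelian
variance is held constant across generations, so the exact covariance of
the simulated breeding values is the *constant-variance* relationship
matrix, whose inverse is produced exactly by Henderson's
2 / 4/3 / 1 rules on any pedigree — the estimation model and the
generator are mutually consistent by construction.  An
inbreeding-adjusted $A^{-1}$ is deliberately out of scope; the mating
restriction keeps realised inbreeding small, and the classical and
constant-variance matrices coincide until a *parent* is inbred.

Some sources describe the missing design's litter as "4 males and 24
females", which is inconsistent with its own per-generation total of
4896 = 204 × 24; the package follows the totals and uses 24 offspring
per dam (4 M, 20 F), which also preserves the within-family candidate
counts (34 males, 170 females) and hence the printed selection rates.

Fixed-effect level values are arbitrary by design; the defaults are
small contrasts (`default_fixed_values()`: 0/1/−1, ±0.5, ±0.3), the same
for both traits, with levels assigned independently and uniformly per
animal.  Residual variances default to 1, so phenotypic variances are
$\sigma^2_{a_j} + 1$.

Randomness is split into three streams derived from the replicate seed —
genetic draws, residual draws (including fixed-effect levels), and
scheme randomness (mating permutations, random-phase selection,
tie-breaks) — so replicates that differ only in the residual copula
share their genetic realisations, enabling paired comparisons between
families.

What the generator does **not** emulate: overlapping generations,
variable litter sizes, culling on the observed traits themselves,
genotype-by-environment structure, inbreeding depression, maternal or
dominance effects, and real phenotype idiosyncrasies (measurement error
scales, censoring).  Conclusions from the tests therefore speak to the
behaviour of REML under controlled dependence misspecification, not to
any particular real population.

## REML, BLUP, and how the likelihood is computed

`am_reml()` maximises the exact restricted log-likelihood of the
bivariate animal model directly, with positive definiteness enforced by
optimising log-Cholesky parameters of $\Sigma_a$ and $\Sigma_e$ (three
parameters each).  Two evaluation paths share the same mathematical
definition:

* **Canonical path** (complete records, shared $X$): for a candidate
  $(\Sigma_a, \Sigma_e)$, a 2×2 transform $T$ with
  $T\Sigma_eT^\top = I$ and $T\Sigma_aT^\top = \mathrm{diag}(\lambda)$
  splits the restricted likelihood into two univariate animal-model
  likelihoods in the transformed traits plus the Jacobian term
  $-(n-p)\log|\Sigma_e|/2$.  Each univariate likelihood needs one sparse
  Cholesky factorisation of $A^{-1} + \lambda I$; the symbolic analysis
  is cached, so an evaluation is a numeric re-factorisation costing
  milliseconds even for tens of thousands of animals.
* **Direct path** (missing trait-2 records, or as a cross-check): the
  full mixed-model equations with per-record residual precision — the
  2×2 inverse for complete records, $1/\sigma^2_{e_1}$ for records with
  trait 2 missing (the observed-subvector formulation; no imputation) —
  and genetic block $\Sigma_a^{-1} \otimes A^{-1}$ are assembled
  sparsely and factorised per evaluation.

The two paths agree to ~1e-9 on complete data, and both agree with a
dense textbook evaluation of
$-\tfrac12(\log|V| + \log|X^\top V^{-1}X| + y^\top P y)$ on small
instances; the test suite pins these equivalences.  The optimiser is
L-BFGS-B with a cached forward-difference gradient, relative
log-likelihood tolerance 1e-8 (tunable), and a cap of 200 iterations;
failures to converge are flagged and the last iterate returned.  This
quasi-Newton-on-exact-likelihood design was chosen over
average-information updates because the AI gradient needs selected
elements of the inverse mixed-model matrix, which have no efficient
sparse interface in pure R, while exact likelihood evaluations here are
so cheap that the extra function calls are immaterial; the log-Cholesky
parameterisation also removes any need for an expectation-maximisation
fallback, since every iterate is automatically positive definite.
Default starting values are neutral (variances 0.3 genetic / 0.7
residual, zero covariances); generation-after-generation re-fits warm
start from the previous fit.  Identifiability of the fixed part uses the
usual reference-level (treatment-contrast) parameterisation.

`am_blup()` solves the same mixed-model equations once at supplied
variance components, for every pedigree member, phenotyped or not.

## Selection and the study loop

At each selection round from generation 3 on, EBVs come from BLUP at the
REML estimates re-fitted on all data available so far (`selection_vc =
"reml"`, the default; `"true"` uses the simulation values instead, a
cheaper variant useful for isolating estimation effects from selection
effects).  The selection index weights the two EBVs 50/50; ties are
broken by a seeded random draw.  Genetic gain at generation $k$ is the
mean EBV of generation $k$ minus the founder mean, scaled by the true
genetic standard deviation of each trait.

`run_study()` crosses parameter sets (`study_parameter_sets()`:
$\tau_a \in \{0.2, 0.4\}$, $\tau_e \in \{\pm0.4, \pm0.7\}$, genetic
variances (0.18, 0.18)/(0.18, 0.67)/(0.67, 0.67) — 24 sets) with copula
families and replicates; `summarize_study()` reports bias (mean estimate
minus truth), the empirical SE (SD of replicate estimates), one-sample
t-tests at $\alpha = 0.05$ (raw, unadjusted — multiplicity is left to
the reader, matching common reporting practice), and genetic gains with
their relative differences against the Gaussian-copula run of the same
set.  Replicate seeds depend only on (master seed, set, replicate
index), never on the family, so family comparisons are paired; failed
replicates (infeasible matings, non-convergence) are excluded and
counted.

### Problem sizes used by the tests

The full-size study (1000 replicates × 24 sets × 8 generations at scale
1) is a batch job, not a desk run.  The package's own test suite and the
acceptance script use reduced settings chosen to keep the Monte-Carlo
error small enough for the qualitative conclusions they check: scale 1/4
(3 sires × 17 dams, 1890 animals through generation 3, 4950 through
generation 8) with 100 replicates per family.  At that size the
empirical SE of a mean heritability estimate is about 0.005, an order of
magnitude below the effects the truncation-selection checks look for
(bias of roughly ∓0.03–0.06 for Clayton/Joe at $\tau_e = 0.7$), while a
single G3 replicate takes well under a second.

## Numerical choices and edge cases

* Bivariate normal CDF: Gauss–Legendre quadrature (64 nodes) on the
  correlation-parameter representation; accuracy ~1e-10, no external
  dependency.
* Frank at $|\theta| < 10^{-10}$, Clayton at $|\theta| < 10^{-10}$, Joe
  at $\theta = 1$ evaluate as the independence copula, making the
  $\tau \to 0$ limit continuous.
* `gaussian_margins()` refuses coordinates at 0 or 1 (infinite
  quantiles) rather than clamping silently.
* Tail dependence of rotated specs reports the base (positive-tau)
  family's coefficients: rotation moves the mass to an off-diagonal
  corner where the usual diagonal limits are zero by construction, so
  the base values are the informative ones.
* The mating repair algorithm (random assignment, then conflict swaps,
  capped at 1000 sweeps) errors out rather than silently accepting a
  sib mating; with a single sire family such an assignment is
  impossible and the replicate is flagged as failed.
* Mardia's statistics error on singular covariance (duplicated points,
  collinear traits) instead of returning pseudo-inverse artefacts.

## Known limitations

* Two traits only; extending the copula machinery to $d > 2$ would
  require hierarchical Archimedean or vine constructions.
* No inbreeding-adjusted relationship inverse (see above); realised
  inbreeding under the mating restriction is small but not zero.
* The REML asymptotics reported are point estimates; standard errors of
  the variance components themselves (e.g. from the average-information
  matrix) are not computed — the study design measures dispersion across
  replicates instead.
* Copula fitting to data (family choice by information criteria) is out
  of scope; the diagnostics module only measures departure from
  normality.
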