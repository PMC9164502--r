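---
title: "Genomic reaction norms for G×E: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic reaction norms for G×E: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery:
what is modelled, which defaults were chosen and why, where the design
was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real data.

## The environmental gradient

Explicit environmental covariates (feed, rainfall, parasite load) are
rarely recorded per cohort, so the environment is *inferred from the
data*: contemporary groups (CGs) that grow fast after weaning were, on
average, in better environments.  `fit_cg_blue()` fits an animal model
for post-weaning growth rate (g/day) with fixed sex, birth-type ×
rear-type interaction, linear and quadratic age, and CG; random additive
genetic effects over a genomic (or pedigree) relationship matrix; and a
random breed-group effect through the proportion matrix `Q`.  The CG
BLUEs are taken under the reference-level constraint — the arbitrary
location cancels in the next step.  `standardize_gradient()` assigns
each animal its CG's BLUE and standardises *over genotyped animals*
(animal-weighted, so large CGs carry more weight), recording
`mean_used`/`sd_used` so gradient values convert back to g/day.

Record filters before this step (`filter_for_gradient()`): growth
period ≥ 40 days; growth rate within 4 SDs of the mean; no quintuplet
births or quadruplet rearing; CGs of ≥ 15 animals.  The 4-SD rules are
single-pass, using the mean/SD of the sample left by the preceding rule:
a one-pass rule is reproducible, whereas iterated trimming depends on
its stopping rule.  One consequence worth knowing: with `k` equal
outliers among `n` records the largest attainable standardised deviation
is `sqrt((n-1)(n-k)/(nk))`, so a 4-SD rule can only catch outliers that
are gross relative to the *contaminated* SD — which is also exactly how
such a filter behaves on real data.

Animals enter the reaction-norm stage (`filter_for_rnm()`) when
genotyped, with body weight within 4 SDs, and either from a CG of ≥ 15
animals or with at least one half-sib (shared sire *or* shared dam —
the natural reading of "half-sib"): families spread across environments
are the information that identifies slopes, so singleton animals with
family links are worth keeping.

## The reaction-norm models

`fit_rnm()` fits body weight as

$$y = Xb + Z_1 a_1 + Z_2 a_2 + Qg + e, \qquad
\begin{pmatrix}a_1\\a_2\end{pmatrix} \sim N(0,\, G \otimes K),$$

with $Z_2 = Z_1\,\mathrm{diag}(x)$ for gradient values $x$, fixed sex,
birth type, rear type, linear age and CG (the quadratic age term is
kept to the gradient model only; the weight model follows the simpler
fixed-effect list), random genetic-group effects
$g \sim N(0, I\sigma^2_g)$, and either

* **RNM-HOM**: $e \sim N(0, I\sigma^2_e)$, or
* **RNM-HET**: $e_i = e_{1i} + x_i e_{2i}$ with 2×2 coefficient
  covariance $E$, i.e. per-record variance
  $\sigma^2_{e1} + 2x_i\sigma_{e1e2} + x_i^2\sigma^2_{e2}$.

A deliberate choice: **E is not constrained positive definite.**  The
heterogeneous residual is a *quadratic variance function* of the
gradient; a negative $\sigma^2_{e2}$ (variance shrinking curvature) is a
legitimate fit as long as every per-record variance stays positive over
the observed gradient range, which the code checks and warns about.
Constraining $E$ to be PD would silently forbid a whole class of
variance shapes.

Since the gradient is constant within a CG and CG is a fixed effect,
the gradient cannot (and does not) appear as a fixed covariate; slope
effects are identified purely through the covariance structure, i.e.
through families observed in different environments.

### Derived quantities

With $\Lambda = [\,1, x\,]$ over a grid of 100 points spanning the
observed gradient range (`variance_profile()`):
$V_a(x) = \Lambda K \Lambda'$, $V_e(x) = \Lambda E \Lambda'$ (constant
for HOM), $h^2(x) = V_a/(V_a+V_e)$ — the group variance is excluded
from the denominator, making $h^2$ a within-breed-composition quantity —
and between-environment genetic correlations from $\hat V$.  Standard
errors are first-order delta-method transforms of the inverse
average-information matrix; the SE of $V_a(0)$ equals the SE of
$\hat\sigma^2_{a1}$ identically, which the tests exploit.  Negative
extrapolated variances at extreme grid points are *reported, not
clamped*: they are informative extrapolation artifacts.
`compare_environments()` summarises at −1.5/0/+1.5 SD; comparisons are
restricted to that central range because profile values further out
rest on few records.

## REML implementation

Every model here has a marginal covariance *linear* in its parameters,
$V(\theta) = \sum_k \theta_k V_k$, which `model_spec()` exploits: the
$V_k$ are precomputed once (genetic kernel, kernel × gradient cross
terms, group kernel, residual diagonals), traces $\mathrm{tr}(PV_k)$
reduce to elementwise sums, and one Cholesky factorisation per
iteration dominates the cost.  `reml_fit()` runs average-information
REML:

* score $-\tfrac12[\mathrm{tr}(PV_k) - y'PV_kPy]$, AI matrix
  $\tfrac12 y'PV_kPV_lPy$;
* proposed steps are **step-halved** (up to 12 times) until the
  covariance is positive definite and the restricted likelihood does
  not decrease, with a scaled score-ascent fallback — so accepted
  iterations are monotone;
* convergence at relative log-likelihood change < `tol` (default 1e-6)
  *and* relative parameter change < `ptol` (default 1e-4), within
  `max_iter` = 100; non-convergence is a flagged result, not an error;
* parameters are unconstrained apart from overall positive definiteness
  of $V$ (see the note on $E$ above; a slightly negative variance
  estimate is informative, not an exception);
* starting values split the OLS residual variance between residual and
  genetic variances, covariances at zero;
* `theta_cov` is the inverse AI matrix at the optimum; with few levels
  behind a variance (the 39 breed groups) its symmetric SEs understate
  the skew of the sampling distribution, which is why single-replicate
  3-SE checks on $\sigma^2_g$ are fragile even though multi-replicate
  coverage is close to nominal.

`lr_test()` compares nested fits by $2\Delta\log L$ against a
chi-square; the HOM/HET comparison uses 2 degrees of freedom
($\sigma_{e1e2}$, $\sigma^2_{e2}$), ignoring boundary corrections —
consistent with treating $E$ as an unconstrained quadratic variance
function.

## Genotypes and the GRM

QC (`qc_filter()`): call rate ≥ 0.90, Hardy–Weinberg 1-df chi-square
p ≥ 1e-15, MAF ≥ 0.01.  A chi-square (not exact) HWE test suffices
because the threshold sits so deep in the tail that the two tests agree
there; the choice is recorded in the QC report.  Duplicate samples are
flagged at genotype correlation > 0.98; the default removes the
later-indexed member of each pair (a flag removes both).

`center_genotypes()` recodes to −1/0/+1 and centres by allele
frequency; missing calls are imputed to the mean dosage `2p`
beforehand, which preserves exact column centring.  Frequencies come
from the current panel by default — the only option without
base-population data — with a documented consequence: column centring
puts the all-ones vector in the null space of $G = WW'/d$, so the GRM
is *always* singular under sample-frequency centring.  `compute_grm()`
therefore adds a recorded ridge of `1e-6 × mean(diag(G))` when the
Cholesky factor signals singularity, making $G^{-1}$ (needed by
back-solving) well-defined; supplying external frequencies to
`center_genotypes()` yields a generically full-rank GRM and exact
back-solving identities.

## The multi-trait benchmark

`assign_sections()` splits the gradient at −1.13 / ±0.59 / +1.13 SD
into low/average/high, *excluding* animals in the two gaps, and
`fit_mtm()` treats section performance as three genetically correlated
traits (unstructured 3×3 over the GRM) with per-section residual
variances.  Between-section residual covariances are fixed at zero —
each animal contributes one record to one section, so they are
inestimable.  The ambiguous printed form of the average-section bounds
is read as $|x| < 0.59$; the exclusion gaps are what make the section
counts sum to less than the full data.  At desk scale the
cross-section covariances carry large SEs (each section may hold only a
few hundred animals), so tests of the no-interaction limit average over
section pairs rather than trusting single unconstrained correlation
estimates.

## GWAS by back-solving

`scale_correct()` removes the intercept-predictable part of the slope:
`component` mode uses $\sigma_{a1a2}/\sigma^2_{a1}$ from the fitted $K$
(the default, and the population-parameter reading of the correction);
`empirical` mode regresses the GEBV themselves, making the corrected
slope *exactly* orthogonal to the intercept GEBV in-sample.  Component
mode leaves a small residual correlation driven by finite GEBV accuracy
— the tests bound it rather than pretending it is zero.

`snp_pvalues()` offers two labelled approximations, because the exact
variance of a back-solved effect depends on prediction-error machinery
that is itself approximate: `empirical_sd` standardises by the SD of
all effects (appropriate under a highly polygenic null and the default
in the pipeline), and `backsolve_var` propagates a supplied GEBV
covariance through $W'G^{-1}\,\mathrm{Var}(\hat a)\,G^{-1}W/d^2$
(`gebv_covariance()` provides it from a kept model spec).  Two-sided
p-values use the t reference (`df = Inf`, the normal limit, by
default); the significance flag is Bonferroni at `alpha/m`.

## The synthetic-population generator

`sim_config()` defaults describe the data structure the analysis
assumes, at the body-weight scale of the motivating sheep application:
2000 animals genotyped at 2000 SNPs in 40 CGs from 100 sires; genetic
intercept/slope covariance `K = [6.98, 0.519; 0.519, 1.19]`
(kg², kg²/SD², correlation 0.18); residual coefficients
`E = [18.17, 1.55; 1.55, −0.32]`; group variance 10.88 kg² over 39
breed groups; CG growth-rate effects with SD 30 g/day (normal by
default, uniform available — their real distribution is unknown, so it
is configurable); 6% of sires confined to a single environment, the
rest guaranteed to span at least two; allele frequencies uniform on
(0.05, 0.5); sex/birth-type/rear-type effects of a few kg and a linear
age effect, with post-weaning ages inside 120–329 days.

Design points worth stating:

* **SNP effects generate the genetic values** (`u1`, `u2` drawn
  bivariate normal with covariance `K/d`, then `a = W u`), so
  back-solving has a recoverable ground truth — an animal-effect
  simulation could not test the GWAS stage.
* **Half-sib structure is genomic, not just labelled**: sire genotypes
  are simulated and each progeny receives one sampled paternal allele,
  so paternal half-sibs genuinely share ~0.25 relationships in `G`.
* Residuals are drawn per record as $N(0, \sigma^2_e(x_i))$ — exactly
  the model's marginal, valid even when `E` is indefinite, with a
  generation-time error if any implied variance is non-positive.
* Breed proportions: purebred rows with probability 0.3, otherwise
  symmetric Dirichlet over 3 groups.

What the generator does **not** emulate: linkage disequilibrium and QTL
placement (SNP effects are exchangeable across the map), selection and
multi-generation pedigrees, genotyping-platform artifacts, and any
nonlinearity of true reaction norms.  Passing tests therefore show that
the estimators recover the generating process *when the model is true*;
they cannot show robustness to LD structure or to model misspecification
on real data.

## Problem sizes and reproducibility

All simulations derive from a single integer seed (genotypes at `seed`,
phenotypes at `seed + 1`), and pipeline artifacts carry
version/seed/config-hash headers so reruns are bit-identical.  The test
suite exercises: oracle equivalence of the solver on 50 random
instances (n ≤ 20, tolerance 1e-8); parameter recovery at the reference
scale n = 2000, m = 2000, 40 CGs over 20 replicates (all seven
heterogeneous-residual parameters within 3 reported SEs in ≥ 18/20);
null calibration of the LRT (20 replicates at n = 500) and of GWAS
type-I error (m = 2000); and smaller designs for properties where the
full scale adds nothing but time.  Those sizes are the package's
reference conditions; anything larger is a matter of waiting, not of
different code paths.

## Known limitations

* Dense algebra throughout: fits are comfortable to a few thousand
  animals; national-evaluation scale would need sparse/iterative
  solvers out of scope here.
* The reaction norm is linear by construction; curvature in the true
  norm loads into the residual (HET) or biases the slope (HOM).
* Gradient estimation error is ignored downstream: the BLUE-based `x`
  enters the reaction norm as known, a standard but first-order
  approximation.
* `theta_cov`-based SEs are asymptotic; for variances supported by few
  levels (breed groups, small sections) their finite-sample coverage is
  asymmetric.
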