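# gxenorm

Genomic reaction-norm models for genotype-by-environment (G×E)
interaction in livestock body weight.

## The problem

The best animal in one environment is not necessarily the best in
another.  When no explicit environmental measurement exists for every
flock-year, the environment can be described by how well each
*contemporary group* (CG — a site × year × management cohort) grew: the
fixed-effect BLUE of CG from an animal model for post-weaning growth
rate, standardised to mean 0 and variance 1, forms a continuous
*environmental gradient* (EG).  A linear reaction norm then models each
animal's genomic breeding value as a function of the gradient,

```
y = X b + Z1 a1 + Z2 a2 + Q g + e,     (a1, a2) ~ N(0, G ⊗ K)
```

where `a1` (intercept) is average performance, `a2` (slope) is
environmental sensitivity — a flatter slope is a more *robust*
genotype — `G` is VanRaden's genomic relationship matrix, `K` the 2×2
intercept/slope covariance, `Q` breed-group proportions with random
group effects `g`, and `Z2 = Z1 diag(x)` for gradient values `x`.  The
residual is homogeneous (RNM-HOM) or a linear function of the gradient
(RNM-HET) with coefficient covariance `E`, giving per-record variance
`σ²e1 + 2xσe1e2 + x²σ²e2`.  Models are fitted by average-information
REML (GREML).  Environment-specific quantities come from
`V̂ = Λ K Λ′` and `R̂ = Λ E Λ′` with `Λ = [1, x]`: genetic variance
`Va(x)`, residual variance `Ve(x)`, heritability `h²(x) = Va/(Va+Ve)`
and between-environment genetic correlations.  A three-section
multi-trait model (low / average / high gradient sections as correlated
traits) benchmarks the reaction norm without assuming linearity.

For genome-wide association, GEBV are back-solved to per-SNP effects,
`û = W′G⁻¹a/d` with `d = 2Σp(1−p)`, for the intercept, the direct
slope, and the *scale-corrected* slope
`a2* = a2 − (σa1a2/σ²a1)·a1`, which removes the part of the slope
predictable from the intercept and isolates rank-type (re-ranking) G×E
from scale-type variance changes.

Because the motivating data are proprietary, the package includes a
first-class synthetic-population generator (`sim_config()`,
`simulate_population()`) with half-sib families spread across CGs,
breed-group proportions, SNP-mediated intercept/slope genetic values and
gradient-dependent residuals, so every stage is testable end to end.

## Worked example

```r
library(gxenorm)

cfg <- sim_config(n_animals = 1000, n_snps = 800, n_cg = 30,
                  n_sires = 60, seed = 42)
sim <- simulate_population(cfg)

qc  <- qc_filter(sim$panel)                      # call rate, HWE, MAF
grm <- compute_grm(center_genotypes(qc$panel))   # VanRaden method 1

flt  <- filter_for_gradient(sim$pheno)           # record filters
blue <- fit_cg_blue(flt$pheno, grm)              # CG BLUEs for growth rate
grad <- standardize_gradient(blue, flt$pheno)    # the gradient
#> Environmental gradient over 1000 animals in 30 CGs; range -1.86 to
#> 1.98 SD (1 SD = 28.03 g/day)

rnm_dat <- filter_for_rnm(sim$pheno, grad)$pheno
hom <- fit_rnm(rnm_dat, grad, grm, residual = "hom")
het <- fit_rnm(rnm_dat, grad, grm, residual = "het")
het
#> RNM-HET fit:
#>   sigma2_a1 = 7.955  sigma2_a2 = 0.629  r_a1a2 = 0.081
#>   sigma2_e1 = 15.738  sigma2_e2 = 1.330  sigma_e1e2 = 1.584
#>   sigma2_g = 12.518
#>   logL = -3003.9741
lr_test(hom, het, df = 2)      # does the residual change along the EG?
#> $statistic
#> [1] 5.4398
#> $p
#> [1] 0.06588134

compare_environments(variance_profile(het))
#> Environment comparison (RNM-HET)
#>  environment    x    Va    Ve     h2
#>          low -1.5 8.828 13.98 0.3871
#>      average  0.0 7.955 15.74 0.3358
#>         high  1.5 9.915 23.48 0.2969
#> Percent changes:
#>     from      to pct_Va pct_Ve pct_h2
#>      low average -9.888  12.57 -13.25
#>      low    high 12.309  67.96 -23.30
#>  average    high 24.633  49.21 -11.58
#> Genetic correlations:
#>           low average  high
#> low     1.000   0.917 0.699
#> average 0.917   1.000 0.926
#> high    0.699   0.926 1.000

scale_correct(het, mode = "component")
#> scale-corrected slope GEBV: a2* = a2 - 0.02277 a1 (component mode)
```

Here the intercept variance is ~8 kg², the slope variance ~0.6 kg²/SD²
(so genotypes differ in sensitivity), the residual variance grows ~68%
from the low- to the high-growth environment, heritability falls from
0.39 to 0.30 across the gradient, and the low/high genetic correlation
of 0.70 indicates genuine re-ranking of genotypes between environments.
The small correction coefficient (0.023) reflects the weak
intercept-slope correlation (0.08) in this simulated replicate.

GWAS tables follow with `backsolve_snp_effects()`, `snp_pvalues()` and
`association_summary()`; `run_pipeline(pipeline_config(...))` (or
`inst/scripts/gxenorm-pipeline.R`) orchestrates the whole chain and
writes tab-delimited reports.

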