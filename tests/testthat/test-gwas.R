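test_that("Bonferroni threshold reproduces -log10(alpha/m) for any inputs", {
  expect_equal(bonferroni_threshold(0.05, 60347), -log10(0.05 / 60347))
  expect_equal(bonferroni_threshold(0.05, 60347), 6.08, tolerance = 0.005)
  for (i in 1:5) {
    a <- runif(1, 0.001, 0.1); m <- sample(1e3:1e6, 1)
    expect_equal(bonferroni_threshold(a, m), -log10(a / m))
  }
})

test_that("genetic-regression coefficients match the component ratios", {
  ## sigma_a1a2 / sigma2_a1: ~0.216 for the homogeneous set (printed
  ## 0.21), ~0.074 for the heterogeneous set (printed 0.075)
  a1 <- rnorm(50); a2 <- rnorm(50)
  hom <- scale_correct(a1, a2, K = K_HOM)
  expect_equal(hom$coefficient, K_HOM[1, 2] / K_HOM[1, 1])
  expect_lt(abs(hom$coefficient - 0.21), 0.01)
  het <- scale_correct(a1, a2, K = K_HET)
  expect_lt(abs(het$coefficient - 0.075), 0.002)
  ## zero covariance: the slope is untouched
  none <- scale_correct(a1, a2, K = k_matrix(4, 2, cov = 0))
  expect_equal(none$a2_star, a2)
  expect_error(scale_correct(a1, a2, K = k_matrix(-1, 1, cov = 0)),
               "positive")
})

test_that("empirical-mode correction is exactly orthogonal to the intercept", {
  set.seed(81)
  a1 <- rnorm(200)
  a2 <- 0.4 * a1 + rnorm(200, 0, 0.5)
  cor_ <- scale_correct(a1, a2, mode = "empirical")
  expect_lt(abs(cov(a1, cor_$a2_star)), 1e-10)
})

test_that("back-solving satisfies its algebraic identities", {
  set.seed(82)
  d <- matrix(rbinom(50 * 500, 2, runif(500, 0.1, 0.5)), 50, 500,
              byrow = FALSE)
  ## base-population frequencies keep the GRM full rank (no ridge), so
  ## the algebraic identities hold exactly
  cg <- center_genotypes(tiny_panel(d, sprintf("an%02d", 1:50)),
                         freq = runif(500, 0.1, 0.5))
  grm <- compute_grm(cg)
  expect_equal(grm$ridge_used, 0)
  ## a = 0 -> u = 0
  zero <- backsolve_snp_effects(cg, grm, rep(0, 50))
  expect_equal(unname(zero), rep(0, 500))
  ## a = G e1 -> u_j = W[1, j] / d
  a <- grm$G[, 1]
  u <- backsolve_snp_effects(cg, grm, unname(a))
  expect_equal(unname(u), unname(cg$W[1, ] / cg$d), tolerance = 1e-8)
  ## round trip: W u = a at full rank
  a2 <- rnorm(50)
  u2 <- backsolve_snp_effects(cg, grm, a2)
  expect_equal(unname(drop(cg$W %*% u2)), a2, tolerance = 1e-8)
  ## linearity
  b <- rnorm(50)
  expect_equal(backsolve_snp_effects(cg, grm, a2 + 2 * b),
               u2 + 2 * backsolve_snp_effects(cg, grm, b),
               tolerance = 1e-10)
  ## misaligned ids are an error
  expect_error(backsolve_snp_effects(cg, grm,
                                     stats::setNames(a2, paste0("x", 1:50))),
               "does not cover")
})

test_that("true SNP effects are better recovered than a permuted control", {
  pop <- small_population(seed = 83, n = 500, m = 400)
  ids <- pop$sim$pheno$animal_id
  cg <- center_genotypes(pop$sim$panel)
  u <- backsolve_snp_effects(cg, pop$grm,
                             stats::setNames(pop$sim$truth$a1_true, ids))
  r_true <- cor(abs(u), abs(pop$sim$truth$u1), method = "spearman")
  set.seed(1)
  r_perm <- cor(abs(u), abs(sample(pop$sim$truth$u1)), method = "spearman")
  expect_gt(r_true, r_perm)
  expect_gt(r_true, 0.2)
})

test_that("p-values behave under both testing modes", {
  set.seed(84)
  d <- matrix(rbinom(100 * 300, 2, runif(300, 0.1, 0.5)), 100, 300,
              byrow = FALSE)
  cg <- center_genotypes(tiny_panel(d, sprintf("an%03d", 1:100)))
  grm <- compute_grm(cg)
  a <- rnorm(100)
  u <- backsolve_snp_effects(cg, grm, a)
  pv <- snp_pvalues(u, cg, grm, method = "empirical_sd")
  expect_true(all(pv$p > 0 & pv$p <= 1))
  ## z = 1.96 -> p ~ 0.05 in the normal limit
  i <- which.min(abs(abs(pv$z) - 1.96))
  expect_equal(pv$p[i], 2 * pnorm(-abs(pv$z[i])))
  ## back-solved-variance mode with a known GEBV covariance
  pv2 <- snp_pvalues(u, cg, grm, method = "backsolve_var",
                     gebv_cov = diag(0.5, 100))
  expect_true(all(pv2$se > 0))
  expect_equal(nrow(pv2), 300)
  ## degenerate effects are refused
  expect_error(snp_pvalues(rep(0.3, 300), cg, grm), "zero SD")
})

test_that("null GEBV give calibrated type-I error at m = 2000", {
  set.seed(85)
  n <- 300; m <- 2000
  d <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)), n, m, byrow = FALSE)
  cg <- center_genotypes(tiny_panel(d, sprintf("an%03d", 1:n)))
  grm <- compute_grm(cg)
  a <- rnorm(n)                     # independent of the genotypes
  u <- backsolve_snp_effects(cg, grm, a)
  pv <- snp_pvalues(u, cg, grm, method = "empirical_sd")
  frac <- mean(pv$p < 0.05)
  expect_lt(abs(frac - 0.05), 1.96 * sqrt(0.05 * 0.95 / m))
  expect_equal(sum(pv$significant), 0)
})

test_that("scale correction reduces the slope-intercept effect correlation", {
  ## GEBV computed by BLUP at the generating variance components; the
  ## corrected slope effects should correlate far less with the
  ## intercept effects than the direct ones do (majority over replicates)
  wins <- 0L
  for (s in 1:10) {
    pop <- small_population(seed = 900 + s, n = 400, m = 300,
                            K_true = K_HOM, E_true = SIGMA2_E_HOM)
    sim <- pop$sim
    ids <- sim$pheno$animal_id
    x <- sim$truth$x_true
    G <- pop$grm$G
    X <- matrix(1, length(ids), 1)
    spec <- model_spec(sim$pheno$pwwt - sim$truth$Q %*% sim$truth$g_true,
                       X, random = rand_regression(x, M = G),
                       residual = resid_hom())
    sol <- solve_mme(spec, c(K_HOM[1, 1], K_HOM[1, 2], K_HOM[2, 2],
                             SIGMA2_E_HOM))
    a1 <- stats::setNames(sol$u[[1]][, "intercept"], ids)
    a2 <- stats::setNames(sol$u[[1]][, "slope"], ids)
    cg <- center_genotypes(sim$panel)
    u1 <- backsolve_snp_effects(cg, pop$grm, a1)
    u2 <- backsolve_snp_effects(cg, pop$grm, a2)
    a2s <- stats::setNames(scale_correct(a1, a2, K = K_HOM)$a2_star, ids)
    u2s <- backsolve_snp_effects(cg, pop$grm, a2s)
    if (abs(cor(u2s, u1)) < abs(cor(u2, u1))) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("association summaries compare runs and track significance changes", {
  set.seed(86)
  d <- matrix(rbinom(60 * 200, 2, runif(200, 0.2, 0.5)), 60, 200,
              byrow = FALSE)
  cg <- center_genotypes(tiny_panel(d, sprintf("an%02d", 1:60)))
  grm <- compute_grm(cg)
  a <- rnorm(60)
  u <- backsolve_snp_effects(cg, grm, a)
  r1 <- snp_pvalues(u, cg, grm, target = "intercept")
  r2 <- snp_pvalues(u, cg, grm, target = "slope_direct")
  summ <- association_summary(list(intercept = r1, slope_direct = r2))
  ## identical runs correlate exactly
  expect_equal(unname(summ$effect_cor["intercept", "slope_direct"]), 1)
  ## association tables round-trip through the PLINK-style writer
  td <- withr::local_tempdir()
  write_association(r1, file.path(td, "assoc.tsv"),
                    file.path(td, "manhattan.tsv"))
  back <- read.delim(file.path(td, "assoc.tsv"), comment.char = "#")
  expect_equal(back$BETA, r1$effect, tolerance = 1e-9)
  expect_equal(names(back), c("CHR", "SNP", "BP", "A1", "FREQ", "BETA",
                              "SE", "P"))
})
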