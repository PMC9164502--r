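test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_animals = 1), "positive")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(K_true = matrix(c(1, 2, 3, 4), 2)), "symmetric")
  expect_error(sim_config(K_true = matrix(c(1, 2, 2, 1), 2)),
               "semi-definite")
  expect_error(sim_config(E_true = -1), "must be > 0")
})

test_that("a fixed seed reproduces the population bit-for-bit", {
  cfg <- sim_config(n_animals = 120, n_snps = 80, n_cg = 6, n_sires = 12,
                    missing_rate = 0.02, seed = 5)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$panel$dosage, s2$panel$dosage)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$truth$u1, s2$truth$u1)
})

test_that("zero missing rate gives complete calls; positive rate is honoured", {
  cfg <- sim_config(n_animals = 150, n_snps = 100, n_cg = 6, n_sires = 10,
                    seed = 2)
  panel <- simulate_genotypes(cfg)
  expect_false(anyNA(panel$dosage))
  expect_true(all(colMeans(!is.na(panel$dosage)) == 1))
  cfg2 <- sim_config(n_animals = 300, n_snps = 200, n_cg = 6, n_sires = 10,
                     missing_rate = 0.05, seed = 2)
  panel2 <- simulate_genotypes(cfg2)
  expect_lt(abs(mean(is.na(panel2$dosage)) - 0.05), 0.005)
})

test_that("allele frequencies follow the binomial sampling model", {
  ## single SNP pinned at p = 0.3 in 5000 animals: the observed frequency
  ## should sit within 3 binomial SEs of the target
  cfg <- sim_config(n_animals = 5000, n_snps = 1, n_cg = 10, n_sires = 100,
                    maf_range = c(0.3, 0.3), seed = 42)
  panel <- simulate_genotypes(cfg)
  p_hat <- mean(panel$dosage) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 5000))
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("sires span several contemporary groups except the single-environment fraction", {
  cfg <- sim_config(n_animals = 600, n_snps = 50, n_cg = 20, n_sires = 50,
                    single_env_sire_frac = 0.1, seed = 8)
  panel <- simulate_genotypes(cfg)
  ped <- panel$pedigree
  ncg <- tapply(ped$cg_id, ped$sire_id, function(x) length(unique(x)))
  expect_equal(sum(ncg == 1), 5)           # 10% of 50 sires
  expect_true(all(ncg[ncg > 1] >= 2))
})

test_that("half-sib families carry elevated genomic relationships", {
  pop <- small_population(seed = 31, n = 400, m = 500, n_sires = 20)
  ped <- pop$sim$panel$pedigree
  G <- pop$grm$G
  fam <- split(seq_len(nrow(ped)), ped$sire_id)
  offdiag <- function(ix) {
    g <- G[ix, ix]
    mean(g[upper.tri(g)])
  }
  within_fam <- mean(vapply(fam, offdiag, numeric(1)))
  overall <- mean(G[upper.tri(G)])
  ## half sibs: expected additive relationship 0.25 vs ~0 unrelated
  expect_gt(within_fam, 0.15)
  expect_lt(abs(overall), 0.05)
})

test_that("true breeding values are the centred genotypes times the SNP effects", {
  pop <- small_population(seed = 32, n = 200, m = 150)
  cg <- center_genotypes(pop$sim$panel)
  expect_equal(pop$sim$truth$a1_true, drop(cg$W %*% pop$sim$truth$u1),
               tolerance = 1e-10)
  expect_equal(pop$sim$truth$a2_true, drop(cg$W %*% pop$sim$truth$u2),
               tolerance = 1e-10)
})

test_that("degenerate generating covariances behave as limits", {
  ## no slope variance -> all slope breeding values exactly zero
  cfg <- sim_config(n_animals = 150, n_snps = 100, n_cg = 6, n_sires = 10,
                    K_true = diag(c(4, 0)), E_true = 17.52, seed = 3)
  sim <- simulate_population(cfg)
  expect_lt(var(sim$truth$a2_true), 1e-20)
  ## scalar residual and a zeroed residual slope block give identical
  ## phenotypes: the homogeneous limit of the variance function
  cfg_a <- sim_config(n_animals = 150, n_snps = 100, n_cg = 6, n_sires = 10,
                      E_true = 17.52, seed = 3)
  cfg_b <- sim_config(n_animals = 150, n_snps = 100, n_cg = 6, n_sires = 10,
                      E_true = matrix(c(17.52, 0, 0, 0), 2), seed = 3)
  expect_equal(simulate_population(cfg_a)$pheno$pwwt,
               simulate_population(cfg_b)$pheno$pwwt, tolerance = 1e-12)
})

test_that("realised breeding-value covariance matches the generating K", {
  ## intercept-slope regression 1.60/7.40 = 0.216 at n = m = 2000
  cfg <- sim_config(K_true = K_HOM, E_true = SIGMA2_E_HOM, seed = 13)
  sim <- simulate_population(cfg)
  ratio <- cov(sim$truth$a1_true, sim$truth$a2_true) /
    var(sim$truth$a1_true)
  expect_equal(ratio, 0.216, tolerance = 0.1 * 0.216)
  ## replicated Monte-Carlo check of each K entry at smaller size
  reps <- t(vapply(1:20, function(s) {
    sm <- simulate_population(sim_config(n_animals = 1000, n_snps = 300,
                                         n_cg = 10, n_sires = 50,
                                         K_true = K_HOM,
                                         E_true = SIGMA2_E_HOM,
                                         seed = 400 + s))
    c(var(sm$truth$a1_true), cov(sm$truth$a1_true, sm$truth$a2_true),
      var(sm$truth$a2_true))
  }, numeric(3)))
  truth <- c(K_HOM[1, 1], K_HOM[1, 2], K_HOM[2, 2])
  for (j in 1:3) {
    mc_se <- sd(reps[, j]) / sqrt(nrow(reps))
    expect_lt(abs(mean(reps[, j]) - truth[j]), 3 * mc_se + 1e-12)
  }
})

test_that("the simulated environment is standardised and CG-constant", {
  pop <- small_population(seed = 33, n = 400, m = 100)
  x <- pop$sim$truth$x_true
  expect_equal(mean(x), 0, tolerance = 1e-10)
  expect_equal(var(x), 1, tolerance = 1e-10)
  expect_true(all(tapply(x, pop$sim$pheno$cg_id, function(v)
    max(v) - min(v)) < 1e-12))
})

test_that("breed proportions sum to one with purebred rows present", {
  pop <- small_population(seed = 34, n = 300, m = 50)
  Q <- pop$sim$truth$Q
  expect_equal(unname(rowSums(Q)), rep(1, 300), tolerance = 1e-10)
  expect_true(any(apply(Q, 1, max) == 1))        # purebreds exist
  expect_true(any(apply(Q, 1, max) < 1))         # crossbreds exist
})

test_that("impossible residual variance along the gradient is a generation error", {
  cfg <- sim_config(n_animals = 200, n_snps = 50, n_cg = 10, n_sires = 10,
                    E_true = matrix(c(1, 0, 0, -2), 2), seed = 4)
  panel <- simulate_genotypes(cfg)
  expect_error(simulate_phenotypes(panel, cfg),
               "residual variance non-positive at x")
})

test_that("a simulated population survives a disk round-trip", {
  pop <- small_population(seed = 35, n = 80, m = 40, n_cg = 5, n_sires = 8)
  td <- withr::local_tempdir()
  write_simulation(pop$sim, td, header_lines = c("seed: 35"))
  panel <- read_dosage_panel(file.path(td, "genotypes.tsv"),
                             file.path(td, "map.tsv"))
  expect_equal(panel$dosage, pop$sim$panel$dosage)
  ph <- read_phenotypes(file.path(td, "phenotypes.tsv"))
  expect_equal(ph$pwwt, pop$sim$pheno$pwwt, tolerance = 1e-9)
})
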