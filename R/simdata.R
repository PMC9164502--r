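#' Synthetic populations for reaction-norm analysis
#'
#' Generates populations with the structure the downstream analysis
#' assumes: half-sib families whose progeny are spread over contemporary
#' groups (CGs) spanning a growth-rate gradient, breed-group proportions,
#' SNP-mediated intercept and slope genetic values with a 2x2 covariance
#' `K`, a random genetic-group effect, and residuals whose variance may
#' change along the gradient through a 2x2 residual coefficient
#' covariance `E`.  Because genetic values are built from per-SNP effects,
#' the back-solving GWAS stage has a recoverable ground truth.
#'
#' Default parameter values are the body-weight scale of the motivating
#' sheep application: genetic intercept variance ~7 kg^2, slope variance
#' ~1.2 kg^2/SD^2, residual intercept variance ~18 kg^2 with a negative
#' residual slope variance (the residual model is a quadratic variance
#' function, not a positive-definite covariance), genetic-group variance
#' ~11 kg^2, and CG growth-rate effects with SD 30 g/day.
#'
#' @name simdata
NULL

#' Configuration for the synthetic-population generator
#'
#' @param n_animals,n_snps,n_cg,n_sires,n_breed_groups population sizes.
#' @param maf_range range of per-SNP allele frequencies, within (0, 0.5].
#' @param K_true 2x2 genetic covariance of intercept (kg^2) and slope
#'   (kg^2/SD^2) effects; must be symmetric positive semi-definite.
#' @param E_true 2x2 residual coefficient covariance (kg^2 scale), or a
#'   single scalar residual variance for the homogeneous mode.  `E_true`
#'   need not be positive definite; only the implied per-record residual
#'   variance over the simulated gradient must be positive.
#' @param sigma2_g genetic-group variance (kg^2).
#' @param cg_effect_sd SD of true CG growth-rate effects (g/day).
#' @param cg_effect_dist distribution of CG effects, `"normal"` or
#'   `"uniform"` (matched SD).
#' @param fixed_effect_levels named list of fixed-effect specifications:
#'   `sex`, `birth_type`, `rear_type` (named effect vectors, kg),
#'   `age_slope` (kg/day), `pwgr_sex` (g/day), plus `wean_age_range` and
#'   `growth_period_range` (days).
#' @param pwgr_mean,pwwt_mean trait means (g/day; kg).
#' @param sigma2_a_pwgr,sigma2_e_pwgr genetic and residual variance of
#'   post-weaning growth rate ((g/day)^2).
#' @param missing_rate fraction of genotype calls set missing, in [0, 1).
#' @param single_env_sire_frac fraction of sires whose progeny are
#'   confined to a single CG (the rest span at least two, providing the
#'   genetic links across environments that identify the slope).
#' @param purebred_frac fraction of animals assigned to a single breed
#'   group; the rest get symmetric-Dirichlet proportions over
#'   `n_cross_groups` groups.
#' @param n_cross_groups breed groups contributing to a crossbred animal.
#' @param seed integer seed governing all randomness.
#' @return validated configuration of class `sim_config`.
#' @export
sim_config <- function(n_animals = 2000L,
                       n_snps = 2000L,
                       n_cg = 40L,
                       n_sires = 100L,
                       n_breed_groups = 39L,
                       maf_range = c(0.05, 0.5),
                       K_true = matrix(c(6.98, 0.519, 0.519, 1.19), 2, 2),
                       E_true = matrix(c(18.17, 1.55, 1.55, -0.32), 2, 2),
                       sigma2_g = 10.88,
                       cg_effect_sd = 30,
                       cg_effect_dist = c("normal", "uniform"),
                       fixed_effect_levels = list(),
                       pwgr_mean = 150, pwwt_mean = 45,
                       sigma2_a_pwgr = 300, sigma2_e_pwgr = 700,
                       missing_rate = 0,
                       single_env_sire_frac = 0.06,
                       purebred_frac = 0.3,
                       n_cross_groups = 3L,
                       seed = 1L) {
  cg_effect_dist <- match.arg(cg_effect_dist)
  err <- function(...) stop("sim_config: ", ..., call. = FALSE)
  if (n_animals < 2 || n_snps < 1 || n_cg < 1 || n_sires < 1 ||
      n_breed_groups < 1)
    err("population sizes must be positive (n_animals >= 2)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    err("maf_range must lie within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    err("missing_rate must be in [0, 1)")
  K_true <- as.matrix(K_true)
  if (!isTRUE(all.equal(K_true, t(K_true)))) err("K_true must be symmetric")
  if (min(eigen(K_true, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * max(abs(K_true)))
    err("K_true must be positive semi-definite")
  if (length(E_true) == 1L) {
    if (E_true <= 0) err("scalar E_true (residual variance) must be > 0")
  } else {
    E_true <- as.matrix(E_true)
    if (!isTRUE(all.equal(E_true, t(E_true)))) err("E_true must be symmetric")
  }
  fx <- utils::modifyList(list(
    sex = c(F = 0, M = 3),
    birth_type = c(`1` = 0, `2` = -1.5, `3` = -3),
    rear_type = c(`1` = 0, `2` = -2),
    age_slope = 0.06,
    pwgr_sex = c(F = 0, M = 15),
    wean_age_range = c(64, 120),
    growth_period_range = c(60, 200)), fixed_effect_levels)
  structure(list(n_animals = as.integer(n_animals),
                 n_snps = as.integer(n_snps), n_cg = as.integer(n_cg),
                 n_sires = as.integer(n_sires),
                 n_breed_groups = as.integer(n_breed_groups),
                 maf_range = maf_range, K_true = K_true, E_true = E_true,
                 sigma2_g = sigma2_g, cg_effect_sd = cg_effect_sd,
                 cg_effect_dist = cg_effect_dist,
                 fixed_effects = fx, pwgr_mean = pwgr_mean,
                 pwwt_mean = pwwt_mean, sigma2_a_pwgr = sigma2_a_pwgr,
                 sigma2_e_pwgr = sigma2_e_pwgr,
                 missing_rate = missing_rate,
                 single_env_sire_frac = single_env_sire_frac,
                 purebred_frac = purebred_frac,
                 n_cross_groups = as.integer(n_cross_groups),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.pad_id <- function(prefix, i, n) {
  sprintf(paste0(prefix, "%0", nchar(as.character(n)), "d"), i)
}

#' Simulate a genotype panel with half-sib family structure
#'
#' Per-SNP allele frequencies are uniform over `maf_range`.  Sire
#' genotypes are drawn binomial(2, p); each progeny receives one allele
#' sampled from its sire and one from the population, so paternal
#' half-sibs share genuine genomic relationships.  Progeny of a sire are
#' spread over at least two CGs unless the sire belongs to the
#' single-environment fraction.  The marker map (26 chromosomes, 1-based
#' bp) is drawn deterministically from the seed.
#'
#' @param config a [sim_config()].
#' @return a [genotype_panel()] with an extra `pedigree` element
#'   (data.frame `animal_id`, `sire_id`, `dam_id`, `cg_id`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_animals; m <- config$n_snps
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  ## map: 26 chromosomes, sorted random positions
  chrom <- rep(seq_len(26), length.out = m)
  chrom <- sort(chrom)
  bp <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(2.5e8, length(ix)))), use.names = FALSE)
  map <- data.frame(chrom = chrom,
                    snp_id = .pad_id("snp", seq_len(m), m),
                    bp = bp, allele1 = "B", allele2 = "A",
                    stringsAsFactors = FALSE)

  ## half-sib families
  sire <- sample(rep(seq_len(config$n_sires), length.out = n))
  sire_dos <- matrix(stats::rbinom(config$n_sires * m, 2, rep(p, each = config$n_sires)),
                     config$n_sires, m)
  pat_p <- sire_dos[sire, , drop = FALSE] / 2
  pat <- matrix(stats::rbinom(n * m, 1, pat_p), n, m)
  mat <- matrix(stats::rbinom(n * m, 1, rep(p, each = n)), n, m)
  dosage <- pat + mat

  ## CG assignment: single-environment sires confined to one CG, the rest
  ## guaranteed to span at least two
  cg <- sample.int(config$n_cg, n, replace = TRUE)
  n_single <- floor(config$single_env_sire_frac * config$n_sires)
  single_sires <- if (n_single > 0)
    sample.int(config$n_sires, n_single) else integer(0)
  for (s in seq_len(config$n_sires)) {
    ix <- which(sire == s)
    if (length(ix) < 2) next
    if (s %in% single_sires) {
      cg[ix] <- cg[ix[1]]
    } else if (length(unique(cg[ix])) == 1L) {
      others <- setdiff(seq_len(config$n_cg), cg[ix[1]])
      cg[ix[1]] <- if (length(others)) sample(others, 1) else cg[ix[1]]
    }
  }

  if (config$missing_rate > 0)
    dosage[stats::runif(n * m) < config$missing_rate] <- NA

  ids <- .pad_id("an", seq_len(n), n)
  panel <- genotype_panel(dosage, map, animal_ids = ids)
  panel$pedigree <- data.frame(
    animal_id = ids,
    sire_id = .pad_id("s", sire, config$n_sires),
    dam_id = .pad_id("d", seq_len(n), n),
    cg_id = .pad_id("cg", cg, config$n_cg),
    stringsAsFactors = FALSE)
  panel
}

.resid_var_fun <- function(E, x) {
  if (length(E) == 1L) rep(as.numeric(E), length(x))
  else E[1, 1] + 2 * x * E[1, 2] + x^2 * E[2, 2]
}

#' Simulate phenotypes and record the generating truth
#'
#' Growth-rate records are built from true CG effects, an additive
#' genetic effect and noise; body-weight records from fixed effects, the
#' SNP-mediated intercept value, the slope value times the animal's
#' standardised environment, a breed-group effect and a residual whose
#' variance follows the quadratic function of the gradient implied by
#' `E_true`.  Per-SNP intercept/slope effects are drawn bivariate normal
#' with covariance `K_true / d` so the realised breeding-value covariance
#' approaches `K_true`.
#'
#' @param panel a panel from [simulate_genotypes()] (with its pedigree).
#' @param config the same [sim_config()].
#' @return list with `pheno` (data.frame; one row per animal with ids,
#'   CG, fixed-effect covariates, `pwgr`, `pwwt`, `genotyped` and breed
#'   proportion columns `bg*`) and `truth` (class `sim_truth`: per-SNP
#'   effects `u1`, `u2`, true breeding values, group and CG effects,
#'   `x_true`, pedigree, `Q`).
#' @export
simulate_phenotypes <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  if (is.null(panel$pedigree))
    stop("panel has no pedigree; use simulate_genotypes()", call. = FALSE)
  n <- length(panel$animal_ids)
  if (n != config$n_animals)
    stop("panel animals do not match config", call. = FALSE)
  set.seed(config$seed + 1L)
  fx <- config$fixed_effects
  ped <- panel$pedigree

  ## centred genotypes (monomorphic columns contribute nothing)
  pfreq <- .allele_freq(panel$dosage)
  d0 <- panel$dosage
  if (anyNA(d0)) {
    idx <- which(is.na(d0), arr.ind = TRUE)
    d0[idx] <- 2 * pfreq[idx[, 2]]
  }
  W <- sweep(d0, 2, 2 * pfreq)
  dscale <- 2 * sum(pfreq * (1 - pfreq))

  ## per-SNP effects: bivariate normal, covariance K_true / d
  m <- ncol(W)
  Lk <- .chol_psd(config$K_true / dscale)
  U <- matrix(stats::rnorm(m * 2), m, 2) %*% t(Lk)
  u1 <- U[, 1]; u2 <- U[, 2]
  a1_true <- drop(W %*% u1)
  a2_true <- drop(W %*% u2)
  u_pwgr <- stats::rnorm(m, 0, sqrt(config$sigma2_a_pwgr / dscale))
  a_pwgr <- drop(W %*% u_pwgr)

  ## CG effects (g/day) and the standardised environment they induce
  cg_lev <- sort(unique(ped$cg_id))
  cg_true <- switch(config$cg_effect_dist,
    normal = stats::rnorm(length(cg_lev), 0, config$cg_effect_sd),
    uniform = stats::runif(length(cg_lev), -sqrt(3) * config$cg_effect_sd,
                           sqrt(3) * config$cg_effect_sd))
  names(cg_true) <- cg_lev
  cg_vals <- cg_true[ped$cg_id]
  x_true <- (cg_vals - mean(cg_vals)) / stats::sd(cg_vals)
  x_true <- unname(x_true)

  ve <- .resid_var_fun(config$E_true, x_true)
  if (any(ve <= 0))
    stop("implied residual variance non-positive at x = ",
         paste(signif(x_true[ve <= 0][1], 4)),
         "; adjust E_true or the gradient range", call. = FALSE)

  ## breed-group proportions
  Q <- matrix(0, n, config$n_breed_groups)
  colnames(Q) <- .pad_id("bg", seq_len(config$n_breed_groups),
                         config$n_breed_groups)
  pure <- stats::runif(n) < config$purebred_frac
  k <- min(config$n_cross_groups, config$n_breed_groups)
  for (i in seq_len(n)) {
    if (pure[i] || config$n_breed_groups == 1L) {
      Q[i, sample.int(config$n_breed_groups, 1)] <- 1
    } else {
      gix <- sample.int(config$n_breed_groups, k)
      w <- stats::rgamma(k, 1)           # symmetric Dirichlet(1)
      Q[i, gix] <- w / sum(w)
    }
  }
  g_true <- stats::rnorm(config$n_breed_groups, 0, sqrt(config$sigma2_g))
  names(g_true) <- colnames(Q)

  ## covariates
  sex <- sample(names(fx$sex), n, replace = TRUE)
  bt_prob <- if (length(fx$birth_type) == 3L) c(0.4, 0.45, 0.15) else NULL
  rt_prob <- if (length(fx$rear_type) == 2L) c(0.6, 0.4) else NULL
  birth_type <- sample(names(fx$birth_type), n, replace = TRUE, prob = bt_prob)
  rear_type <- sample(names(fx$rear_type), n, replace = TRUE, prob = rt_prob)
  wean_age <- round(stats::runif(n, fx$wean_age_range[1], fx$wean_age_range[2]))
  period <- round(stats::runif(n, fx$growth_period_range[1],
                               fx$growth_period_range[2]))
  postwean_age <- wean_age + period

  pwgr <- config$pwgr_mean + fx$pwgr_sex[sex] + cg_vals + a_pwgr +
    stats::rnorm(n, 0, sqrt(config$sigma2_e_pwgr))
  age_c <- postwean_age - mean(postwean_age)
  pwwt <- config$pwwt_mean + fx$sex[sex] + fx$birth_type[birth_type] +
    fx$rear_type[rear_type] + fx$age_slope * age_c +
    a1_true + x_true * a2_true + drop(Q %*% g_true) +
    stats::rnorm(n, 0, sqrt(ve))

  pheno <- data.frame(animal_id = ped$animal_id, sire_id = ped$sire_id,
                      dam_id = ped$dam_id, cg_id = ped$cg_id,
                      sex = sex, birth_type = as.integer(birth_type),
                      rear_type = as.integer(rear_type),
                      wean_age = wean_age, postwean_age = postwean_age,
                      pwgr = unname(pwgr), pwwt = unname(pwwt),
                      genotyped = TRUE, stringsAsFactors = FALSE)
  pheno <- cbind(pheno, as.data.frame(Q))
  truth <- structure(list(u1 = u1, u2 = u2, u_pwgr = u_pwgr,
                          a1_true = a1_true, a2_true = a2_true,
                          g_true = g_true, cg_true = cg_true,
                          x_true = x_true, pedigree = ped, Q = Q,
                          config = config),
                     class = "sim_truth")
  list(pheno = pheno, truth = truth)
}

.chol_psd <- function(S) {
  ## lower-triangular factor of a symmetric PSD matrix (eigen fallback for
  ## semi-definite cases where chol() fails)
  ch <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  ei <- eigen(S, symmetric = TRUE)
  ei$vectors %*% diag(sqrt(pmax(ei$values, 0)), nrow(S))
}

#' Simulate a complete population
#'
#' Convenience wrapper running [simulate_genotypes()] and
#' [simulate_phenotypes()].
#'
#' @inheritParams simulate_genotypes
#' @return list with `panel`, `pheno`, `truth`.
#' @export
simulate_population <- function(config) {
  panel <- simulate_genotypes(config)
  ph <- simulate_phenotypes(panel, config)
  list(panel = panel, pheno = ph$pheno, truth = ph$truth)
}

#' Write a simulated population to tab-delimited files
#'
#' Writes `genotypes.tsv` + `map.tsv` (dosage panel), `phenotypes.tsv`,
#' and the generating truth (`truth_snp.tsv`, `truth_animal.tsv`,
#' `truth_group.tsv`, `truth_cg.tsv`).
#'
#' @param sim result of [simulate_population()].
#' @param dir output directory (created if needed).
#' @param header_lines provenance comment lines for every file.
#' @export
write_simulation <- function(sim, dir, header_lines = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dosage_panel(sim$panel, file.path(dir, "genotypes.tsv"),
                     file.path(dir, "map.tsv"), header_lines)
  write_phenotypes(sim$pheno, file.path(dir, "phenotypes.tsv"),
                   header_lines)
  tr <- sim$truth
  .write_tsv(data.frame(snp_id = sim$panel$map$snp_id, u1 = tr$u1,
                        u2 = tr$u2, u_pwgr = tr$u_pwgr),
             file.path(dir, "truth_snp.tsv"), header_lines)
  .write_tsv(data.frame(animal_id = tr$pedigree$animal_id,
                        a1_true = tr$a1_true, a2_true = tr$a2_true,
                        x_true = tr$x_true),
             file.path(dir, "truth_animal.tsv"), header_lines)
  .write_tsv(data.frame(group = names(tr$g_true), g_true = tr$g_true),
             file.path(dir, "truth_group.tsv"), header_lines)
  .write_tsv(data.frame(cg_id = names(tr$cg_true), cg_true = tr$cg_true),
             file.path(dir, "truth_cg.tsv"), header_lines)
  invisible(dir)
}
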