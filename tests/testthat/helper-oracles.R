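# Dense GLS / direct-likelihood oracle, independent of the package's
# solver path: V is built explicitly by the caller and everything is
# computed by textbook formulas with solve().
gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  n <- length(y)
  p <- ncol(X)
  logL <- -0.5 * ((n - p) * log(2 * pi) +
                    as.numeric(determinant(V)$modulus) +
                    as.numeric(determinant(XtViX)$modulus) +
                    drop(t(y) %*% P %*% y))
  list(beta = drop(beta), logL = logL, P = P)
}

# random small mixed-model instance: one identity-relationship random
# term with q levels plus homogeneous residual
random_instance <- function(n, seed) {
  set.seed(seed)
  q <- sample(2:4, 1)
  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), sample(q, n, replace = TRUE))] <- 1
  X <- cbind(1, stats::rnorm(n))
  colnames(X) <- c("mu", "cov")
  theta <- c(stats::runif(1, 0.2, 2), stats::runif(1, 0.5, 2))
  y <- drop(X %*% c(1, 0.5) + Z %*% stats::rnorm(q, 0, sqrt(theta[1])) +
              stats::rnorm(n, 0, sqrt(theta[2])))
  list(y = y, X = X, Z = Z, theta = theta,
       V = theta[1] * tcrossprod(Z) + theta[2] * diag(n))
}

# tiny genotype panel from a dosage matrix, map synthesised
tiny_panel <- function(dosage, ids = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  map <- data.frame(chrom = 1L, snp_id = sprintf("s%03d", seq_len(m)),
                    bp = seq_len(m) * 1000L, allele1 = "B", allele2 = "A")
  genotype_panel(dosage, map, animal_ids = ids)
}

# small simulated population + GRM + truth-valued gradient, shared by
# several test files
small_population <- function(seed, n = 500, m = 400, n_cg = 20,
                             n_sires = 40, ...) {
  cfg <- sim_config(n_animals = n, n_snps = m, n_cg = n_cg,
                    n_sires = n_sires, seed = seed, ...)
  sim <- simulate_population(cfg)
  grm <- compute_grm(center_genotypes(sim$panel))
  grad <- env_gradient(stats::setNames(sim$truth$x_true,
                                       sim$pheno$animal_id))
  list(sim = sim, grm = grm, grad = grad, cfg = cfg)
}

# variance components used throughout as generating values (body-weight
# scale): homogeneous- and heterogeneous-residual parameter sets
K_HOM <- k_matrix(7.40, 1.28, r = 0.52)
K_HET <- k_matrix(6.98, 1.19, r = 0.18)
E_HET <- matrix(c(18.17, 1.55, 1.55, -0.32), 2, 2)
SIGMA2_E_HOM <- 17.52
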