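#' Linear reaction-norm models for body weight
#'
#' The reaction-norm model regresses each animal's breeding value on the
#' standardised environmental gradient \eqn{x}:
#' \deqn{y = Xb + Z_1 a_1 + Z_2 a_2 + Q g + e,}
#' with intercept and slope breeding values
#' \eqn{(a_1, a_2) \sim N(0, G \otimes K)}, random genetic-group effects
#' \eqn{g \sim N(0, I\sigma^2_g)} through the breed-proportion matrix
#' \eqn{Q}, and \eqn{Z_2 = Z_1 \mathrm{diag}(x)}.  The residual is either
#' homogeneous (RNM-HOM) or a linear function of the gradient with
#' coefficient covariance `E` (RNM-HET), giving per-record variance
#' \eqn{\sigma^2_{e1} + 2x\sigma_{e1e2} + x^2\sigma^2_{e2}}.  Fixed
#' effects are sex, birth type, rear type, age at post-weaning (linear)
#' and CG.
#'
#' Environment-specific quantities derive from \eqn{\hat V = \Lambda K
#' \Lambda'} and \eqn{\hat R = \Lambda E \Lambda'} with
#' \eqn{\Lambda = [1, x]}: genetic variance
#' \eqn{V_a(x) = \sigma^2_{a1} + 2x\sigma_{a1a2} + x^2\sigma^2_{a2}},
#' residual variance analogously, heritability
#' \eqn{h^2(x) = V_a/(V_a + V_e)}, and between-environment genetic
#' correlations from \eqn{\hat V}.
#'
#' @name rnm
NULL

#' Assemble a 2x2 intercept-slope covariance matrix
#'
#' @param v1 intercept variance.
#' @param v2 slope variance.
#' @param r correlation between intercept and slope (used when `cov`
#'   is not given).
#' @param cov covariance between intercept and slope.
#' @return symmetric 2x2 matrix.
#' @export
k_matrix <- function(v1, v2, r = NULL, cov = NULL) {
  if (is.null(cov)) {
    if (is.null(r)) stop("give either r or cov", call. = FALSE)
    cov <- r * sqrt(v1 * v2)
  }
  matrix(c(v1, cov, cov, v2), 2, 2)
}

.rnm_fixed_design <- function(pheno) {
  df <- data.frame(cg = factor(pheno$cg_id))
  terms <- "cg"
  if (length(unique(pheno$sex)) > 1) {
    df$sex <- factor(pheno$sex); terms <- c("sex", terms)
  }
  if (length(unique(pheno$birth_type)) > 1) {
    df$birth <- factor(pheno$birth_type); terms <- c("birth", terms)
  }
  if (length(unique(pheno$rear_type)) > 1) {
    df$rear <- factor(pheno$rear_type); terms <- c("rear", terms)
  }
  age <- pheno$postwean_age - mean(pheno$postwean_age)
  if (stats::sd(age) > 0) {
    df$age <- age; terms <- c("age", terms)
  }
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(fml, df)
}

#' Fit a linear reaction-norm model by AI-REML
#'
#' @param pheno filtered phenotype data.frame (one body-weight record per
#'   animal; see [filter_for_rnm()]).
#' @param gradient an [standardize_gradient()] result covering all
#'   animals.
#' @param grm a [compute_grm()] result covering all animals.
#' @param residual `"hom"` for homogeneous residual variance, `"het"`
#'   for the gradient-dependent residual.
#' @param keep_spec retain the model spec (needed later by
#'   [gebv_covariance()]); costs memory proportional to the number of
#'   variance parameters times n^2.
#' @param init,... passed to [reml_fit()].
#' @return object of class `rnm_fit`: `model`, `K` (2x2 genetic
#'   covariance), `r_a1a2`, `E` (2x2, `NULL` for HOM), `sigma2_e` (HOM),
#'   `sigma2_g`, GEBV vectors `a1`, `a2`, group effects `g`, `beta`,
#'   `theta`, `se`, `theta_cov`, `logL`, `converged`, `n_iter`,
#'   `x` (named per-animal gradient), `x_range`.
#' @export
fit_rnm <- function(pheno, gradient, grm, residual = c("hom", "het"),
                    keep_spec = FALSE, init = NULL, ...) {
  residual <- match.arg(residual)
  ids <- pheno$animal_id
  x <- gradient$x[ids]
  if (anyNA(x))
    stop("gradient missing for ", sum(is.na(x)), " animal(s)",
         call. = FALSE)
  x <- unname(x)
  if (stats::sd(x) == 0)
    stop("environmental gradient is constant; the slope variance is ",
         "unidentified", call. = FALSE)
  G <- .sub_rel(grm, ids)
  X <- .rnm_fixed_design(pheno)
  Q <- .q_matrix(pheno)
  random <- list(rand_regression(x, M = G))
  if (!is.null(Q))
    random <- c(random, list(rand_scalar(Z = Q, name = "sigma2_g")))
  res <- if (residual == "hom") resid_hom() else resid_het2(x)
  spec <- model_spec(pheno$pwwt, X, random = random, residual = res)
  fit <- reml_fit(spec, init = init, ...)
  th <- fit$theta
  K <- k_matrix(th["sigma2_a1"], th["sigma2_a2"], cov = th["sigma_a1a2"])
  E <- NULL; sigma2_e <- NULL
  if (residual == "het") {
    E <- matrix(c(th["sigma2_e1"], th["sigma_e1e2"],
                  th["sigma_e1e2"], th["sigma2_e2"]), 2, 2)
    ve_obs <- .resid_var_fun(E, range(x))
    if (any(ve_obs <= 0))
      warning("implied residual variance non-positive within the ",
              "observed gradient range", call. = FALSE)
  } else {
    sigma2_e <- unname(th["sigma2_e"])
  }
  a <- fit$u[[1]]
  g <- if (length(fit$u) > 1) {
    gg <- drop(fit$u[[2]])
    stats::setNames(gg, colnames(Q))
  } else NULL
  out <- structure(list(model = paste0("RNM-", toupper(residual)),
                 K = K, r_a1a2 = unname(K[1, 2] / sqrt(K[1, 1] * K[2, 2])),
                 E = E, sigma2_e = sigma2_e,
                 sigma2_g = if ("sigma2_g" %in% names(th))
                   unname(th["sigma2_g"]) else NULL,
                 a1 = stats::setNames(a[, "intercept"], ids),
                 a2 = stats::setNames(a[, "slope"], ids),
                 g = g, beta = fit$beta, theta = th, se = fit$se,
                 theta_cov = fit$theta_cov, logL = fit$logL,
                 converged = fit$converged, n_iter = fit$n_iter,
                 x = stats::setNames(x, ids), x_range = range(x)),
            class = "rnm_fit")
  if (keep_spec) attr(out, "spec") <- spec
  out
}

#' Reaction-norm parameter set without a data fit
#'
#' Wraps externally obtained variance components (e.g. a published
#' parameter table) in the same structure as [fit_rnm()] so that
#' [variance_profile()] and [compare_environments()] can be applied to
#' them directly.
#'
#' @param K 2x2 genetic intercept/slope covariance (see [k_matrix()]).
#' @param E 2x2 residual coefficient covariance, or `NULL`.
#' @param sigma2_e homogeneous residual variance (used when `E` is
#'   `NULL`).
#' @param sigma2_g genetic-group variance.
#' @param theta_cov optional parameter covariance for delta-method SEs.
#' @param x_range gradient range the parameters apply to.
#' @param logL optional log-likelihood.
#' @return object of class `rnm_fit` (without GEBV).
#' @export
rnm_parameters <- function(K, E = NULL, sigma2_e = NULL, sigma2_g = 0,
                           theta_cov = NULL, x_range = c(-2.15, 2.06),
                           logL = NA_real_) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == 2, isTRUE(all.equal(K, t(K))))
  if (is.null(E) && is.null(sigma2_e))
    stop("give E or sigma2_e", call. = FALSE)
  model <- if (is.null(E)) "RNM-HOM" else "RNM-HET"
  th <- c(sigma2_a1 = K[1, 1], sigma_a1a2 = K[1, 2], sigma2_a2 = K[2, 2],
          sigma2_g = sigma2_g)
  th <- if (is.null(E)) c(th, sigma2_e = sigma2_e) else
    c(th, sigma2_e1 = E[1, 1], sigma_e1e2 = E[1, 2], sigma2_e2 = E[2, 2])
  structure(list(model = model, K = K,
                 r_a1a2 = unname(K[1, 2] / sqrt(K[1, 1] * K[2, 2])),
                 E = E, sigma2_e = sigma2_e, sigma2_g = sigma2_g,
                 a1 = NULL, a2 = NULL, g = NULL, beta = NULL,
                 theta = th, se = NULL, theta_cov = theta_cov,
                 logL = logL, converged = TRUE, n_iter = 0L,
                 x = NULL, x_range = as.numeric(x_range)),
            class = "rnm_fit")
}

#' @export
print.rnm_fit <- function(x, ...) {
  cat(x$model, " fit", if (!x$converged) " (NOT converged)", ":\n",
      sep = "")
  cat(sprintf("  sigma2_a1 = %.3f  sigma2_a2 = %.3f  r_a1a2 = %.3f\n",
              x$K[1, 1], x$K[2, 2], x$r_a1a2))
  if (!is.null(x$E))
    cat(sprintf("  sigma2_e1 = %.3f  sigma2_e2 = %.3f  sigma_e1e2 = %.3f\n",
                x$E[1, 1], x$E[2, 2], x$E[1, 2]))
  else if (!is.null(x$sigma2_e))
    cat(sprintf("  sigma2_e = %.3f\n", x$sigma2_e))
  if (!is.null(x$sigma2_g))
    cat(sprintf("  sigma2_g = %.3f\n", x$sigma2_g))
  cat("  logL =", format(x$logL, digits = 8), "\n")
  invisible(x)
}

.va_fun <- function(K, x) K[1, 1] + 2 * x * K[1, 2] + x^2 * K[2, 2]

.quad_se <- function(cov3, x) {
  ## delta-method SE of v(x) = theta1 + 2x theta2 + x^2 theta3
  if (is.null(cov3)) return(rep(NA_real_, length(x)))
  vapply(x, function(xi) {
    gr <- c(1, 2 * xi, xi^2)
    sqrt(max(drop(gr %*% cov3 %*% gr), 0))
  }, numeric(1))
}

#' Environment-specific variances, heritabilities and correlations
#'
#' Evaluates the genetic and residual variance functions, heritability
#' and the between-environment genetic correlation matrix on a grid of
#' gradient values (default 100 points spanning the fit's observed
#' range).  Standard errors come from the first-order delta method on the
#' fit's parameter covariance.  Negative variances at extreme grid points
#' are reported as-is, not clamped.
#'
#' @param fit an [fit_rnm()] or [rnm_parameters()] object.
#' @param grid gradient values; default `n_grid` points over
#'   `fit$x_range`.
#' @param n_grid grid size when `grid` is not given.
#' @return object of class `variance_profile`: `profile` data.frame
#'   (`x`, `Va`, `se_Va`, `Ve`, `se_Ve`, `h2`, `se_h2`), `corr` (genetic
#'   correlation matrix over the grid), `K`, `E`, `model`.
#' @export
variance_profile <- function(fit, grid = NULL, n_grid = 100L) {
  stopifnot(inherits(fit, "rnm_fit"))
  if (!fit$converged)
    warning("variance profile from a non-converged fit", call. = FALSE)
  if (is.null(grid))
    grid <- seq(fit$x_range[1], fit$x_range[2], length.out = n_grid)
  K <- fit$K
  Va <- .va_fun(K, grid)
  gnames <- c("sigma2_a1", "sigma_a1a2", "sigma2_a2")
  covK <- if (!is.null(fit$theta_cov) &&
              all(gnames %in% rownames(fit$theta_cov)))
    fit$theta_cov[gnames, gnames] else NULL
  se_Va <- .quad_se(covK, grid)
  if (!is.null(fit$E)) {
    Ve <- .va_fun(fit$E, grid)
    enames <- c("sigma2_e1", "sigma_e1e2", "sigma2_e2")
    covE <- if (!is.null(fit$theta_cov) &&
                all(enames %in% rownames(fit$theta_cov)))
      fit$theta_cov[enames, enames] else NULL
    se_Ve <- .quad_se(covE, grid)
  } else {
    Ve <- rep(fit$sigma2_e, length(grid))
    se_e <- if (!is.null(fit$theta_cov) &&
                "sigma2_e" %in% rownames(fit$theta_cov))
      sqrt(fit$theta_cov["sigma2_e", "sigma2_e"]) else NA_real_
    se_Ve <- rep(se_e, length(grid))
  }
  h2 <- Va / (Va + Ve)
  se_h2 <- .h2_se(fit, grid, Va, Ve)
  ## Lambda K Lambda' over the grid -> correlation matrix
  L <- cbind(1, grid)
  V <- L %*% K %*% t(L)
  s <- sqrt(pmax(diag(V), 0))
  corr <- V / outer(s, s)
  dimnames(corr) <- list(signif(grid, 4), signif(grid, 4))
  structure(list(profile = data.frame(x = grid, Va = Va, se_Va = se_Va,
                                      Ve = Ve, se_Ve = se_Ve, h2 = h2,
                                      se_h2 = se_h2),
                 corr = corr, K = K, E = fit$E, model = fit$model,
                 fit = fit),
            class = "variance_profile")
}

.theta_jacobian_se <- function(fit, fun, x) {
  ## numeric delta method over the full parameter vector
  if (is.null(fit$theta_cov)) return(rep(NA_real_, length(x)))
  th <- fit$theta
  nm <- rownames(fit$theta_cov)
  if (is.null(nm) || !all(nm %in% names(th))) return(rep(NA_real_, length(x)))
  vapply(x, function(xi) {
    gr <- vapply(nm, function(p) {
      h <- max(1e-6, 1e-6 * abs(th[p]))
      tp <- th; tp[p] <- tp[p] + h
      tm <- th; tm[p] <- tm[p] - h
      (fun(tp, xi) - fun(tm, xi)) / (2 * h)
    }, numeric(1))
    sqrt(max(drop(gr %*% fit$theta_cov %*% gr), 0))
  }, numeric(1))
}

.h2_se <- function(fit, x, Va, Ve) {
  het <- !is.null(fit$E)
  fun <- function(th, xi) {
    va <- th["sigma2_a1"] + 2 * xi * th["sigma_a1a2"] + xi^2 * th["sigma2_a2"]
    ve <- if (het)
      th["sigma2_e1"] + 2 * xi * th["sigma_e1e2"] + xi^2 * th["sigma2_e2"]
    else th["sigma2_e"]
    unname(va / (va + ve))
  }
  .theta_jacobian_se(fit, fun, x)
}

#' Genetic correlation between two environments
#'
#' \eqn{\mathrm{cov}(x_1,x_2) = \sigma^2_{a1} + (x_1+x_2)\sigma_{a1a2} +
#' x_1 x_2 \sigma^2_{a2}} normalised by the two genetic SDs.
#'
#' @param K 2x2 genetic covariance.
#' @param x1,x2 gradient values.
#' @export
genetic_correlation <- function(K, x1, x2) {
  cv <- K[1, 1] + (x1 + x2) * K[1, 2] + x1 * x2 * K[2, 2]
  cv / sqrt(.va_fun(K, x1) * .va_fun(K, x2))
}

#' @export
plot.variance_profile <- function(x, ...) {
  pr <- x$profile
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(pr$x, cbind(pr$Va, pr$Ve), type = "l", lty = 1,
                    col = c("darkgreen", "grey40"),
                    xlab = "environmental gradient (SD)",
                    ylab = "variance", ...)
  graphics::legend("topleft", c("Va", "Ve"), lty = 1,
                   col = c("darkgreen", "grey40"), bty = "n")
  graphics::plot(pr$x, pr$h2, type = "l",
                 xlab = "environmental gradient (SD)",
                 ylab = expression(h^2), ...)
  invisible(x)
}

#' Compare variances, heritabilities and correlations between
#' environments
#'
#' Summarises the profile at a small set of gradient points (default
#' low/average/high at -1.5, 0 and +1.5 SD; comparisons are restricted to
#' this central range because profile values further out rest on little
#' data) with percent changes between every pair and the pairwise genetic
#' correlations.
#'
#' @param profile a [variance_profile()] (or `rnm_fit`, profiled first).
#' @param points gradient values to compare.
#' @return object of class `env_comparison`: `values`, `percent`,
#'   `corr`.
#' @export
compare_environments <- function(profile, points = c(-1.5, 0, 1.5)) {
  if (inherits(profile, "rnm_fit"))
    profile <- variance_profile(profile,
                                grid = seq(min(c(points, profile$x_range)),
                                           max(c(points, profile$x_range)),
                                           length.out = 100))
  stopifnot(inherits(profile, "variance_profile"))
  K <- profile$K
  Va <- .va_fun(K, points)
  Ve <- if (!is.null(profile$E)) .va_fun(profile$E, points)
        else rep(profile$fit$sigma2_e, length(points))
  h2 <- Va / (Va + Ve)
  lab <- if (length(points) == 3) c("low", "average", "high") else
    paste0("x=", signif(points, 3))
  values <- data.frame(environment = lab, x = points, Va = Va, Ve = Ve,
                       h2 = h2)
  pairs <- utils::combn(seq_along(points), 2)
  pct <- function(v) 100 * (v[pairs[2, ]] / v[pairs[1, ]] - 1)
  percent <- data.frame(from = lab[pairs[1, ]], to = lab[pairs[2, ]],
                        pct_Va = pct(Va), pct_Ve = pct(Ve),
                        pct_h2 = pct(h2))
  corr <- outer(points, points, function(a, b) genetic_correlation(K, a, b))
  dimnames(corr) <- list(lab, lab)
  structure(list(values = values, percent = percent, corr = corr,
                 model = profile$model),
            class = "env_comparison")
}

#' @export
print.env_comparison <- function(x, ...) {
  cat("Environment comparison (", x$model, ")\n", sep = "")
  print(x$values, row.names = FALSE, digits = 4)
  cat("Percent changes:\n")
  print(x$percent, row.names = FALSE, digits = 4)
  cat("Genetic correlations:\n")
  print(round(x$corr, 3))
  invisible(x)
}
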