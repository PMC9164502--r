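#' Back-solved SNP associations for intercept and slope
#'
#' GEBV from the reaction-norm fit are converted to per-SNP allele
#' effects by back-solving through the GRM,
#' \deqn{\hat u = W' G^{-1} a / d,}
#' for the intercept, the direct slope and the scale-corrected slope.
#' The scale correction removes the part of the slope GEBV predictable
#' from the intercept GEBV by genetic regression,
#' \deqn{a_2^* = a_2 - (\sigma_{a1a2}/\sigma^2_{a1}) a_1,}
#' isolating rank-type (re-ranking) genotype-by-environment interaction
#' from scale-type variance changes.
#'
#' @name gwas
NULL

#' Bonferroni significance threshold on the -log10 scale
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (SNPs).
#' @return `-log10(alpha / m)`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  -log10(alpha / m)
}

#' Scale-correct slope GEBV by genetic regression on the intercept
#'
#' In `"component"` mode the regression coefficient is
#' \eqn{\sigma_{a1a2}/\sigma^2_{a1}} from the fitted (or supplied)
#' genetic covariance; in `"empirical"` mode it is the sample
#' `cov(a1, a2)/var(a1)`, which makes the corrected slope exactly
#' uncorrelated with the intercept GEBV in-sample.
#'
#' @param a1,a2 aligned GEBV vectors for intercept and slope (or an
#'   `rnm_fit` as `a1`, in which case its GEBV and `K` are used).
#' @param K 2x2 genetic covariance (component mode).
#' @param mode `"component"` or `"empirical"`.
#' @return object of class `corrected_slope`: `a2_star`, `coefficient`,
#'   `mode`.
#' @export
scale_correct <- function(a1, a2 = NULL, K = NULL,
                          mode = c("component", "empirical")) {
  mode <- match.arg(mode)
  if (inherits(a1, "rnm_fit")) {
    fit <- a1
    if (is.null(K)) K <- fit$K
    a1 <- fit$a1
    a2 <- fit$a2
  }
  stopifnot(length(a1) == length(a2))
  coef <- switch(mode,
    component = {
      if (is.null(K)) stop("component mode needs K", call. = FALSE)
      if (K[1, 1] <= 0)
        stop("intercept variance must be positive", call. = FALSE)
      K[1, 2] / K[1, 1]
    },
    empirical = {
      v <- stats::var(a1)
      if (v <= 0) stop("intercept GEBV variance is zero", call. = FALSE)
      stats::cov(a1, a2) / v
    })
  structure(list(a2_star = a2 - coef * a1, coefficient = unname(coef),
                 mode = mode),
            class = "corrected_slope")
}

#' @export
print.corrected_slope <- function(x, ...) {
  cat(sprintf("scale-corrected slope GEBV: a2* = a2 - %.4g a1 (%s mode)\n",
              x$coefficient, x$mode))
  invisible(x)
}

#' Back-solve GEBV to SNP effects
#'
#' \eqn{\hat u_j = w_j' G^{-1} a / d} per SNP, with `W`, `d` from
#' [center_genotypes()] and the GRM inverse from [grm_inverse()] (ridged
#' beforehand if the GRM was singular).  Animal ordering between the
#' genotypes and the GEBV vector is checked by id.
#'
#' @param cg a [center_genotypes()] result.
#' @param grm the [compute_grm()] result built from `cg`.
#' @param a GEBV vector, named by animal id (or a `corrected_slope`).
#' @param Ginv optional precomputed GRM inverse (to amortise across
#'   targets).
#' @return numeric vector of per-SNP effects (length = SNPs), named by
#'   SNP id.
#' @export
backsolve_snp_effects <- function(cg, grm, a, Ginv = NULL) {
  stopifnot(inherits(cg, "centered_genotypes"))
  if (inherits(a, "corrected_slope")) a <- a$a2_star
  if (!is.null(names(a))) {
    if (!identical(names(a), cg$animal_ids)) {
      if (!all(cg$animal_ids %in% names(a)))
        stop("GEBV vector does not cover the genotyped animals",
             call. = FALSE)
      a <- a[cg$animal_ids]
    }
  } else if (length(a) != length(cg$animal_ids)) {
    stop("GEBV length does not match animals (and no names to align by)",
         call. = FALSE)
  }
  if (is.null(Ginv)) Ginv <- grm_inverse(grm)
  u <- drop(crossprod(cg$W, Ginv %*% a)) / cg$d
  stats::setNames(u, cg$map$snp_id)
}

#' Approximate per-SNP tests for back-solved effects
#'
#' Back-solved effects are linear in the GEBV, so two approximate tests
#' are offered and labelled in the output.  `"empirical_sd"`
#' standardises each effect by the SD of all effects
#' (\eqn{z_j = \hat u_j / \mathrm{SD}(\hat u)}); `"backsolve_var"` uses
#' per-SNP sampling variances \eqn{\mathrm{diag}(W'G^{-1}
#' \mathrm{Var}(\hat a) G^{-1} W)/d^2} from a supplied GEBV covariance.
#' Two-sided p-values come from the t reference with `df` degrees of
#' freedom (default `Inf`, the normal limit).
#'
#' @param effects named per-SNP effect vector from
#'   [backsolve_snp_effects()].
#' @param cg,grm the genotype objects (needed for map/frequencies, and
#'   for `backsolve_var`).
#' @param method `"empirical_sd"` or `"backsolve_var"`.
#' @param gebv_cov animal x animal covariance of the GEBV
#'   (`backsolve_var` only).
#' @param target label: `"intercept"`, `"slope_direct"`,
#'   `"slope_corrected"`.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param df degrees of freedom of the t reference.
#' @return data.frame of class `snp_association` with columns `chrom`,
#'   `snp_id`, `bp`, `allele1`, `freq`, `effect`, `se`, `z`, `p`,
#'   `neg_log10_p`, `significant`; attributes `target`, `method`,
#'   `threshold` (-log10 scale), `alpha`.
#' @export
snp_pvalues <- function(effects, cg, grm = NULL,
                        method = c("empirical_sd", "backsolve_var"),
                        gebv_cov = NULL,
                        target = "intercept", alpha = 0.05, df = Inf) {
  method <- match.arg(method)
  m <- length(effects)
  if (method == "empirical_sd") {
    s <- stats::sd(effects)
    if (!is.finite(s) || s == 0)
      stop("zero SD of SNP effects", call. = FALSE)
    se <- rep(s, m)
  } else {
    if (is.null(gebv_cov) || is.null(grm))
      stop("backsolve_var needs grm and gebv_cov", call. = FALSE)
    Gi <- grm_inverse(grm)
    WtGi <- crossprod(cg$W, Gi)
    v <- rowSums((WtGi %*% gebv_cov) * WtGi) / cg$d^2
    se <- sqrt(pmax(v, 0))
    if (any(se == 0))
      stop("zero back-solved SE for ", sum(se == 0), " SNP(s)",
           call. = FALSE)
  }
  z <- effects / se
  p <- 2 * stats::pt(-abs(z), df = df)
  p <- pmax(p, .Machine$double.xmin)   # keep p in (0, 1]
  thr <- bonferroni_threshold(alpha, m)
  out <- data.frame(chrom = cg$map$chrom, snp_id = cg$map$snp_id,
                    bp = cg$map$bp, allele1 = cg$map$allele1,
                    freq = cg$p, effect = unname(effects), se = se,
                    z = unname(z), p = unname(p),
                    neg_log10_p = -log10(unname(p)),
                    significant = unname(p) < alpha / m,
                    row.names = NULL)
  attr(out, "target") <- target
  attr(out, "method") <- method
  attr(out, "threshold") <- thr
  attr(out, "alpha") <- alpha
  class(out) <- c("snp_association", "data.frame")
  out
}

#' Covariance of GEBV from a reaction-norm fit
#'
#' \eqn{\mathrm{Var}(\hat a) = C P C'} where \eqn{C = \mathrm{Cov}(a, y)}
#' and \eqn{P} is the REML projection matrix at the fitted parameters;
#' used by the `backsolve_var` p-value mode.
#'
#' @param fit an [fit_rnm()] result.
#' @param grm the GRM used in the fit.
#' @param target `"intercept"` or `"slope"`.
#' @return animal x animal covariance matrix of the GEBV.
#' @export
gebv_covariance <- function(fit, grm, target = c("intercept", "slope")) {
  target <- match.arg(target)
  ids <- names(fit$a1)
  G <- .sub_rel(grm, ids)
  x <- fit$x
  th <- fit$theta
  C <- if (target == "intercept")
    th["sigma2_a1"] * G + th["sigma_a1a2"] * (G * rep(x, each = nrow(G)))
  else
    th["sigma_a1a2"] * G + th["sigma2_a2"] * (G * rep(x, each = nrow(G)))
  ## rebuild P at the fitted parameters
  spec <- attr(fit, "spec")
  if (is.null(spec))
    stop("fit does not carry its model spec; refit with keep_spec = TRUE",
         call. = FALSE)
  P <- .lmm_eval(spec, fit$theta)$P
  C %*% P %*% t(C)
}

#' Compare association runs for intercept, direct and corrected slope
#'
#' @param runs named list of `snp_association` tables on the same panel
#'   (e.g. `intercept`, `slope_direct`, `slope_corrected`).
#' @return object of class `association_summary`: `effect_cor` (pairwise
#'   Pearson correlations of effect vectors), `n_significant`,
#'   `significant` (per-run SNP id lists), `status_changes` (SNPs whose
#'   significance differs between direct and corrected slope, when both
#'   are present).
#' @export
association_summary <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 2)
  if (is.null(names(runs)))
    names(runs) <- vapply(runs, attr, "", "target")
  ids <- lapply(runs, function(r) r$snp_id)
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("runs are not on the same SNP panel", call. = FALSE)
  eff <- vapply(runs, function(r) r$effect, numeric(nrow(runs[[1]])))
  effect_cor <- stats::cor(eff)
  sig <- lapply(runs, function(r) r$snp_id[r$significant])
  changes <- NULL
  if (all(c("slope_direct", "slope_corrected") %in% names(runs))) {
    d <- runs$slope_direct$significant
    c_ <- runs$slope_corrected$significant
    changes <- data.frame(snp_id = runs[[1]]$snp_id[d != c_],
                          direct = d[d != c_], corrected = c_[d != c_])
  }
  structure(list(effect_cor = effect_cor,
                 n_significant = vapply(sig, length, integer(1)),
                 significant = sig, status_changes = changes),
            class = "association_summary")
}

#' @export
print.association_summary <- function(x, ...) {
  cat("SNP-effect correlations between runs:\n")
  print(round(x$effect_cor, 3))
  cat("Significant SNPs:",
      paste(sprintf("%s %d", names(x$n_significant), x$n_significant),
            collapse = ", "), "\n")
  if (!is.null(x$status_changes) && nrow(x$status_changes))
    cat(nrow(x$status_changes),
        "SNP(s) change significance between direct and corrected slope\n")
  invisible(x)
}

#' Write an association table (PLINK-style) and a Manhattan-ready file
#'
#' @param assoc a [snp_pvalues()] table.
#' @param file output path for the `CHR SNP BP A1 FREQ BETA SE P` table.
#' @param manhattan_file optional path for `chrom bp neg_log10_p`.
#' @param header_lines provenance comment lines.
#' @export
write_association <- function(assoc, file, manhattan_file = NULL,
                              header_lines = character(0)) {
  tab <- data.frame(CHR = assoc$chrom, SNP = assoc$snp_id, BP = assoc$bp,
                    A1 = assoc$allele1, FREQ = assoc$freq,
                    BETA = assoc$effect, SE = assoc$se, P = assoc$p)
  .write_tsv(tab, file, c(header_lines,
                          paste("target:", attr(assoc, "target")),
                          paste("method:", attr(assoc, "method")),
                          sprintf("bonferroni -log10 threshold: %.4f",
                                  attr(assoc, "threshold"))))
  if (!is.null(manhattan_file))
    .write_tsv(data.frame(chrom = assoc$chrom, bp = assoc$bp,
                          neg_log10_p = assoc$neg_log10_p),
               manhattan_file, header_lines)
  invisible(file)
}
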