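#' Three-section multi-trait validation of the reaction norm
#'
#' As an internal benchmark, animals are split into low, average and high
#' growth environments by thresholding the gradient (animals falling in
#' the gaps between sections are excluded), and body weight in the three
#' sections is treated as three distinct, genetically correlated traits.
#' The unstructured 3x3 genetic covariance and per-trait residual
#' variances provide estimates of the between-environment genetic
#' correlations that do not assume linearity of the reaction norm.
#'
#' @name mtm
NULL

#' Assign animals to gradient sections
#'
#' Default thresholds: low below -1.13 SD, average within +/-0.59 SD,
#' high above +1.13 SD; animals between 0.59 and 1.13 in absolute value
#' are excluded, so the three sections do not exhaust the data.
#'
#' @param gradient an [standardize_gradient()] result (or a named numeric
#'   vector of gradient values).
#' @param thresholds named vector `low_max`, `avg_abs_max`, `high_min`.
#' @return object of class `section_assignment`: factor `section`
#'   (levels low/average/high/excluded, named by animal), `counts`,
#'   `thresholds`, `section_means` (mean gradient per section).
#' @export
assign_sections <- function(gradient,
                            thresholds = c(low_max = -1.13,
                                           avg_abs_max = 0.59,
                                           high_min = 1.13)) {
  x <- if (inherits(gradient, "env_gradient")) gradient$x else gradient
  sec <- rep("excluded", length(x))
  sec[x < thresholds["low_max"]] <- "low"
  sec[abs(x) < thresholds["avg_abs_max"]] <- "average"
  sec[x > thresholds["high_min"]] <- "high"
  sec <- factor(sec, levels = c("low", "average", "high", "excluded"))
  names(sec) <- names(x)
  counts <- table(sec)
  if (any(counts[c("low", "average", "high")] == 0))
    stop("empty section(s): ",
         paste(names(which(counts[1:3] == 0)), collapse = ", "),
         "; adjust the thresholds to the gradient range", call. = FALSE)
  means <- tapply(x, sec, mean)
  structure(list(section = sec, counts = counts, thresholds = thresholds,
                 section_means = means),
            class = "section_assignment")
}

#' @export
print.section_assignment <- function(x, ...) {
  cat("Gradient sections:\n")
  for (s in names(x$counts))
    cat(sprintf("  %-8s n = %5d  mean x = %s\n", s, x$counts[s],
                if (is.na(x$section_means[s])) "-" else
                  sprintf("%+.2f", x$section_means[s])))
  invisible(x)
}

#' Fit the three-section multi-trait model
#'
#' Body weight in the low/average/high sections is modelled as three
#' traits with an unstructured 3x3 genetic covariance over the GRM, a
#' random genetic-group effect and a separate residual variance per
#' section.  Each animal contributes one record to one trait, so
#' between-trait residual covariances are inestimable and fixed at zero.
#' Because the gradient is constant within a CG, every CG belongs to one
#' section and the CG fixed effect provides the per-trait means.
#'
#' @param pheno phenotype data.frame.
#' @param assignment an [assign_sections()] result covering the animals.
#' @param grm a [compute_grm()] result.
#' @param ... passed to [reml_fit()].
#' @return object of class `mtm_fit`: `K3` (3x3 genetic covariance),
#'   `corr` (genetic correlations), `Ve` (per-trait residual variances),
#'   `h2` (per-trait heritabilities), `sigma2_g`, `counts`, `logL`,
#'   `theta`, `se`, `theta_cov`, `converged`.  Non-convergence is
#'   reported in the object, not an error.
#' @export
fit_mtm <- function(pheno, assignment, grm, ...) {
  stopifnot(inherits(assignment, "section_assignment"))
  sec <- assignment$section[pheno$animal_id]
  keep <- !is.na(sec) & sec != "excluded"
  ph <- pheno[keep, , drop = FALSE]
  f <- droplevels(sec[keep])
  ids <- ph$animal_id
  G <- .sub_rel(grm, ids)
  X <- .rnm_fixed_design(ph)
  Q <- .q_matrix(ph)
  random <- list(rand_unstructured(f, M = G, prefix = "k"))
  if (!is.null(Q))
    random <- c(random, list(rand_scalar(Z = Q, name = "sigma2_g")))
  spec <- model_spec(ph$pwwt, X, random = random,
                     residual = resid_groups(f))
  fit <- reml_fit(spec, ...)
  th <- fit$theta
  lev <- levels(f)
  K3 <- matrix(0, 3, 3, dimnames = list(lev, lev))
  for (a in 1:3) for (b in a:3) {
    K3[a, b] <- K3[b, a] <- th[paste0("k[", lev[a], ",", lev[b], "]")]
  }
  s <- sqrt(pmax(diag(K3), 0))
  corr <- K3 / outer(s, s)
  Ve <- stats::setNames(th[paste0("sigma2_e[", lev, "]")], lev)
  h2 <- diag(K3) / (diag(K3) + Ve)
  structure(list(K3 = K3, corr = corr, Ve = Ve, h2 = h2,
                 sigma2_g = if ("sigma2_g" %in% names(th))
                   unname(th["sigma2_g"]) else NULL,
                 counts = table(f), logL = fit$logL, theta = th,
                 se = fit$se, theta_cov = fit$theta_cov,
                 converged = fit$converged, n_iter = fit$n_iter),
            class = "mtm_fit")
}

#' @export
print.mtm_fit <- function(x, ...) {
  cat("Three-section multi-trait fit",
      if (!x$converged) "(NOT converged; partial report)", "\n")
  cat("Genetic correlations:\n")
  print(round(x$corr, 3))
  cat("Per-trait h2:", paste(sprintf("%s %.2f", names(x$h2), x$h2),
                             collapse = ", "), "\n")
  invisible(x)
}
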