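#' SNP panels, quality control and the genomic relationship matrix
#'
#' A `genotype_panel` holds biallelic SNP dosages (counted-allele counts
#' 0/1/2, `NA` for missing) for a set of animals together with a marker
#' map.  QC filters follow standard chip-genotype practice: call rate,
#' Hardy-Weinberg disequilibrium and minor allele frequency, plus detection
#' of duplicated samples by genotype correlation.  Centred genotypes feed
#' VanRaden's first genomic relationship matrix \eqn{G = WW'/d} with
#' \eqn{d = 2\sum_j p_j(1-p_j)}.
#'
#' @name genotypes
NULL

#' Construct a genotype panel
#'
#' @param dosage animals x SNPs matrix with entries in {0, 1, 2, NA}
#'   counting copies of the coded (+1) allele.
#' @param map data.frame with columns `chrom`, `snp_id`, `bp` (1-based),
#'   `allele1`, `allele2`; one row per SNP column of `dosage`.
#' @param animal_ids character vector of animal identifiers.
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, map, animal_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(animal_ids)) animal_ids <- paste0("id", seq_len(nrow(dosage)))
  animal_ids <- as.character(animal_ids)
  stopifnot(length(animal_ids) == nrow(dosage))
  map <- as.data.frame(map)
  need <- c("chrom", "snp_id", "bp", "allele1", "allele2")
  if (!all(need %in% names(map)))
    stop("map must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(map) != ncol(dosage))
    stop("map has ", nrow(map), " rows but dosage has ", ncol(dosage),
         " SNPs", call. = FALSE)
  if (any(map$bp <= 0)) stop("bp positions must be positive", call. = FALSE)
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  rownames(dosage) <- animal_ids
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, map = map, animal_ids = animal_ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$animal_ids), "animals x",
      nrow(x$map), "SNPs;",
      sprintf("%.2f%% missing", 100 * mean(is.na(x$dosage))), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

.allele_freq <- function(dosage) {
  ## frequency of the +1-coded allele from non-missing calls
  colMeans(dosage, na.rm = TRUE) / 2
}

.hwe_chisq_p <- function(dosage) {
  ## 1-df goodness-of-fit chi-square of genotype counts against
  ## Hardy-Weinberg proportions, per SNP
  n0 <- colSums(dosage == 0, na.rm = TRUE)
  n1 <- colSums(dosage == 1, na.rm = TRUE)
  n2 <- colSums(dosage == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  chisq <- ifelse(p <= 0 | p >= 1, 0,
                  (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2)
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Filter SNPs on call rate, Hardy-Weinberg equilibrium and MAF
#'
#' A SNP is removed when its call rate is below `callrate_min`, its 1-df
#' Hardy-Weinberg chi-square p-value (from non-missing genotype counts)
#' falls below `hwe_p_min`, or its minor allele frequency is below
#' `maf_min`.  The defaults are the usual chip-data settings: call rate
#' 0.90, HWE p < 1e-15, MAF < 0.01.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minimum minor allele frequency.
#' @param callrate_min minimum per-SNP call rate.
#' @param hwe_p_min minimum HWE p-value.
#' @return list with the filtered `panel` and a `report` (class
#'   `qc_report`) counting removals per criterion; criteria are assessed on
#'   the incoming panel so the counts can overlap.
#' @export
qc_filter <- function(panel, maf_min = 0.01, callrate_min = 0.90,
                      hwe_p_min = 1e-15) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  if (ncol(d) == 0L) stop("empty panel", call. = FALSE)
  callrate <- colMeans(!is.na(d))
  hwe <- .hwe_chisq_p(d)
  p <- .allele_freq(d)
  maf <- pmin(p, 1 - p)
  fail_call <- callrate < callrate_min
  fail_hwe <- hwe$p < hwe_p_min
  fail_maf <- maf < maf_min | is.na(maf)
  drop <- fail_call | fail_hwe | fail_maf
  if (all(drop))
    stop("all SNPs removed by QC; relax the thresholds", call. = FALSE)
  keep <- !drop
  out <- genotype_panel(d[, keep, drop = FALSE], panel$map[keep, ],
                        panel$animal_ids)
  report <- structure(list(
    n_in = ncol(d), n_out = sum(keep),
    removed_callrate = sum(fail_call),
    removed_hwe = sum(fail_hwe),
    removed_maf = sum(fail_maf),
    removed_total = sum(drop),
    thresholds = c(maf_min = maf_min, callrate_min = callrate_min,
                   hwe_p_min = hwe_p_min),
    hwe_test = "1-df chi-square on genotype counts"),
    class = "qc_report")
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC:", x$n_in, "in ->", x$n_out, "retained\n")
  cat("  call rate <", x$thresholds["callrate_min"], ":",
      x$removed_callrate, "\n")
  cat("  HWE p <", format(x$thresholds["hwe_p_min"]), ":",
      x$removed_hwe, " (", x$hwe_test, ")\n")
  cat("  MAF <", x$thresholds["maf_min"], ":", x$removed_maf, "\n")
  cat("  total removed:", x$removed_total, "\n")
  invisible(x)
}

#' Find duplicated genotype samples
#'
#' Flags unordered pairs of animals whose genotype vectors (over shared
#' non-missing SNPs) have Pearson correlation above `r_threshold`
#' (default 0.98, the usual sample-mixup screen).  Removal policy is the
#' caller's; [drop_duplicates()] removes the later-indexed animal of each
#' pair (or both with `both = TRUE`).
#'
#' @inheritParams qc_filter
#' @param r_threshold correlation above which a pair is reported.
#' @return data.frame with columns `i`, `j` (indices, i < j), `id_i`,
#'   `id_j`, `r`; zero rows when there are no duplicates.
#' @export
find_duplicates <- function(panel, r_threshold = 0.98) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$dosage)
  if (n < 2L) stop("need at least two animals", call. = FALSE)
  R <- suppressWarnings(stats::cor(t(panel$dosage),
                                   use = "pairwise.complete.obs"))
  R[lower.tri(R, diag = TRUE)] <- NA
  hit <- which(!is.na(R) & R > r_threshold, arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2],
             id_i = panel$animal_ids[hit[, 1]],
             id_j = panel$animal_ids[hit[, 2]],
             r = R[hit], row.names = NULL)
}

#' @rdname find_duplicates
#' @param pairs output of [find_duplicates()].
#' @param both remove both members of each pair instead of the
#'   later-indexed one.
#' @export
drop_duplicates <- function(panel, pairs, both = FALSE) {
  drop <- if (both) union(pairs$i, pairs$j) else unique(pairs$j)
  if (!length(drop)) return(panel)
  keep <- setdiff(seq_along(panel$animal_ids), drop)
  genotype_panel(panel$dosage[keep, , drop = FALSE], panel$map,
                 panel$animal_ids[keep])
}

#' Centre genotypes for GBLUP
#'
#' Recodes dosages to M in {-1, 0, +1} (heterozygote 0) and centres by
#' allele frequency: \eqn{W = M - 2(p - 0.5)}, with `p` the +1-allele
#' frequency computed from non-missing calls and missing dosages imputed
#' to their mean `2p` beforehand.  Every column of `W` then has exactly
#' zero mean.  Also returns the scaling constant \eqn{d = 2\sum p(1-p)}.
#'
#' When `freq` is `NULL` (the default) allele frequencies come from the
#' panel itself, which centres every column of `W` exactly but leaves the
#' all-ones vector in the null space of `WW'` (the resulting GRM needs a
#' ridge before inversion).  Supplying external (e.g. base-population)
#' frequencies gives a generically full-rank GRM.
#'
#' @inheritParams qc_filter
#' @param freq optional per-SNP frequencies of the +1-coded allele used
#'   for imputation and centring instead of the observed ones.
#' @return object of class `centered_genotypes` with `W`, `p`, `d`,
#'   `animal_ids`, `map`.
#' @export
center_genotypes <- function(panel, freq = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  p <- if (is.null(freq)) .allele_freq(d) else {
    stopifnot(length(freq) == ncol(d))
    as.numeric(freq)
  }
  mono <- p <= 0 | p >= 1 | is.na(p)
  if (any(mono))
    stop(sum(mono), " monomorphic SNP(s) (allele frequency 0 or 1); ",
         "apply a MAF filter (qc_filter) first", call. = FALSE)
  if (anyNA(d)) {
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- 2 * p[idx[, 2]]
  }
  W <- sweep(d, 2, 2 * p)           # (M - 1) - (2p - 1) = dosage - 2p
  structure(list(W = W, p = p, d = 2 * sum(p * (1 - p)),
                 animal_ids = panel$animal_ids, map = panel$map),
            class = "centered_genotypes")
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' \eqn{G = WW'/d}.  When `G` is numerically singular (reciprocal
#' condition number below `cond_tol`, e.g. more animals than markers), a
#' small ridge `ridge * mean(diag(G))` is added to the diagonal so that
#' the inverse needed for back-solving exists; the ridge actually applied
#' is recorded.
#'
#' @param cg a [center_genotypes()] result.
#' @param ridge relative ridge to apply if needed (default `1e-6`);
#'   must be non-negative.
#' @param cond_tol reciprocal-condition-number threshold that triggers
#'   ridging.
#' @return object of class `grm` with `G`, `ridge_used`, `animal_ids`,
#'   `n_snps`.
#' @export
compute_grm <- function(cg, ridge = 1e-6, cond_tol = 1e-10) {
  stopifnot(inherits(cg, "centered_genotypes"))
  if (ridge < 0) stop("ridge must be non-negative", call. = FALSE)
  if (cg$d <= 0) stop("d must be positive", call. = FALSE)
  G <- tcrossprod(cg$W) / cg$d
  G <- (G + t(G)) / 2
  ridge_used <- 0
  ch <- tryCatch(chol(G), error = function(e) NULL)
  ## cheap condition estimate from the Cholesky diagonal
  needs_ridge <- is.null(ch) ||
    (min(diag(ch)) / max(diag(ch)))^2 < cond_tol
  if (needs_ridge && ridge > 0) {
    ridge_used <- ridge * mean(diag(G))
    G <- G + diag(ridge_used, nrow(G))
  }
  dimnames(G) <- list(cg$animal_ids, cg$animal_ids)
  structure(list(G = G, ridge_used = ridge_used,
                 animal_ids = cg$animal_ids, n_snps = length(cg$p)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("GRM:", nrow(x$G), "animals from", x$n_snps, "SNPs; mean diag =",
      signif(mean(diag(x$G)), 4),
      if (x$ridge_used > 0) sprintf("(ridge %.3g applied)", x$ridge_used)
      else "", "\n")
  invisible(x)
}

#' Inverse of a GRM by symmetric factorisation
#'
#' @param grm a [compute_grm()] result (ridged if it was singular).
#' @return symmetric inverse matrix.
#' @export
grm_inverse <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  ch <- tryCatch(chol(grm$G), error = function(e)
    stop("GRM not positive definite; recompute with a positive ridge",
         call. = FALSE))
  Gi <- chol2inv(ch)
  dimnames(Gi) <- dimnames(grm$G)
  Gi
}
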