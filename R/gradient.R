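#' Environmental gradient from contemporary-group growth-rate BLUEs
#'
#' Explicit environmental measurements are rarely available for every
#' flock-year, so the environment is described by how well each
#' contemporary group (CG) grew: the fixed-effect BLUE of CG from an
#' animal model for post-weaning growth rate.  Each animal is assigned its
#' CG's BLUE, and the assigned values are standardised over genotyped
#' animals to mean 0, variance 1, giving the environmental gradient used
#' as the reaction-norm covariate.
#'
#' @name gradient
NULL

.q_matrix <- function(pheno) {
  bg <- grep("^bg", names(pheno), value = TRUE)
  if (!length(bg)) return(NULL)
  Q <- as.matrix(pheno[, bg, drop = FALSE])
  storage.mode(Q) <- "double"
  Q
}

#' Record-level filters before estimating CG effects
#'
#' Removes, in order: records with a growth period shorter than
#' `min_days`; growth-rate records more than `sd_limit` SDs from the mean
#' (single pass, mean/SD computed after the previous rule); animals born
#' as quintuplets (birth type >= 5) or reared as quadruplets (rear type
#' >= 4).  CGs left with fewer than `min_cg` animals are then dropped.
#'
#' @param pheno phenotype data.frame (see [simulate_phenotypes()]).
#' @param min_days minimum growth period in days.
#' @param sd_limit growth-rate outlier limit in SDs.
#' @param min_cg minimum CG size.
#' @return list with filtered `pheno` and a `report` (class
#'   `filter_report`) counting removals per rule in application order.
#' @export
filter_for_gradient <- function(pheno, min_days = 40, sd_limit = 4,
                                min_cg = 15) {
  rep_ <- list(n_in = nrow(pheno))
  keep <- (pheno$postwean_age - pheno$wean_age) >= min_days
  rep_$short_period <- sum(!keep)
  ph <- pheno[keep, , drop = FALSE]

  mu <- mean(ph$pwgr); s <- stats::sd(ph$pwgr)
  keep <- abs(ph$pwgr - mu) <= sd_limit * s
  rep_$pwgr_outlier <- sum(!keep)
  ph <- ph[keep, , drop = FALSE]

  keep <- ph$birth_type < 5
  rep_$quintuplet <- sum(!keep)
  ph <- ph[keep, , drop = FALSE]

  keep <- ph$rear_type < 4
  rep_$quad_reared <- sum(!keep)
  ph <- ph[keep, , drop = FALSE]

  sz <- table(ph$cg_id)
  keep <- sz[ph$cg_id] >= min_cg
  rep_$small_cg <- sum(!keep)
  ph <- ph[keep, , drop = FALSE]

  if (nrow(ph) == 0L)
    stop("no records left after gradient filters", call. = FALSE)
  rep_$n_out <- nrow(ph)
  list(pheno = ph, report = structure(rep_, class = "filter_report"))
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Record filters:", x$n_in, "in ->", x$n_out, "retained\n")
  for (nm in setdiff(names(x), c("n_in", "n_out")))
    cat(" ", nm, ":", x[[nm]], "removed\n")
  invisible(x)
}

.sub_rel <- function(relationship, ids) {
  M <- if (inherits(relationship, "grm")) relationship$G else
    as.matrix(relationship)
  if (is.null(rownames(M)))
    stop("relationship matrix needs animal ids as dimnames", call. = FALSE)
  missing <- setdiff(ids, rownames(M))
  if (length(missing))
    stop("relationship matrix does not cover animals: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  M[ids, ids]
}

.cg_fixed_design <- function(pheno, fixed = c("full", "cg_only"),
                             age_quadratic = TRUE) {
  fixed <- match.arg(fixed)
  df <- data.frame(cg = factor(pheno$cg_id))
  terms <- "cg"
  if (fixed == "full") {
    if (length(unique(pheno$sex)) > 1) {
      df$sex <- factor(pheno$sex); terms <- c("sex", terms)
    }
    br <- interaction(pheno$birth_type, pheno$rear_type, drop = TRUE)
    if (nlevels(br) > 1) {
      df$birth_rear <- br; terms <- c("birth_rear", terms)
    }
    age <- pheno$postwean_age - mean(pheno$postwean_age)
    if (stats::sd(age) > 0) {
      df$age <- age; terms <- c("age", terms)
      if (age_quadratic) {
        df$age2 <- age^2; terms <- c(terms, "age2")
      }
    }
  }
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(fml, df)
}

#' BLUEs of contemporary-group effects for growth rate
#'
#' Fits the animal model for post-weaning growth rate: fixed sex,
#' birth-type x rear-type interaction, age at post-weaning (linear and
#' quadratic) and CG; random additive genetic effect over `relationship`
#' (genomic or pedigree-based) and random genetic-group effect through the
#' breed-proportion matrix.  Variance components are estimated by AI-REML
#' on the same data unless `theta` is supplied.  CG solutions are returned
#' under the reference-level constraint (first CG = 0); the gradient
#' standardisation later removes the arbitrary location.
#'
#' @param pheno filtered phenotype data.frame.
#' @param relationship a [compute_grm()] result or a (pedigree) numerator
#'   relationship matrix with animal-id dimnames.
#' @param fixed `"full"` for the complete fixed-effect set, `"cg_only"`
#'   for CG alone.
#' @param theta optional fixed variance parameters (genetic, group,
#'   residual) to solve at instead of REML estimation.
#' @param ... passed to [reml_fit()].
#' @return object of class `cg_blue_fit`: `blues` (named per CG), `fit`
#'   (or `NULL` when `theta` given), `beta`, `spec`.
#' @export
fit_cg_blue <- function(pheno, relationship, fixed = "full", theta = NULL,
                        ...) {
  ids <- pheno$animal_id
  G <- .sub_rel(relationship, ids)
  X <- .cg_fixed_design(pheno, fixed)
  Q <- .q_matrix(pheno)
  random <- list(rand_scalar(M = G, name = "sigma2_a"))
  if (!is.null(Q))
    random <- c(random, list(rand_scalar(Z = Q, name = "sigma2_group")))
  spec <- model_spec(pheno$pwgr, X, random = random, residual = resid_hom())
  if (is.null(theta)) {
    fit <- reml_fit(spec, ...)
    sol <- list(beta = fit$beta)
  } else {
    fit <- NULL
    sol <- solve_mme(spec, theta)
  }
  beta <- sol$beta
  cg_lev <- levels(factor(pheno$cg_id))
  blues <- stats::setNames(numeric(length(cg_lev)), cg_lev)
  for (l in cg_lev) {
    cn <- paste0("cg", l)
    if (cn %in% names(beta)) blues[l] <- beta[cn]
  }
  structure(list(blues = blues, fit = fit, beta = beta, spec = spec),
            class = "cg_blue_fit")
}

#' @export
print.cg_blue_fit <- function(x, ...) {
  cat("CG BLUEs for", length(x$blues), "contemporary groups; range",
      paste(signif(range(x$blues), 4), collapse = " to "), "g/day\n")
  invisible(x)
}

#' Standardise CG BLUEs into the environmental gradient
#'
#' Each animal receives the BLUE of its CG; the assigned values are
#' standardised to mean 0, variance 1 *over genotyped animals*
#' (animal-weighted, so large CGs carry more weight), and the constants
#' are recorded for reuse.
#'
#' @param blues a [fit_cg_blue()] result or a named per-CG vector
#'   (g/day).
#' @param pheno phenotype data.frame with `animal_id`, `cg_id`,
#'   `genotyped`.
#' @return object of class `env_gradient`: `cg_blue`, `mean_used`,
#'   `sd_used` (g/day per SD), `x` (named per-animal standardised values),
#'   `cg_id`.
#' @export
standardize_gradient <- function(blues, pheno) {
  if (inherits(blues, "cg_blue_fit")) blues <- blues$blues
  gt <- if ("genotyped" %in% names(pheno)) pheno$genotyped else
    rep(TRUE, nrow(pheno))
  ph <- pheno[gt, , drop = FALSE]
  if (!all(ph$cg_id %in% names(blues)))
    stop("no BLUE for CG(s): ",
         paste(utils::head(setdiff(ph$cg_id, names(blues)), 5),
               collapse = ", "), call. = FALSE)
  vals <- blues[ph$cg_id]
  mu <- mean(vals); s <- stats::sd(vals)
  if (!is.finite(s) || s == 0)
    stop("gradient SD is zero (a single CG?); cannot standardise",
         call. = FALSE)
  x <- (vals - mu) / s
  structure(list(cg_blue = blues, mean_used = mu, sd_used = s,
                 x = stats::setNames(unname(x), ph$animal_id),
                 cg_id = stats::setNames(ph$cg_id, ph$animal_id)),
            class = "env_gradient")
}

#' @export
print.env_gradient <- function(x, ...) {
  cat("Environmental gradient over", length(x$x), "animals in",
      length(unique(x$cg_id)), "CGs; range",
      paste(signif(range(x$x), 3), collapse = " to "), "SD",
      sprintf("(1 SD = %.2f g/day)\n", x$sd_used))
  invisible(x)
}

#' Environmental gradient from user-supplied values
#'
#' Wraps an existing per-animal environmental descriptor (already
#' standardised, or standardised here) as an `env_gradient`, for use when
#' the covariate comes from outside the CG-BLUE machinery.
#'
#' @param x named numeric vector of per-animal environmental values.
#' @param cg_id optional named CG labels.
#' @param standardize standardise `x` to mean 0, variance 1 first.
#' @param sd_used gradient scale in g/day per SD (for unit conversion
#'   only).
#' @return an `env_gradient` object.
#' @export
env_gradient <- function(x, cg_id = NULL, standardize = FALSE,
                         sd_used = NA_real_) {
  if (is.null(names(x))) stop("x must be named by animal id", call. = FALSE)
  mu <- 0
  if (standardize) {
    mu <- mean(x)
    s <- stats::sd(x)
    if (s == 0) stop("gradient SD is zero", call. = FALSE)
    x <- (x - mu) / s
    if (is.na(sd_used)) sd_used <- s
  }
  if (is.null(cg_id)) cg_id <- stats::setNames(names(x), names(x))
  structure(list(cg_blue = NULL, mean_used = mu, sd_used = sd_used,
                 x = x, cg_id = cg_id),
            class = "env_gradient")
}

#' Convert gradient values between SD units and g/day
#'
#' @param gradient an [standardize_gradient()] result.
#' @param x gradient values in SD units.
#' @return values in g/day (deviation from the gradient mean).
#' @export
gradient_to_units <- function(gradient, x) {
  stopifnot(inherits(gradient, "env_gradient"))
  x * gradient$sd_used
}

#' Animal filters before the reaction-norm fit
#'
#' Keeps genotyped animals whose body weight lies within `sd_limit` SDs
#' of the mean, and which either come from a CG of at least `min_cg`
#' animals or have at least one half-sib (shared sire or shared dam)
#' among the retained animals: the cross-environment family links are
#' what identify the reaction-norm slope.
#'
#' @inheritParams filter_for_gradient
#' @param gradient an [standardize_gradient()] result covering the
#'   animals.
#' @param sd_limit body-weight outlier limit in SDs.
#' @return list with filtered `pheno` and `report`.
#' @export
filter_for_rnm <- function(pheno, gradient, sd_limit = 4, min_cg = 15) {
  rep_ <- list(n_in = nrow(pheno))
  gt <- if ("genotyped" %in% names(pheno)) pheno$genotyped else
    rep(TRUE, nrow(pheno))
  rep_$not_genotyped <- sum(!gt)
  ph <- pheno[gt, , drop = FALSE]

  mu <- mean(ph$pwwt); s <- stats::sd(ph$pwwt)
  keep <- abs(ph$pwwt - mu) <= sd_limit * s
  rep_$pwwt_outlier <- sum(!keep)
  ph <- ph[keep, , drop = FALSE]

  sz <- table(ph$cg_id)
  big_cg <- sz[ph$cg_id] >= min_cg
  sire_n <- table(ph$sire_id)
  dam_n <- table(ph$dam_id)
  halfsib <- (!is.na(ph$sire_id) & sire_n[ph$sire_id] >= 2) |
    (!is.na(ph$dam_id) & dam_n[ph$dam_id] >= 2)
  keep <- as.vector(big_cg | halfsib)
  rep_$no_cg_or_halfsib <- sum(!keep)
  ph <- ph[keep, , drop = FALSE]
  if (nrow(ph) == 0L)
    stop("no records left after reaction-norm filters", call. = FALSE)
  rep_$n_out <- nrow(ph)
  list(pheno = ph, report = structure(rep_, class = "filter_report"))
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive relationship matrix for the union of animals and
#' their listed parents, parents processed first; unknown parents
#' (`NA` or ids absent from `animal_id` and never listed as parents) are
#' treated as unrelated founders.  Intended for desk-scale pedigrees.
#'
#' @param animal_id,sire_id,dam_id parallel id vectors (`NA` for unknown
#'   parents).
#' @return symmetric relationship matrix with animal ids as dimnames,
#'   covering parents and animals.
#' @export
nrm_from_pedigree <- function(animal_id, sire_id, dam_id) {
  animal_id <- as.character(animal_id)
  sire_id <- as.character(sire_id)
  dam_id <- as.character(dam_id)
  founders <- setdiff(stats::na.omit(c(sire_id, dam_id)), animal_id)
  ids <- c(founders, animal_id)
  if (anyDuplicated(ids)) stop("duplicated animal ids", call. = FALSE)
  n <- length(ids)
  sire <- match(c(rep(NA_character_, length(founders)), sire_id), ids)
  dam <- match(c(rep(NA_character_, length(founders)), dam_id), ids)
  pos <- seq_len(n)
  if (any(sire >= pos, na.rm = TRUE) || any(dam >= pos, na.rm = TRUE))
    stop("pedigree not sorted: parents must precede offspring",
         call. = FALSE)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) +
                   (if (!is.na(d)) A[j, d] else 0))
      A[j, i] <- aj
      A[i, j] <- aj
    }
  }
  A
}
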