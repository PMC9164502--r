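#' Mixed-model machinery for reaction-norm GBLUP
#'
#' The models fitted by this package (contemporary-group BLUE model,
#' linear reaction norms, three-section multi-trait model) all share one
#' structure: a Gaussian linear mixed model whose marginal covariance is
#' *linear* in its variance parameters,
#' \deqn{V(\theta) = \sum_k \theta_k V_k,}
#' where each \eqn{V_k} is a fixed symmetric matrix built from design
#' matrices, a relationship matrix (genomic or identity) and, for random
#' regressions, the environmental covariate.  [model_spec()] assembles the
#' \eqn{V_k}; [reml_fit()] maximises the restricted likelihood by
#' average-information (AI) REML; [solve_mme()] returns BLUE/BLUP solutions
#' at a given parameter value.
#'
#' @name lmm
NULL

## ---- random-term constructors -------------------------------------------

#' Random term with a single variance component
#'
#' Contributes \eqn{\sigma^2 Z M Z'} to the marginal covariance, where `M`
#' is a relationship matrix (genomic `G`, pedigree `A`, or identity) over
#' the term's levels.
#'
#' @param Z incidence matrix (records x levels); `NULL` means identity
#'   (one record per level, in order).
#' @param M relationship matrix over levels; `NULL` means identity.
#' @param name parameter name used in fit output.
#' @return term descriptor for [model_spec()].
#' @export
rand_scalar <- function(Z = NULL, M = NULL, name = "sigma2_u") {
  structure(list(type = "scalar", Z = Z, M = M, name = name),
            class = "lmm_term")
}

#' Correlated random intercept and slope (random regression)
#'
#' Contributes the 2x2 covariance \eqn{K} of intercept and slope effects,
#' expanded over a relationship matrix: with \eqn{Z_1 = Z} and
#' \eqn{Z_2 = \mathrm{diag}(x) Z},
#' \deqn{K_{11} Z_1 M Z_1' + K_{12}(Z_1 M Z_2' + Z_2 M Z_1') + K_{22} Z_2 M Z_2'.}
#' Three parameters: variance of the intercept, intercept-slope covariance,
#' variance of the slope.
#'
#' @param x per-record environmental covariate (standardised gradient).
#' @inheritParams rand_scalar
#' @param names length-3 parameter names (intercept var, covariance,
#'   slope var).
#' @export
rand_regression <- function(x, Z = NULL, M = NULL,
                            names = c("sigma2_a1", "sigma_a1a2", "sigma2_a2")) {
  stopifnot(length(names) == 3L)
  structure(list(type = "regression", x = as.numeric(x), Z = Z, M = M,
                 names = names),
            class = "lmm_term")
}

#' Unstructured multi-trait random term
#'
#' For records partitioned into traits (factor `f`), contributes an
#' unstructured t x t genetic covariance over a shared relationship matrix:
#' one parameter per distinct pair of traits.  Used by the three-section
#' multi-trait benchmark.
#'
#' @param f factor giving each record's trait.
#' @inheritParams rand_scalar
#' @param prefix parameter-name prefix; names become `prefix[t,s]`.
#' @export
rand_unstructured <- function(f, Z = NULL, M = NULL, prefix = "k") {
  f <- as.factor(f)
  structure(list(type = "unstructured", f = f, Z = Z, M = M, prefix = prefix),
            class = "lmm_term")
}

#' Residual specifications
#'
#' `resid_hom()` is a single homogeneous residual variance.  `resid_het2(x)`
#' models the residual of record *i* as \eqn{e_{1i} + x_i e_{2i}} with
#' 2x2 coefficient covariance `E`, giving per-record variance
#' \eqn{\sigma^2_{e1} + 2 x_i \sigma_{e1e2} + x_i^2 \sigma^2_{e2}}.  `E` is
#' deliberately *not* constrained positive definite: the model is a
#' quadratic variance function of the gradient and only the per-record
#' variances must stay positive over the observed range.
#' `resid_groups(f)` gives each level of `f` its own residual variance
#' (between-group residual covariances fixed at zero).
#'
#' @param x per-record standardised environmental covariate.
#' @param f factor of residual-variance groups.
#' @name residuals
#' @export
resid_hom <- function() {
  structure(list(type = "hom"), class = "lmm_resid")
}

#' @rdname residuals
#' @export
resid_het2 <- function(x) {
  structure(list(type = "het2", x = as.numeric(x)), class = "lmm_resid")
}

#' @rdname residuals
#' @export
resid_groups <- function(f) {
  structure(list(type = "groups", f = as.factor(f)), class = "lmm_resid")
}

## ---- spec assembly -------------------------------------------------------

.apply_Z <- function(Z, M) {
  ## Z M Z' with NULL meaning identity
  if (is.null(M)) {
    if (is.null(Z)) stop("term needs at least one of Z, M", call. = FALSE)
    tcrossprod(Z)
  } else if (is.null(Z)) {
    M
  } else {
    Z %*% M %*% t(Z)
  }
}

.term_components <- function(term, n) {
  switch(term$type,
    scalar = {
      V <- if (is.null(term$Z) && is.null(term$M)) diag(n) else
        .apply_Z(term$Z, term$M)
      list(mats = list(V), names = term$name, vartype = "var")
    },
    regression = {
      x <- term$x
      if (length(x) != n) stop("covariate length does not match records",
                               call. = FALSE)
      Z1 <- if (is.null(term$Z)) diag(n) else term$Z
      Z2 <- x * Z1
      M <- term$M
      A11 <- .apply_Z(Z1, M)
      A12 <- if (is.null(M)) tcrossprod(Z1, Z2) else Z1 %*% M %*% t(Z2)
      A22 <- .apply_Z(Z2, M)
      list(mats = list(A11, A12 + t(A12), A22),
           names = term$names, vartype = c("var", "cov", "var"))
    },
    unstructured = {
      f <- term$f
      lev <- levels(f)
      t_ <- length(lev)
      Zb <- if (is.null(term$Z)) diag(n) else term$Z
      S <- lapply(lev, function(l) (f == l) * Zb)
      M <- term$M
      mats <- list(); nm <- character(0); vt <- character(0)
      for (a in seq_len(t_)) for (b in a:t_) {
        Vab <- if (is.null(M)) tcrossprod(S[[a]], S[[b]]) else
          S[[a]] %*% M %*% t(S[[b]])
        if (a == b) {
          mats <- c(mats, list(Vab))
          vt <- c(vt, "var")
        } else {
          mats <- c(mats, list(Vab + t(Vab)))
          vt <- c(vt, "cov")
        }
        nm <- c(nm, paste0(term$prefix, "[", lev[a], ",", lev[b], "]"))
      }
      list(mats = mats, names = nm, vartype = vt)
    },
    stop("unknown term type")
  )
}

.resid_components <- function(resid, n) {
  switch(resid$type,
    hom = list(mats = list(diag(n)), names = "sigma2_e", vartype = "var"),
    het2 = {
      x <- resid$x
      if (length(x) != n) stop("residual covariate length mismatch",
                               call. = FALSE)
      list(mats = list(diag(n), diag(2 * x), diag(x^2)),
           names = c("sigma2_e1", "sigma_e1e2", "sigma2_e2"),
           vartype = c("var", "cov", "var"))
    },
    groups = {
      f <- resid$f
      lev <- levels(f)
      list(mats = lapply(lev, function(l) diag(as.numeric(f == l))),
           names = paste0("sigma2_e[", lev, "]"),
           vartype = rep("var", length(lev)))
    }
  )
}

#' Specify a linear mixed model with linear covariance structure
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (already under the caller's
#'   identifiability constraint, e.g. from [stats::model.matrix()] with
#'   reference-level contrasts).  Must be full column rank; rank-deficient
#'   designs raise an error naming the aliased columns.
#' @param random list of random terms from [rand_scalar()],
#'   [rand_regression()], [rand_unstructured()].
#' @param residual residual specification, see [resid_hom()].
#' @return object of class `lmm_spec`.
#' @export
model_spec <- function(y, X, random = list(), residual = resid_hom()) {
  y <- as.numeric(y)
  n <- length(y)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and y have different numbers of records",
                         call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (inherits(random, "lmm_term")) random <- list(random)
  comps <- list(); nm <- character(0); vt <- character(0)
  term_index <- list()
  pos <- 0L
  for (i in seq_along(random)) {
    tc <- .term_components(random[[i]], n)
    comps <- c(comps, tc$mats)
    nm <- c(nm, tc$names)
    vt <- c(vt, tc$vartype)
    term_index[[i]] <- pos + seq_along(tc$mats)
    pos <- pos + length(tc$mats)
  }
  rc <- .resid_components(residual, n)
  comps <- c(comps, rc$mats)
  nm <- c(nm, rc$names)
  vt <- c(vt, rc$vartype)
  resid_index <- pos + seq_along(rc$mats)
  if (anyDuplicated(nm))
    nm <- make.unique(nm)
  structure(list(y = y, X = X, random = random, residual = residual,
                 components = comps, par_names = nm, par_type = vt,
                 term_index = term_index, resid_index = resid_index,
                 n = n),
            class = "lmm_spec")
}

#' @export
print.lmm_spec <- function(x, ...) {
  cat("Linear mixed model spec: ", x$n, " records, ",
      ncol(x$X), " fixed-effect columns, ",
      length(x$par_names), " variance parameters (",
      paste(x$par_names, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

.build_V <- function(spec, theta) {
  V <- matrix(0, spec$n, spec$n)
  for (k in seq_along(theta)) V <- V + theta[k] * spec$components[[k]]
  V
}

## Core per-theta quantities; errors (not NaN) on non-PD covariance.
.lmm_eval <- function(spec, theta, need_P = TRUE) {
  V <- .build_V(spec, theta)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    stop("covariance matrix is not positive definite at theta = (",
         paste(signif(theta, 4), collapse = ", "), ")", call. = FALSE)
  Vi <- chol2inv(ch)
  X <- spec$X
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx))
    stop("X'V^{-1}X singular: fixed effects confounded", call. = FALSE)
  XtViX_inv <- chol2inv(chx)
  beta <- drop(XtViX_inv %*% crossprod(ViX, spec$y))
  names(beta) <- colnames(X)
  Viy <- Vi %*% spec$y
  Py <- Viy - ViX %*% (XtViX_inv %*% crossprod(ViX, spec$y))
  Py <- drop(Py)
  n <- spec$n; p <- ncol(X)
  logdetV <- 2 * sum(log(diag(ch)))
  logdetX <- 2 * sum(log(diag(chx)))
  yPy <- sum(spec$y * Py)
  logL <- -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetX + yPy)
  out <- list(V = V, Vi = Vi, ViX = ViX, XtViX_inv = XtViX_inv,
              beta = beta, Py = Py, logL = logL)
  if (need_P)
    out$P <- Vi - ViX %*% tcrossprod(XtViX_inv, ViX)
  out
}

#' Restricted log-likelihood at a parameter value
#'
#' Evaluates the full REML log-likelihood
#' \eqn{-\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| + y'Py]}
#' so that differences between nested fits are valid likelihood-ratio
#' statistics.
#'
#' @param spec an [model_spec()] object.
#' @param theta variance-parameter vector, in `spec$par_names` order.
#' @return scalar log-likelihood.
#' @export
restricted_loglik <- function(spec, theta) {
  .lmm_eval(spec, theta, need_P = FALSE)$logL
}

#' Solve the mixed-model equations at fixed variance parameters
#'
#' Returns the BLUE of fixed effects and BLUP of every random term for
#' given variance parameters, via the marginal (GLS) form
#' \eqn{\hat\beta = (X'V^{-1}X)^{-1}X'V^{-1}y},
#' \eqn{\hat u = \mathrm{Cov}(u, y) P y}.
#'
#' @inheritParams restricted_loglik
#' @return list with `beta`, `u` (one entry per random term; regression
#'   terms return a two-column matrix of intercept and slope effects;
#'   unstructured terms one column per trait), and `fitted` (X beta).
#' @export
solve_mme <- function(spec, theta) {
  ev <- .lmm_eval(spec, theta, need_P = FALSE)
  Py <- ev$Py
  u <- vector("list", length(spec$random))
  names(u) <- vapply(seq_along(spec$random), function(i) {
    tm <- spec$random[[i]]
    if (!is.null(tm[["name"]])) tm[["name"]]
    else if (!is.null(tm[["prefix"]])) tm[["prefix"]]
    else "regression"
  }, character(1))
  for (i in seq_along(spec$random)) {
    tm <- spec$random[[i]]
    th <- theta[spec$term_index[[i]]]
    u[[i]] <- .term_blup(tm, th, Py, spec$n)
  }
  list(beta = ev$beta, u = u, fitted = drop(spec$X %*% ev$beta),
       logL = ev$logL)
}

.term_blup <- function(tm, th, Py, n) {
  MZt_py <- function(Z, M, v) {
    w <- if (is.null(Z)) v else drop(crossprod(Z, v))
    if (is.null(M)) w else drop(M %*% w)
  }
  switch(tm$type,
    scalar = th[1] * MZt_py(tm$Z, tm$M, Py),
    regression = {
      Z1 <- tm$Z
      x <- tm$x
      z1p <- if (is.null(Z1)) Py else drop(crossprod(Z1, Py))
      z2p <- if (is.null(Z1)) x * Py else drop(crossprod(x * Z1, Py))
      Mw <- function(w) if (is.null(tm$M)) w else drop(tm$M %*% w)
      cbind(intercept = Mw(th[1] * z1p + th[2] * z2p),
            slope     = Mw(th[2] * z1p + th[3] * z2p))
    },
    unstructured = {
      f <- tm$f; lev <- levels(f); t_ <- length(lev)
      K <- matrix(0, t_, t_)
      K[upper.tri(K, diag = TRUE)] <- th
      K <- K + t(K) - diag(diag(K))
      Zb <- if (is.null(tm$Z)) diag(n) else tm$Z
      Sp <- vapply(lev, function(l) drop(crossprod((f == l) * Zb, Py)),
                   numeric(ncol(Zb)))
      out <- Sp %*% K
      if (!is.null(tm$M)) out <- tm$M %*% out
      colnames(out) <- lev
      out
    })
}

## ---- AI-REML -------------------------------------------------------------

.default_init <- function(spec) {
  r <- qr.resid(qr(spec$X), spec$y)
  v <- stats::var(r)
  k <- length(spec$par_names)
  th <- numeric(k)
  is_var <- spec$par_type == "var"
  is_res <- seq_len(k) %in% spec$resid_index
  ## put half the residual variance on the residual intercept terms,
  ## spread the rest over the genetic variances
  nv_res <- sum(is_var & is_res)
  nv_gen <- sum(is_var & !is_res)
  th[is_var & is_res] <- 0.5 * v / max(nv_res, 1)
  th[is_var & !is_res] <- 0.5 * v / max(nv_gen, 1)
  th[!is_var] <- 0
  ## het2 residual: keep the slope variance modest so V stays PD
  if (spec$residual$type == "het2") {
    idx <- spec$resid_index
    th[idx[1]] <- 0.5 * v
    th[idx[3]] <- 0.05 * v
  }
  th
}

#' Fit a mixed model by average-information REML
#'
#' Maximises the restricted likelihood by AI-REML.  Each iteration solves
#' `AI %*% delta = score`; if the proposed point has a non-positive-definite
#' covariance or decreases the likelihood, the step is halved (up to
#' `max_halving` times), falling back to a scaled score step.  Variance
#' parameters are unconstrained apart from overall positive definiteness of
#' `V`, which is what permits a negative residual slope variance in the
#' heterogeneous residual model.
#'
#' @inheritParams restricted_loglik
#' @param init optional starting values; defaults to an equal split of the
#'   OLS residual variance over the variance parameters.
#' @param tol relative log-likelihood convergence tolerance.
#' @param ptol relative parameter-change tolerance.
#' @param max_iter maximum AI iterations.
#' @param max_halving step-halvings per iteration before the score
#'   fallback.
#' @param verbose print the likelihood trajectory.
#' @return object of class `lmm_fit`: `theta`, `se`, `theta_cov` (inverse
#'   average-information matrix), `beta`, `u`, `logL`, `converged`,
#'   `n_iter`, `trajectory`.  Non-convergence is flagged, not an error.
#' @export
reml_fit <- function(spec, init = NULL, tol = 1e-6, ptol = 1e-4,
                     max_iter = 100L, max_halving = 12L, verbose = FALSE) {
  stopifnot(inherits(spec, "lmm_spec"))
  theta <- if (is.null(init)) .default_init(spec) else as.numeric(init)
  if (length(theta) != length(spec$par_names))
    stop("init has wrong length; expected ", length(spec$par_names),
         " parameters (", paste(spec$par_names, collapse = ", "), ")",
         call. = FALSE)
  ev <- .lmm_eval(spec, theta)   # errors if init infeasible
  trajectory <- ev$logL
  converged <- FALSE
  AI <- NULL
  iter <- 0L
  K <- length(theta)
  for (iter in seq_len(max_iter)) {
    P <- ev$P
    Py <- ev$Py
    ## score and AI matrix for the linear structure
    Tm <- vapply(spec$components, function(Vk) drop(Vk %*% Py),
                 numeric(spec$n))                      # n x K
    PT <- P %*% Tm
    score <- numeric(K)
    for (k in seq_len(K))
      score[k] <- -0.5 * (sum(P * spec$components[[k]]) - sum(Py * Tm[, k]))
    AI <- 0.5 * crossprod(Tm, PT)
    AI <- (AI + t(AI)) / 2
    delta <- tryCatch(solve(AI, score), error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta)))
      delta <- score / max(diag(AI), 1e-8)
    ## step-halving until feasible and non-decreasing
    step <- 1
    ok <- FALSE
    for (h in seq_len(max_halving)) {
      cand <- theta + step * delta
      ev_new <- tryCatch(.lmm_eval(spec, cand), error = function(e) NULL)
      if (!is.null(ev_new) && is.finite(ev_new$logL) &&
          ev_new$logL >= ev$logL - 1e-10) {
        ok <- TRUE
        break
      }
      step <- step / 2
    }
    if (!ok) {
      ## scaled score-ascent fallback
      sc <- 0.1 * max(abs(theta)) / max(abs(score), 1e-12)
      for (h in seq_len(max_halving)) {
        cand <- theta + sc * score
        ev_new <- tryCatch(.lmm_eval(spec, cand), error = function(e) NULL)
        if (!is.null(ev_new) && is.finite(ev_new$logL) &&
            ev_new$logL >= ev$logL - 1e-10) {
          ok <- TRUE
          break
        }
        sc <- sc / 2
      }
    }
    if (!ok) break  # stuck: report non-convergence
    dl <- abs(ev_new$logL - ev$logL) / (abs(ev$logL) + 1)
    dp <- max(abs(cand - theta)) / (max(abs(theta)) + 1)
    theta <- cand
    ev <- ev_new
    trajectory <- c(trajectory, ev$logL)
    if (verbose)
      message(sprintf("iter %3d logL %.6f", iter, ev$logL))
    if (dl < tol && dp < ptol) {
      converged <- TRUE
      break
    }
  }
  theta_cov <- tryCatch(solve(AI), error = function(e)
    matrix(NA_real_, K, K))
  theta_cov <- (theta_cov + t(theta_cov)) / 2
  dimnames(theta_cov) <- list(spec$par_names, spec$par_names)
  names(theta) <- spec$par_names
  sol <- solve_mme(spec, theta)
  structure(list(theta = theta, se = sqrt(pmax(diag(theta_cov), 0)),
                 theta_cov = theta_cov, beta = sol$beta, u = sol$u,
                 logL = ev$logL, converged = converged, n_iter = iter,
                 trajectory = trajectory, par_names = spec$par_names),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("AI-REML fit: logL =", format(x$logL, digits = 8),
      if (x$converged) sprintf("(converged, %d iterations)", x$n_iter)
      else sprintf("(NOT converged after %d iterations)", x$n_iter), "\n")
  print(data.frame(estimate = x$theta, se = x$se, row.names = x$par_names))
  invisible(x)
}

#' Likelihood-ratio test between nested REML fits
#'
#' @param fit_null,fit_alt fitted models (`lmm_fit` or anything with a
#'   `logL` element), the null nested in the alternative with identical
#'   data and fixed effects.
#' @param df difference in number of variance parameters.
#' @param tol tolerance for a slightly negative statistic before it is
#'   treated as an optimizer failure.
#' @return list with `statistic` and `p` (upper-tail chi-square).
#' @export
lr_test <- function(fit_null, fit_alt, df, tol = 1e-6) {
  l0 <- if (is.list(fit_null)) fit_null$logL else as.numeric(fit_null)
  l1 <- if (is.list(fit_alt)) fit_alt$logL else as.numeric(fit_alt)
  stat <- 2 * (l1 - l0)
  if (stat < -tol)
    stop("negative likelihood-ratio statistic (", format(stat),
         "): alternative fit did not reach its optimum", call. = FALSE)
  stat <- max(stat, 0)
  list(statistic = stat, p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
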