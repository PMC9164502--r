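#' End-to-end pipeline: simulate, QC, gradient, reaction norms, MTM, GWAS
#'
#' [run_pipeline()] executes the stages in dependency order, writing
#' every artifact as a tab-delimited table with a provenance comment
#' header (package version, seed, configuration hash), so a rerun with
#' the same configuration and seed produces bit-identical numeric
#' tables.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed integer seed driving the whole run (overrides the
#'   simulation config's seed).
#' @param sim a [sim_config()] for the synthetic population.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "qc", "grm", "gradient", "rnm_hom", "rnm_het",
#'   "mtm", "gwas")`.  Dependencies are checked before anything runs.
#' @param maf_min,callrate_min,hwe_p_min QC thresholds.
#' @param dup_r duplicate-sample correlation threshold.
#' @param min_cg minimum CG size for the record filters.
#' @param section_thresholds MTM section thresholds, see
#'   [assign_sections()].
#' @param alpha GWAS family-wise error rate.
#' @param p_method GWAS p-value mode, see [snp_pvalues()].
#' @param correction_mode slope scale-correction mode, see
#'   [scale_correct()].
#' @param compare_points gradient values for the environment comparison.
#' @return configuration of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            sim = sim_config(seed = seed),
                            stages = c("simulate", "qc", "grm", "gradient",
                                       "rnm_hom", "rnm_het", "mtm", "gwas"),
                            maf_min = 0.01, callrate_min = 0.90,
                            hwe_p_min = 1e-15, dup_r = 0.98,
                            min_cg = 15,
                            section_thresholds = c(low_max = -1.13,
                                                   avg_abs_max = 0.59,
                                                   high_min = 1.13),
                            alpha = 0.05,
                            p_method = "empirical_sd",
                            correction_mode = "component",
                            compare_points = c(-1.5, 0, 1.5)) {
  all_stages <- c("simulate", "qc", "grm", "gradient", "rnm_hom",
                  "rnm_het", "mtm", "gwas")
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  deps <- list(qc = "simulate", grm = "qc", gradient = c("grm"),
               rnm_hom = c("gradient"), rnm_het = c("gradient"),
               mtm = c("gradient"), gwas = c("rnm_hom", "rnm_het"))
  for (s in stages) {
    need <- setdiff(deps[[s]], stages)
    if (length(need))
      stop("stage '", s, "' requires stage(s): ",
           paste(need, collapse = ", "), call. = FALSE)
  }
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 stages = stages, maf_min = maf_min,
                 callrate_min = callrate_min, hwe_p_min = hwe_p_min,
                 dup_r = dup_r, min_cg = min_cg,
                 section_thresholds = section_thresholds, alpha = alpha,
                 p_method = p_method, correction_mode = correction_mode,
                 compare_points = compare_points),
            class = "pipeline_config")
}

.config_hash <- function(config) {
  ## polynomial rolling hash over the deparsed configuration (stays
  ## within 31-bit integer range); the output path is not part of the
  ## scientific configuration, so identical analyses hash identically
  ## wherever they are written
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- paste(deparse(cfg), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the pipeline
#'
#' Executes the configured stages in order.  A stage failure writes a
#' `FAILED` marker file naming the stage and halts downstream stages;
#' artifacts already written are retained.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return (invisibly) list with `status` (`"ok"` or `"failed"`),
#'   `failed_stage` (or `NULL`), and the in-memory stage results
#'   (`sim`, `panel`, `grm`, `gradient`, `rnm_hom`, `rnm_het`, `mtm`,
#'   `gwas`, `summary`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste("gxenorm", as.character(utils::packageVersion("gxenorm"))),
           paste("seed:", config$seed),
           paste("config:", .config_hash(config)))
  res <- list(status = "ok", failed_stage = NULL)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  out <- function(...) file.path(config$out_dir, ...)
  on_stage <- function(name, body) {
    tryCatch(body, error = function(e) {
      writeLines(c(paste("stage:", name), paste("error:", conditionMessage(e))),
                 out("FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  enabled <- function(s) s %in% config$stages

  result <- tryCatch({
    if (enabled("simulate")) {
      say("simulate")
      res$sim <- on_stage("simulate", {
        sim <- simulate_population(config$sim)
        write_simulation(sim, out("sim"), hdr)
        sim
      })
    }
    panel <- res$sim$panel
    if (enabled("qc")) {
      say("qc")
      res$qc <- on_stage("qc", {
        qc <- qc_filter(panel, config$maf_min, config$callrate_min,
                        config$hwe_p_min)
        dup <- find_duplicates(qc$panel, config$dup_r)
        qc$panel <- drop_duplicates(qc$panel, dup)
        .write_tsv(data.frame(criterion = c("callrate", "hwe", "maf",
                                            "total", "duplicates"),
                              removed = c(qc$report$removed_callrate,
                                          qc$report$removed_hwe,
                                          qc$report$removed_maf,
                                          qc$report$removed_total,
                                          nrow(dup))),
                   out("qc_report.tsv"), hdr)
        qc
      })
      panel <- res$qc$panel
    }
    if (enabled("grm")) {
      say("grm")
      res$cg_geno <- on_stage("grm", center_genotypes(panel))
      res$grm <- on_stage("grm", {
        g <- compute_grm(res$cg_geno)
        write_grm_gcta(g, out("grm"))
        g
      })
    }
    if (enabled("gradient")) {
      say("gradient")
      res$gradient <- on_stage("gradient", {
        flt <- filter_for_gradient(res$sim$pheno, min_cg = config$min_cg)
        blue <- fit_cg_blue(flt$pheno, res$grm)
        grad <- standardize_gradient(blue, flt$pheno)
        .write_tsv(data.frame(cg_id = names(blue$blues),
                              blue = unname(blue$blues)),
                   out("cg_blues.tsv"), hdr)
        .write_tsv(data.frame(animal_id = names(grad$x),
                              cg_id = unname(grad$cg_id),
                              x = unname(grad$x)),
                   out("gradient.tsv"), hdr)
        list(filter = flt, blue = blue, gradient = grad)
      })
      res$rnm_data <- on_stage("gradient", {
        keep <- res$sim$pheno$animal_id %in% names(res$gradient$gradient$x)
        filter_for_rnm(res$sim$pheno[keep, , drop = FALSE],
                       res$gradient$gradient, min_cg = config$min_cg)$pheno
      })
    }
    for (mod in c("rnm_hom", "rnm_het")) {
      if (!enabled(mod)) next
      say(mod)
      residual <- sub("rnm_", "", mod)
      res[[mod]] <- on_stage(mod, {
        ## restrict to animals present in the (possibly QC-reduced) GRM
        ph <- res$rnm_data[res$rnm_data$animal_id %in%
                             res$grm$animal_ids, , drop = FALSE]
        fit <- fit_rnm(ph, res$gradient$gradient, res$grm,
                       residual = residual)
        prof <- variance_profile(fit)
        cmp <- compare_environments(prof, config$compare_points)
        .write_tsv(prof$profile, out(paste0("profile_", residual, ".tsv")),
                   hdr)
        .write_tsv(cbind(data.frame(env = rownames(cmp$corr)),
                         as.data.frame(cmp$corr)),
                   out(paste0("env_corr_", residual, ".tsv")), hdr)
        .write_tsv(cmp$percent, out(paste0("env_pct_", residual, ".tsv")),
                   hdr)
        list(fit = fit, profile = prof, comparison = cmp)
      })
    }
    if (enabled("rnm_hom") && enabled("rnm_het")) {
      ## parameter report juxtaposing the two models
      tab <- do.call(rbind, lapply(list(res$rnm_hom$fit, res$rnm_het$fit),
        function(f) {
          th <- f$theta; se <- f$se
          g <- function(p) if (p %in% names(th))
            sprintf("%.3f (%.3f)", th[p], se[p]) else "-"
          data.frame(model = f$model, sigma2_a1 = g("sigma2_a1"),
                     sigma2_a2 = g("sigma2_a2"),
                     r_a1a2 = sprintf("%.3f", f$r_a1a2),
                     sigma2_e1 = if (is.null(f$E)) g("sigma2_e") else
                       g("sigma2_e1"),
                     sigma2_e2 = g("sigma2_e2"),
                     sigma_e1e2 = g("sigma_e1e2"), g = g("sigma2_g"),
                     logL = sprintf("%.2f", f$logL),
                     converged = f$converged)
        }))
      .write_tsv(tab, out("params_rnm.tsv"), hdr)
      lrt <- lr_test(res$rnm_hom$fit, res$rnm_het$fit, df = 2)
      .write_tsv(data.frame(statistic = lrt$statistic, df = 2, p = lrt$p),
                 out("lrt_hom_vs_het.tsv"), hdr)
    }
    if (enabled("mtm")) {
      say("mtm")
      res$mtm <- on_stage("mtm", {
        sec <- assign_sections(res$gradient$gradient,
                               config$section_thresholds)
        ph <- res$rnm_data[res$rnm_data$animal_id %in%
                             res$grm$animal_ids, , drop = FALSE]
        fit <- fit_mtm(ph, sec, res$grm)
        .write_tsv(cbind(data.frame(section = rownames(fit$K3)),
                         as.data.frame(fit$K3),
                         Ve = unname(fit$Ve), h2 = unname(fit$h2)),
                   out("mtm_params.tsv"), hdr)
        .write_tsv(cbind(data.frame(section = rownames(fit$corr)),
                         as.data.frame(fit$corr)),
                   out("mtm_corr.tsv"), hdr)
        list(sections = sec, fit = fit)
      })
    }
    if (enabled("gwas")) {
      say("gwas")
      res$gwas <- on_stage("gwas", {
        Ginv <- grm_inverse(res$grm)
        cg <- res$cg_geno
        runs_all <- list()
        for (mod in c("rnm_hom", "rnm_het")) {
          fit <- res[[mod]]$fit
          lab <- sub("rnm_", "", mod)
          corr <- scale_correct(fit, mode = config$correction_mode)
          keep_ids <- names(fit$a1)
          cg_sub <- .subset_centered(cg, keep_ids)
          grm_sub <- .subset_grm(res$grm, keep_ids)
          Gi_sub <- grm_inverse(grm_sub)
          targets <- list(intercept = fit$a1, slope_direct = fit$a2,
                          slope_corrected =
                            stats::setNames(corr$a2_star, keep_ids))
          runs <- lapply(names(targets), function(tg) {
            u <- backsolve_snp_effects(cg_sub, grm_sub, targets[[tg]],
                                       Ginv = Gi_sub)
            a <- snp_pvalues(u, cg_sub, grm_sub,
                             method = config$p_method, target = tg,
                             alpha = config$alpha)
            write_association(a, out(paste0("gwas_", lab, "_", tg, ".tsv")),
                              out(paste0("manhattan_", lab, "_", tg, ".tsv")),
                              hdr)
            a
          })
          names(runs) <- names(targets)
          summ <- association_summary(runs)
          .write_tsv(cbind(data.frame(target = rownames(summ$effect_cor)),
                           as.data.frame(summ$effect_cor)),
                     out(paste0("gwas_", lab, "_effect_cor.tsv")), hdr)
          runs_all[[mod]] <- list(runs = runs, summary = summ,
                                  correction = corr)
        }
        runs_all
      })
    }
    res
  }, error = function(e) {
    res$status <- "failed"
    res$error <- conditionMessage(e)
    mark <- regmatches(conditionMessage(e),
                       regexpr("stage '[a-z_]+'", conditionMessage(e)))
    res$failed_stage <- gsub("stage '|'", "", mark)
    res
  })
  invisible(result)
}

.subset_centered <- function(cg, ids) {
  if (identical(cg$animal_ids, ids)) return(cg)
  ix <- match(ids, cg$animal_ids)
  structure(list(W = cg$W[ix, , drop = FALSE], p = cg$p, d = cg$d,
                 animal_ids = ids, map = cg$map),
            class = "centered_genotypes")
}

.subset_grm <- function(grm, ids) {
  if (identical(grm$animal_ids, ids)) return(grm)
  structure(list(G = grm$G[ids, ids], ridge_used = grm$ridge_used,
                 animal_ids = ids, n_snps = grm$n_snps),
            class = "grm")
}
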