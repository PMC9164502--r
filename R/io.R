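#' Readers and writers for the package's tab-delimited exchange formats
#'
#' Genotypes travel as a dosage table (animals x SNPs, 0/1/2 of the
#' counted allele, `NA` for missing) plus a marker map; GRMs as GCTA-style
#' text triplets; association results as PLINK-style tables.  All tables
#' are tab-delimited; lines starting with `#` are treated as comments.
#'
#' @name io
NULL

.read_tsv <- function(file, ...) {
  utils::read.delim(file, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, ...)
}

.write_tsv <- function(x, file, header_lines = character(0)) {
  con <- file(file, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read a genotype panel as dosage + map tables
#'
#' @param panel a [genotype_panel()].
#' @param dosage_file,map_file file paths.
#' @param header_lines optional provenance comment lines.
#' @return `read_dosage_panel()` returns a [genotype_panel()].
#' @export
write_dosage_panel <- function(panel, dosage_file, map_file,
                               header_lines = character(0)) {
  stopifnot(inherits(panel, "genotype_panel"))
  tab <- data.frame(animal_id = panel$animal_ids,
                    panel$dosage, check.names = FALSE)
  .write_tsv(tab, dosage_file, header_lines)
  .write_tsv(panel$map, map_file, header_lines)
  invisible(c(dosage_file, map_file))
}

#' @rdname write_dosage_panel
#' @export
read_dosage_panel <- function(dosage_file, map_file) {
  tab <- .read_tsv(dosage_file, check.names = FALSE)
  map <- .read_tsv(map_file)
  dosage <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dosage) <- "double"
  genotype_panel(dosage, map, animal_ids = tab[[1]])
}

#' Read a PLINK `.raw` additive-dosage file
#'
#' Accepts the header dialect `FID IID PAT MAT SEX PHENOTYPE` followed by
#' one `SNP_allele` column per marker (values 0/1/2/NA counting the named
#' allele).  A map is synthesised (unknown chromosome 0, bp by column
#' order) unless `map` is supplied.
#'
#' @param file path to the `.raw` file (whitespace-delimited).
#' @param map optional marker map matching the SNP columns.
#' @return a [genotype_panel()].
#' @export
read_plink_raw <- function(file, map = NULL) {
  tab <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(tab)[1:6]))
    stop("not a PLINK .raw header (expected FID IID PAT MAT SEX PHENOTYPE)",
         call. = FALSE)
  snp_cols <- setdiff(names(tab), meta)
  dosage <- as.matrix(tab[, snp_cols, drop = FALSE])
  storage.mode(dosage) <- "double"
  ## SNP_allele -> snp id and counted allele
  snp_id <- sub("_[^_]*$", "", snp_cols)
  allele1 <- sub("^.*_", "", snp_cols)
  if (is.null(map))
    map <- data.frame(chrom = 0L, snp_id = snp_id,
                      bp = seq_along(snp_id), allele1 = allele1,
                      allele2 = "?", stringsAsFactors = FALSE)
  genotype_panel(dosage, map, animal_ids = tab$IID)
}

#' Write / read a GRM as GCTA-style text files
#'
#' `<prefix>.grm.txt` holds the 1-based lower triangle as
#' `i j n_snps value`; `<prefix>.grm.id` holds family and individual ids.
#'
#' @param grm a [compute_grm()] result.
#' @param prefix file prefix.
#' @return `read_grm_gcta()` returns a `grm` object (with `ridge_used`
#'   unknown, 0).
#' @export
write_grm_gcta <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$G)
  idx <- which(lower.tri(grm$G, diag = TRUE), arr.ind = TRUE)
  ## GCTA convention: row index >= column index
  tab <- data.frame(i = idx[, 1], j = idx[, 2], n_snps = grm$n_snps,
                    value = grm$G[idx])
  tab <- tab[order(tab$i, tab$j), ]
  utils::write.table(tab, paste0(prefix, ".grm.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(fid = grm$animal_ids, iid = grm$animal_ids),
                     paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm_gcta
#' @export
read_grm_gcta <- function(prefix) {
  tab <- utils::read.table(paste0(prefix, ".grm.txt"))
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)
  n <- nrow(ids)
  G <- matrix(0, n, n)
  G[cbind(tab[[1]], tab[[2]])] <- tab[[4]]
  G[cbind(tab[[2]], tab[[1]])] <- tab[[4]]
  dimnames(G) <- list(ids[[2]], ids[[2]])
  structure(list(G = G, ridge_used = 0, animal_ids = ids[[2]],
                 n_snps = tab[[3]][1]),
            class = "grm")
}

#' Write a phenotype/covariate table
#'
#' @param pheno phenotype data.frame (see [simulate_phenotypes()]).
#' @param file path.
#' @param header_lines optional provenance comment lines.
#' @export
write_phenotypes <- function(pheno, file, header_lines = character(0)) {
  .write_tsv(pheno, file, header_lines)
  invisible(file)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(file) {
  .read_tsv(file, check.names = FALSE)
}
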