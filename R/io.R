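#' Export genotypes as a plain dosage matrix
#'
#' Tab-separated text: one row per individual (id column first), one column
#' per locus, values 0/1/2 (reference-allele counts).
#'
#' @param pop a `gs_pop`.
#' @param file output path.
#' @param loci optional locus subset.
#' @export
write_geno_matrix <- function(pop, file, loci = NULL) {
  g <- genotypes(pop, loci)
  colnames(g) <- paste0("L", if (is.null(loci)) seq_len(ncol(g)) else loci)
  df <- data.frame(id = pop$id, g, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export phased genotypes to VCF
#'
#' Positions are mapped to base pairs under the 1 cM = 1 Mb convention
#' (`round(Morgans * 1e8)`), contig `"1"`. Requires the suggested vcfR
#' package; output is bgzipped by vcfR.
#'
#' @param pop a `gs_pop`.
#' @param file output path (`.vcf.gz`).
#' @param loci optional locus subset.
#' @export
write_vcf <- function(pop, file, loci = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("write_vcf() needs the vcfR package")
  if (is.null(loci)) loci <- seq_len(nrow(pop$haps))
  h <- pop$haps[loci, , drop = FALSE]
  n <- ncol(h) %/% 2L
  gt <- matrix(paste0(h[, seq(1L, 2L * n, 2L), drop = FALSE], "|",
                      h[, seq(2L, 2L * n, 2L), drop = FALSE]),
               nrow = length(loci))
  colnames(gt) <- paste0(pop$breed, pop$id)
  fix <- cbind(CHROM = "1",
               POS = as.character(round(pop$positions[loci] * 1e8)),
               ID = paste0("L", loci), REF = "A", ALT = "T", QUAL = ".",
               FILTER = "PASS", INFO = ".")
  vcf <- methods::new("vcfR",
                      meta = c("##fileformat=VCFv4.2",
                               "##contig=<ID=1>",
                               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                      fix = fix,
                      gt = cbind(FORMAT = "GT", gt))
  vcfR::write.vcf(vcf, file)
  invisible(file)
}

#' Read an external training set
#'
#' Genotypes: either a dosage matrix written by [write_geno_matrix()] or a
#' VCF (read with vcfR, dosage = count of the ALT allele). Phenotypes: a
#' two-column delimited file `id`, `y`.
#'
#' @param geno_file genotype path (`.vcf`/`.vcf.gz` or tab-separated matrix).
#' @param pheno_file phenotype path.
#' @return A `gs_train` usable with [fit_blasso()].
#' @export
read_training_set <- function(geno_file, pheno_file) {
  ph <- utils::read.table(pheno_file, header = TRUE, sep = "\t")
  if (!all(c("id", "y") %in% names(ph)))
    abort("phenotype file needs columns `id` and `y`")
  if (grepl("\\.vcf(\\.gz)?$", geno_file)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      abort("reading VCF needs the vcfR package")
    v <- vcfR::read.vcfR(geno_file, verbose = FALSE)
    gt <- vcfR::extract.gt(v)
    X <- t(apply(gt, 2, function(col) {
      vapply(strsplit(col, "[|/]"), function(al) sum(as.integer(al)),
             integer(1))
    }))
    ids <- rownames(X)
  } else {
    df <- utils::read.table(geno_file, header = TRUE, sep = "\t",
                            check.names = FALSE)
    ids <- as.character(df$id)
    X <- as.matrix(df[, -1, drop = FALSE])
  }
  ord <- match(as.character(ph$id), ids)
  if (anyNA(ord)) abort("phenotype ids missing from the genotype file")
  X <- X[ord, , drop = FALSE]
  storage.mode(X) <- "integer"
  if (any(!X %in% 0:2)) abort("genotype dosages must be 0, 1 or 2")
  structure(list(y = as.numeric(ph$y), X = X, Z = (X == 1L) * 1L,
                 breed = rep("ext", nrow(X)), id = as.character(ph$id)),
            class = "gs_train")
}

#' Serialize a trait architecture
#'
#' @param arch a `gs_arch`.
#' @param file output path; tab-separated with scaling metadata in `#`
#'   comment lines.
#' @export
write_architecture <- function(arch, file) {
  con <- file(file, "w")
  on.exit(close(con))
  sf <- attr(arch, "scale_factors")
  writeLines(sprintf("# scaled: %s; scale_a: %.10g; scale_d: %.10g",
                     isTRUE(attr(arch, "scaled")), sf[["a"]], sf[["d"]]), con)
  utils::write.table(as.data.frame(arch), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
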