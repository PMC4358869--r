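#' Phased population objects
#'
#' A `gs_pop` holds one generation of a simulated population: a phased
#' haplotype matrix (loci in rows, two columns per individual), a pedigree
#' slice (ids and parent ids), sexes, and labels for the simulation step and
#' breed. Alleles are coded 0/1; allele 1 is the reference allele everywhere
#' (genotype dosage = count of allele 1).
#'
#' @param haps integer matrix, `n_loci x 2*n_ind`, values 0/1; columns
#'   `2i-1, 2i` are the two haplotypes of individual `i`.
#' @param id,sire,dam integer vectors of length `n_ind` (`NA` for founders).
#' @param sex character vector, `"M"`/`"F"`.
#' @param generation single string tagging step and generation index.
#' @param breed one of `"historical"`, `"A"`, `"B"`, `"AB"`.
#' @return An object of class `gs_pop`.
#' @export
new_population <- function(haps, id, sire = rep(NA_integer_, length(id)),
                           dam = rep(NA_integer_, length(id)), sex,
                           generation = "0", breed = "historical") {
  stopifnot(is.matrix(haps), ncol(haps) == 2L * length(id),
            length(sex) == length(id))
  structure(
    list(haps = haps, id = as.integer(id), sire = as.integer(sire),
         dam = as.integer(dam), sex = as.character(sex),
         generation = generation, breed = breed),
    class = "gs_pop"
  )
}

#' @export
print.gs_pop <- function(x, ...) {
  cat(sprintf("<gs_pop> breed %s, generation %s: %d individuals x %d loci\n",
              x$breed, x$generation, n_ind(x), nrow(x$haps)))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `gs_pop`.
#' @export
n_ind <- function(pop) ncol(pop$haps) %/% 2L

#' Reference-allele frequencies
#'
#' @param pop a `gs_pop`.
#' @param loci optional integer locus indices (default: all).
#' @return Numeric vector of allele-1 frequencies.
#' @export
allele_freq <- function(pop, loci = NULL) {
  h <- if (is.null(loci)) pop$haps else pop$haps[loci, , drop = FALSE]
  rowMeans(h)
}

#' Minor allele frequencies
#' @inheritParams allele_freq
#' @export
maf <- function(pop, loci = NULL) {
  p <- allele_freq(pop, loci)
  pmin(p, 1 - p)
}

#' Genotype dosage matrix
#'
#' @inheritParams allele_freq
#' @return Integer matrix `n_ind x n_loci` of reference-allele counts (0/1/2).
#' @export
genotypes <- function(pop, loci = NULL) {
  h <- if (is.null(loci)) pop$haps else pop$haps[loci, , drop = FALSE]
  n <- ncol(h) %/% 2L
  g <- h[, seq(1L, 2L * n, by = 2L), drop = FALSE] +
    h[, seq(2L, 2L * n, by = 2L), drop = FALSE]
  t(g)
}

#' Tidy per-individual view of a population
#'
#' @param pop a `gs_pop`.
#' @return A tibble with one row per individual (no genotypes).
#' @export
pop_tibble <- function(pop) {
  tibble(id = pop$id, sire = pop$sire, dam = pop$dam, sex = pop$sex,
         generation = pop$generation, breed = pop$breed)
}

# Offspring construction shared by all simulation steps. sires/dams are
# 1-based indices into pop; one offspring per entry. Sexes are assigned to
# balance exactly 50/50 (random assignment of which offspring are male).
make_offspring <- function(pop, sires, dams, positions, chrom_len, mut_rate,
                           generation, breed = pop$breed, id_start = 1L) {
  n_off <- length(sires)
  haps <- cpp_offspring(pop$haps, as.integer(sires - 1L),
                        as.integer(dams - 1L), positions, chrom_len, mut_rate)
  n_m <- n_off %/% 2L
  sex <- rep("F", n_off)
  sex[sample.int(n_off, n_m)] <- "M"
  new_population(haps, id = seq.int(id_start, length.out = n_off),
                 sire = pop$id[sires], dam = pop$id[dams], sex = sex,
                 generation = generation, breed = breed)
}
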