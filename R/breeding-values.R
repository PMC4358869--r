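#' Breeding values for purebred or crossbred performance
#'
#' For a parent mated at random into a line with reference-allele frequency
#' `p` at locus `j`, the expected offspring genotypic value contributed by
#' that locus is
#' `p a + q d` (parent AA), `0.5 p a + 0.5 q d + 0.5 p d - 0.5 q a` (Aa) or
#' `-q a + p d` (aa). Purebred breeding values use the individual's own-line
#' frequencies; crossbred breeding values use the other line's. With true QTL
#' effects this yields TBVP/TBVC; with estimated SNP effects and candidate
#' SNP frequencies it yields GEBVP/GEBVC.
#'
#' @param geno dosage matrix `n_ind x n_loci` (0/1/2), QTL or SNP panel.
#' @param a,d effect vectors (true or estimated), one per locus.
#' @param p reference-allele frequencies of the mate line, one per locus.
#' @param component `"total"`, `"additive"` (d set to 0 in the weights) or
#'   `"dominance"` (a set to 0); additive + dominance = total exactly.
#' @return Numeric vector of breeding values.
#' @export
breeding_value <- function(geno, a, d, p,
                           component = c("total", "additive", "dominance")) {
  component <- match.arg(component)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  m <- ncol(geno)
  if (length(a) != m || length(d) != m || length(p) != m)
    abort("effect/frequency vectors must match the genotype columns")
  if (component == "additive") d <- rep(0, m)
  if (component == "dominance") a <- rep(0, m)
  q <- 1 - p
  w2 <- p * a + q * d
  w1 <- 0.5 * p * a + 0.5 * q * d + 0.5 * p * d - 0.5 * q * a
  w0 <- -q * a + p * d
  drop((geno == 2L) %*% w2 + (geno == 1L) %*% w1 + (geno == 0L) %*% w0)
}

#' Partition breeding values into additive and dominance components
#'
#' @inheritParams breeding_value
#' @return A tibble with columns `total`, `additive`, `dominance`
#'   (`total = additive + dominance` exactly).
#' @export
bv_partition <- function(geno, a, d, p) {
  tibble(
    total = breeding_value(geno, a, d, p, "total"),
    additive = breeding_value(geno, a, d, p, "additive"),
    dominance = breeding_value(geno, a, d, p, "dominance")
  )
}

#' Accuracy of estimated breeding values
#'
#' Pearson correlation between true and estimated values; undefined (NA) when
#' either vector has zero variance or fewer than 3 records.
#'
#' @param true,estimated numeric vectors.
#' @export
accuracy <- function(true, estimated) {
  stopifnot(length(true) == length(estimated))
  if (length(true) < 3) return(NA_real_)
  if (sd(true) == 0 || sd(estimated) == 0) return(NA_real_)
  cor(true, estimated)
}
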