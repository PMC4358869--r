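#' Signed pairwise LD from phased haplotypes
#'
#' Computes `r` from haplotype frequencies, i.e.
#' `(p_AB - p_A p_B) / sqrt(p_A q_A p_B q_B)`, exactly as the Pearson
#' correlation of the two loci's allele indicators across haplotypes.
#' Monomorphic loci (and loci at or below `maf_min`) are excluded.
#'
#' @param pop a `gs_pop` with phased haplotypes.
#' @param loci integer locus indices (e.g. the SNP panel).
#' @param maf_min strict lower MAF bound for inclusion (0 keeps every
#'   segregating locus).
#' @param max_dist optional maximum pair distance in Morgans.
#' @return A tibble with one row per retained locus pair: `i`, `j` (locus
#'   indices, `i < j` by map order), `dist` (Morgans), `r` and `r2`.
#' @export
ld_pairs <- function(pop, loci, maf_min = 0, max_dist = NULL) {
  keep <- loci[maf(pop, loci) > maf_min]
  if (length(keep) < 2) abort("fewer than two loci pass the MAF filter")
  H <- t(pop$haps[keep, , drop = FALSE])
  r <- cor(H)
  pos <- pop$positions[keep]
  iu <- which(upper.tri(r), arr.ind = TRUE)
  out <- tibble(i = keep[iu[, 1]], j = keep[iu[, 2]],
                dist = abs(pos[iu[, 2]] - pos[iu[, 1]]),
                r = r[iu])
  out$r2 <- out$r^2
  if (!is.null(max_dist)) out <- out[out$dist <= max_dist, ]
  out
}

#' LD decay curve
#'
#' Mean `r^2` of SNP pairs grouped by map distance into half-open 1-cM bins
#' `[k, k+1)` from 0 to `max_cm`. Bins without pairs are `NA`.
#'
#' @param pairs a pair table from [ld_pairs()] (use `maf_min = 0.1` for the
#'   conventional filter).
#' @param max_cm upper bound of the binning range in cM.
#' @return A tibble of class `gs_ld_decay`: `bin_cm` (left edge), `mean_r2`,
#'   `n_pairs`.
#' @export
ld_decay <- function(pairs, max_cm = 100) {
  bin <- floor(pairs$dist * 100)
  res <- tibble(bin_cm = seq(0, max_cm - 1))
  agg <- tapply(pairs$r2, factor(bin, levels = res$bin_cm), mean)
  cnt <- tapply(pairs$r2, factor(bin, levels = res$bin_cm), length)
  res$mean_r2 <- unname(as.numeric(agg))
  res$n_pairs <- unname(ifelse(is.na(cnt), 0L, as.integer(cnt)))
  class(res) <- c("gs_ld_decay", class(res))
  res
}

#' Mean r-squared of adjacent panel SNPs
#'
#' Adjacent means consecutive along the map among the panel SNPs that pass
#' the MAF filter.
#'
#' @inheritParams ld_pairs
#' @export
adjacent_r2 <- function(pop, loci, maf_min = 0.1) {
  keep <- loci[maf(pop, loci) > maf_min]
  if (length(keep) < 2) abort("fewer than two loci pass the MAF filter")
  keep <- keep[order(pop$positions[keep])]
  H <- t(pop$haps[keep, , drop = FALSE])
  k <- length(keep)
  r <- vapply(seq_len(k - 1), function(s) cor(H[, s], H[, s + 1]), 0)
  mean(r^2)
}

#' Between-breed persistence of LD phase
#'
#' For SNP pairs built from loci segregating (MAF > 0) in both breeds, the
#' signed `r` is computed per pair in each breed (with a consistent reference
#' allele, inherited from the shared simulation coding) and Pearson-correlated
#' between breeds within half-open 1-cM distance bins from 0 to `max_cm`.
#'
#' @param pop_a,pop_b `gs_pop` objects for the two breeds.
#' @param loci SNP panel locus indices.
#' @param max_cm upper distance bound in cM (pairs farther apart are
#'   excluded).
#' @return A tibble of class `gs_phase`: `bin_cm`, `R_AB`, `n_pairs`. The
#'   attribute `pairs` holds the per-pair table (`dist`, `r_a`, `r_b`).
#' @export
phase_persistence <- function(pop_a, pop_b, loci, max_cm = 50) {
  keep <- loci[maf(pop_a, loci) > 0 & maf(pop_b, loci) > 0]
  if (length(keep) < 2) abort("fewer than two loci segregate in both breeds")
  ra <- cor(t(pop_a$haps[keep, , drop = FALSE]))
  rb <- cor(t(pop_b$haps[keep, , drop = FALSE]))
  pos <- pop_a$positions[keep]
  iu <- which(upper.tri(ra), arr.ind = TRUE)
  pairs <- tibble(dist = abs(pos[iu[, 2]] - pos[iu[, 1]]),
                  r_a = ra[iu], r_b = rb[iu])
  pairs <- pairs[pairs$dist < max_cm / 100, ]
  bin <- floor(pairs$dist * 100)
  bins <- seq(0, max_cm - 1)
  f <- factor(bin, levels = bins)
  R <- vapply(split(seq_len(nrow(pairs)), f), function(idx) {
    if (length(idx) < 2) return(NA_real_)
    suppressWarnings(cor(pairs$r_a[idx], pairs$r_b[idx]))
  }, 0)
  out <- tibble(bin_cm = bins, R_AB = as.numeric(R),
                n_pairs = as.integer(table(f)))
  attr(out, "pairs") <- pairs
  class(out) <- c("gs_phase", class(out))
  out
}

#' Headline LD statistics for a pair of training populations
#'
#' Convenience wrapper computing, from the two breeds' training populations:
#' mean adjacent-SNP `r^2` (averaged over breeds, MAF > 0.1), mean `r^2` of
#' the first and fifth 1-cM distance intervals (pairs up to 1 cM / between 4
#' and 5 cM apart), the between-breed phase correlation `R_AB` in the first
#' 1-cM interval, and `R_AB` for pairs closer than 50 kb (0.05 cM).
#'
#' @param train_a,train_b `gs_pop` training populations.
#' @param snp_loci SNP panel locus indices.
#' @return A one-row tibble: `adjacent_r2`, `r2_1cm`, `r2_5cm`, `R_AB_1cm`,
#'   `R_AB_50kb`.
#' @export
ld_regime_stats <- function(train_a, train_b, snp_loci) {
  dec <- lapply(list(train_a, train_b), function(p)
    ld_decay(ld_pairs(p, snp_loci, maf_min = 0.1)))
  pp <- phase_persistence(train_a, train_b, snp_loci)
  tibble(
    adjacent_r2 = mean(c(adjacent_r2(train_a, snp_loci),
                         adjacent_r2(train_b, snp_loci))),
    r2_1cm = mean(vapply(dec, function(d) d$mean_r2[d$bin_cm == 0], 0)),
    r2_5cm = mean(vapply(dec, function(d) d$mean_r2[d$bin_cm == 4], 0)),
    R_AB_1cm = pp$R_AB[pp$bin_cm == 0],
    R_AB_50kb = phase_correlation_below(pp, 0.05)
  )
}

#' Phase correlation for pairs closer than a distance cutoff
#'
#' Under the 1 cM = 1 Mb convention, `max_dist_cm = 0.05` is the "< 50 kb"
#' statistic.
#'
#' @param phase a `gs_phase` result (with its `pairs` attribute) or a pair
#'   tibble with columns `dist`, `r_a`, `r_b`.
#' @param max_dist_cm strict upper bound on pair distance, in cM.
#' @export
phase_correlation_below <- function(phase, max_dist_cm = 0.05) {
  pairs <- if (is_tibble(phase) && all(c("r_a", "r_b") %in% names(phase)))
    phase else attr(phase, "pairs")
  sub <- pairs[pairs$dist < max_dist_cm / 100, ]
  if (nrow(sub) < 2) return(NA_real_)
  cor(sub$r_a, sub$r_b)
}
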