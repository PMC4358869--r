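#' The five selection scenarios
#'
#' Breed A is the sire line, breed B the dam line. Scenarios differ in the
#' selection criterion per breed (GEBV for purebred vs crossbred performance)
#' and in whether marker effects come from separate per-breed reference
#' populations or one combined reference.
#'
#' @return A tibble: `scenario`, `criterion_A`, `criterion_B`, `training`.
#' @export
scenario_table <- function() {
  tibble(
    scenario = c("ref", "1", "2", "3", "4"),
    criterion_A = c("GEBVP", "GEBVC", "GEBVC", "GEBVC", "GEBVC"),
    criterion_B = c("GEBVP", "GEBVP", "GEBVC", "GEBVP", "GEBVC"),
    training = c("separate", "separate", "separate", "common", "common")
  )
}

#' Selection-program settings
#' @param n_sires,n_dams selected males/females per breed per generation.
#' @param offspring_per_dam litter size (purebred and crossbred).
#' @param n_generations selection generations.
#' @export
prog_config <- function(n_sires = 100L, n_dams = 200L,
                        offspring_per_dam = 5L, n_generations = 5L) {
  stopifnot(n_sires > 0, n_dams > 0, offspring_per_dam > 0,
            n_generations > 0)
  structure(list(n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
                 offspring_per_dam = as.integer(offspring_per_dam),
                 n_generations = as.integer(n_generations)),
            class = "gs_prog")
}

# A cohort is a population plus its genotypic values and phenotypes.
make_cohort <- function(pop, arch, params) {
  G <- genotypic_value(genotypes(pop, arch$qtl), arch)
  list(pop = pop, G = G, y = simulate_phenotype(G, params))
}

subset_pop <- function(pop, idx) {
  cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  out <- new_population(pop$haps[, cols, drop = FALSE], id = pop$id[idx],
                        sire = pop$sire[idx], dam = pop$dam[idx],
                        sex = pop$sex[idx], generation = pop$generation,
                        breed = pop$breed)
  out$positions <- pop$positions
  out
}

#' Found the base selection populations
#'
#' Per breed, `n_sires` males and `n_dams` females are sampled at random from
#' the training generation and mated randomly (`offspring_per_dam` offspring
#' per dam, one random sire per dam with replacement) to produce the
#' generation-0 candidates (1000 per breed at study scale, sexes balanced).
#'
#' @param train_a,train_b training populations (generation 8 of the expansion
#'   step) for breeds A and B.
#' @param arch scaled trait architecture.
#' @param params [trait_params()].
#' @param pcfg [prog_config()].
#' @param cfg [sim_config()] (for mutation rate and chromosome length).
#' @return List with cohorts `A` and `B` (each `pop`, `G`, `y`).
#' @export
found_base <- function(train_a, train_b, arch, params, pcfg, cfg) {
  lapply(list(A = train_a, B = train_b), function(tp) {
    if (n_ind(tp) < pcfg$n_sires + pcfg$n_dams)
      abort("training population too small to found the base generation")
    pop <- litter_generation(tp, pcfg$n_sires, pcfg$n_dams,
                             pcfg$offspring_per_dam, cfg, "G0")
    make_cohort(pop, arch, params)
  })
}

#' Truncation selection within sex
#'
#' Top `n_sires` males and `n_dams` females by the criterion; ties broken by
#' individual id (ascending), so selection is deterministic given the values.
#'
#' @param pop a `gs_pop`.
#' @param values criterion per individual (finite).
#' @param pcfg [prog_config()].
#' @return List with integer index vectors `males` and `females`.
#' @export
select_top <- function(pop, values, pcfg) {
  stopifnot(length(values) == n_ind(pop))
  if (any(!is.finite(values))) abort("selection criterion must be finite")
  pick <- function(idx, k) {
    if (length(idx) < k) abort("fewer candidates than the selection quota")
    o <- idx[order(-values[idx], pop$id[idx])]
    o[seq_len(k)]
  }
  list(males = pick(which(pop$sex == "M"), pcfg$n_sires),
       females = pick(which(pop$sex == "F"), pcfg$n_dams))
}

# GEBV (or TBV) of candidates for a given criterion. `est` carries a/d
# effect vectors and the loci they refer to; p_own/p_other are the matching
# current-generation candidate frequencies.
criterion_values <- function(geno, a, d, p_own, p_other, criterion) {
  p <- if (criterion == "GEBVP") p_own else p_other
  bv_partition(geno, a, d, p)
}

cross_offspring <- function(sel_a_pop, sel_b_pop, cfg, pcfg, generation) {
  stopifnot(all(sel_a_pop$sex == "M"), all(sel_b_pop$sex == "F"))
  haps <- cbind(sel_a_pop$haps, sel_b_pop$haps)
  na <- n_ind(sel_a_pop)
  joint <- new_population(haps, id = seq_len(na + n_ind(sel_b_pop)),
                          sex = c(sel_a_pop$sex, sel_b_pop$sex),
                          generation = generation, breed = "AB")
  joint$positions <- sel_a_pop$positions
  dams <- na + seq_len(n_ind(sel_b_pop))
  dam_sire <- sample.int(na, length(dams), replace = TRUE)
  off <- make_offspring(joint, rep(dam_sire, each = pcfg$offspring_per_dam),
                        rep(dams, each = pcfg$offspring_per_dam),
                        joint$positions, cfg$chrom_len, cfg$mutation_rate,
                        generation, breed = "AB")
  off$positions <- joint$positions
  off
}

#' Run one selection scenario
#'
#' Five generations of within-breed truncation selection on the scenario's
#' criterion, with marker effects estimated once before selection starts.
#' Allele frequencies entering the breeding-value formulas are recomputed
#' from the current selection candidates each generation. Each round also
#' mates the selected breed-A males to the selected breed-B females to
#' produce a terminal crossbred cohort.
#'
#' Reported at generation `g` (the `g`-th selection round): the
#' criterion-matched accuracies (total, additive and dominance components)
#' and the purebred-crossbred correlation of true breeding values, both
#' evaluated on the candidates that round selects among; the phenotypic means
#' of the purebred replacements and the crossbred cohort that round produces;
#' and the expected heterosis `H = sum_l d_l (p_Al - p_Bl)^2` over QTL from
#' the selected parents' frequencies.
#'
#' @param base list with base cohorts `A`, `B` from [found_base()] (shared
#'   across scenarios of one replicate).
#' @param arch scaled trait architecture (`gs_arch`).
#' @param est_a,est_b marker effects used for breeds A and B: `gs_blasso`
#'   fits (the same object in common-training scenarios) or plain tibbles
#'   with columns `a_hat`, `d_hat` (e.g. true effects, for validation).
#' @param snp_loci SNP panel locus indices.
#' @param criterion_a,criterion_b `"GEBVP"` or `"GEBVC"`.
#' @param params [trait_params()].
#' @param pcfg [prog_config()].
#' @param cfg [sim_config()].
#' @param scenario label recorded in the output.
#' @return A tibble of generation summaries (class `gs_scenario`).
#' @export
run_scenario <- function(base, arch, est_a, est_b, snp_loci,
                         criterion_a, criterion_b, params, pcfg, cfg,
                         scenario = "ref") {
  stopifnot(criterion_a %in% c("GEBVP", "GEBVC"),
            criterion_b %in% c("GEBVP", "GEBVC"))
  cand <- base
  as_eff <- function(est) {
    if (inherits(est, "gs_blasso")) est <- tidy(est)
    stopifnot(all(c("a_hat", "d_hat") %in% names(est)))
    est
  }
  eff <- list(A = as_eff(est_a), B = as_eff(est_b))
  crit <- list(A = criterion_a, B = criterion_b)
  rows <- vector("list", pcfg$n_generations)

  for (g in seq_len(pcfg$n_generations)) {
    freq_snp <- lapply(cand, function(co) allele_freq(co$pop, snp_loci))
    freq_qtl <- lapply(cand, function(co) allele_freq(co$pop, arch$qtl))
    sel <- list(); acc <- list(); rpc <- list()
    for (br in c("A", "B")) {
      other <- setdiff(c("A", "B"), br)
      geno_s <- genotypes(cand[[br]]$pop, snp_loci)
      geno_q <- genotypes(cand[[br]]$pop, arch$qtl)
      gebv <- criterion_values(geno_s, eff[[br]]$a_hat, eff[[br]]$d_hat,
                               freq_snp[[br]], freq_snp[[other]], crit[[br]])
      tbv <- criterion_values(geno_q, arch$a, arch$d,
                              freq_qtl[[br]], freq_qtl[[other]], crit[[br]])
      acc[[br]] <- c(bv = accuracy(tbv$total, gebv$total),
                     add = accuracy(tbv$additive, gebv$additive),
                     dom = accuracy(tbv$dominance, gebv$dominance))
      tbvp <- breeding_value(geno_q, arch$a, arch$d, freq_qtl[[br]])
      tbvc <- breeding_value(geno_q, arch$a, arch$d, freq_qtl[[other]])
      rpc[[br]] <- accuracy(tbvp, tbvc)
      sel[[br]] <- select_top(cand[[br]]$pop, gebv$total, pcfg)
    }
    sel_a_m <- subset_pop(cand$A$pop, sel$A$males)
    sel_b_f <- subset_pop(cand$B$pop, sel$B$females)

    # next purebred candidates
    new_cand <- list()
    for (br in c("A", "B")) {
      keep <- c(sel[[br]]$males, sel[[br]]$females)
      sp <- subset_pop(cand[[br]]$pop, keep)
      pop <- litter_generation(sp, pcfg$n_sires, pcfg$n_dams,
                               pcfg$offspring_per_dam, cfg, paste0("G", g))
      new_cand[[br]] <- make_cohort(pop, arch, params)
    }
    # terminal crossbreds
    ab_pop <- cross_offspring(sel_a_m, sel_b_f, cfg, pcfg, paste0("AB", g))
    ab <- make_cohort(ab_pop, arch, params)

    # heterosis expected for this crossbred cohort, from its parents' gametes
    H <- heterosis(arch$d, allele_freq(sel_a_m, arch$qtl),
                   allele_freq(sel_b_f, arch$qtl))

    cand <- new_cand
    freq_qtl <- lapply(cand, function(co) allele_freq(co$pop, arch$qtl))

    rows[[g]] <- tibble(
      scenario = scenario, generation = g,
      criterion_A = criterion_a, criterion_B = criterion_b,
      crossbred_mean = mean(ab$y), crossbred_G = mean(ab$G),
      heterosis = H,
      mean_pheno_A = mean(cand$A$y), mean_pheno_B = mean(cand$B$y),
      breed_average = (mean(cand$A$y) + mean(cand$B$y)) / 2,
      acc_A = acc$A[["bv"]], acc_A_add = acc$A[["add"]],
      acc_A_dom = acc$A[["dom"]],
      acc_B = acc$B[["bv"]], acc_B_add = acc$B[["add"]],
      acc_B_dom = acc$B[["dom"]],
      r_pc_A = rpc$A, r_pc_B = rpc$B,
      qtl_freq_div = sum((freq_qtl$A - freq_qtl$B)^2)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gs_scenario", class(out))
  out
}

#' Expected heterosis from allele-frequency divergence
#'
#' With dominance as the only non-additive effect, the excess of the
#' crossbred mean over the parental average is `H = sum_l d_l (p_Al - p_Bl)^2`
#' over QTL.
#'
#' @param d dominance effects per QTL.
#' @param p_a,p_b reference-allele frequencies in the two parental gamete
#'   pools.
#' @export
heterosis <- function(d, p_a, p_b) {
  stopifnot(length(d) == length(p_a), length(p_a) == length(p_b))
  sum(d * (p_a - p_b)^2)
}

#' Purebred-crossbred correlation of true breeding values
#'
#' Correlation between TBV for purebred and for crossbred performance among
#' candidates, reported per breed and pooled.
#'
#' @param base cohorts `A`, `B` (e.g. from [found_base()]).
#' @param arch scaled `gs_arch`.
#' @return A tibble: `breed` (`A`, `B`, `pooled`) and `r_pc`.
#' @export
purebred_crossbred_correlation <- function(base, arch) {
  freq <- lapply(base, function(co) allele_freq(co$pop, arch$qtl))
  vals <- lapply(c(A = "A", B = "B"), function(br) {
    other <- setdiff(c("A", "B"), br)
    geno <- genotypes(base[[br]]$pop, arch$qtl)
    tibble(
      tbvp = breeding_value(geno, arch$a, arch$d, freq[[br]]),
      tbvc = breeding_value(geno, arch$a, arch$d, freq[[other]])
    )
  })
  tibble(
    breed = c("A", "B", "pooled"),
    r_pc = c(accuracy(vals$A$tbvp, vals$A$tbvc),
             accuracy(vals$B$tbvp, vals$B$tbvc),
             accuracy(c(vals$A$tbvp, vals$B$tbvp),
                      c(vals$A$tbvc, vals$B$tbvc)))
  )
}
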