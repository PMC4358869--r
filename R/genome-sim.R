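#' Simulate the historical population
#'
#' Runs the ancestral phases: `phase1_generations` at constant size, then a
#' gradual decline to `phase2_end_size` (plus an optional terminal plateau,
#' used by the high LD-phase regime). Mating is random union of gametes (each
#' offspring draws one gamete from a random male and one from a random
#' female); the only evolutionary forces are recurrent mutation and drift.
#' Starting allele frequencies are uniform on (0, 1); candidate locus
#' positions are uniform on the 1-Morgan chromosome.
#'
#' @param cfg a [sim_config()].
#' @return The final historical generation as a [new_population()] object,
#'   with the genetic map stored in `$positions`.
#' @export
simulate_historical <- function(cfg) {
  validate_sim_config(cfg)
  n_loci <- cfg$n_candidates
  positions <- sort(runif(n_loci, 0, cfg$chrom_len))
  while (anyDuplicated(positions)) {
    positions <- sort(c(positions[!duplicated(positions)],
                        runif(sum(duplicated(positions)), 0, cfg$chrom_len)))
  }
  p0 <- runif(n_loci)
  n0 <- cfg$phase1_size
  haps <- matrix(as.integer(runif(n_loci * 2L * n0) < p0), nrow = n_loci)
  sex <- rep(1L, n0)
  sex[sample.int(n0, n0 %/% 2L)] <- 0L
  sizes <- historical_sizes(cfg)
  res <- cpp_run_phase(haps, sex, as.integer(sizes), positions,
                       cfg$chrom_len, cfg$mutation_rate)
  pop <- new_population(res$haps, id = seq_len(ncol(res$haps) %/% 2L),
                        sex = c("M", "F")[res$sex + 1L],
                        generation = paste0("HG", length(sizes)))
  pop$positions <- positions
  pop
}

# Litter-based random mating used from breed formation onward: n_sires and
# n_dams parents are sampled from the previous generation, each dam gets one
# sire drawn uniformly with replacement, and litters have fixed size.
litter_generation <- function(pop, n_sires, n_dams, litter, cfg, generation,
                              breed = pop$breed) {
  males <- which(pop$sex == "M")
  females <- which(pop$sex == "F")
  if (length(males) < 1L || length(females) < 1L)
    abort("need parents of both sexes")
  sire_pool <- males[sample.int(length(males), min(n_sires, length(males)))]
  dam_set <- females[sample.int(length(females), min(n_dams, length(females)))]
  dam_sire <- sire_pool[sample.int(length(sire_pool), length(dam_set),
                                   replace = TRUE)]
  sires <- rep(dam_sire, each = litter)
  dams <- rep(dam_set, each = litter)
  off <- make_offspring(pop, sires, dams, pop$positions, cfg$chrom_len,
                        cfg$mutation_rate, generation, breed = breed)
  off$positions <- pop$positions
  off
}

#' Split the historical population into two diverging breeds
#'
#' Two disjoint founder sets are drawn from the last historical generation
#' (balanced for sex so random mating is always possible) and each breed is
#' randomly mated for `breed_generations` generations: `breed_sires` sires
#' and `breed_dams` dams are sampled per generation, each dam receives one
#' sire drawn uniformly with replacement and a litter of
#' `offspring_per_dam_bf`, giving a census of 250 at the default settings.
#' No selection acts.
#'
#' @param historical the final historical generation from
#'   [simulate_historical()].
#' @param cfg a [sim_config()].
#' @return A list with `gs_pop` elements `A` and `B`.
#' @export
split_and_diverge <- function(historical, cfg) {
  need <- 2L * (cfg$breed_founder_males + cfg$breed_founder_females)
  if (n_ind(historical) < need)
    abort(sprintf("need >= %d historical animals to found the breeds", need))
  males <- which(historical$sex == "M")
  females <- which(historical$sex == "F")
  if (length(males) < 2L * cfg$breed_founder_males ||
      length(females) < 2L * cfg$breed_founder_females)
    abort("too few historical animals of one sex to found both breeds")
  ms <- sample(males, 2L * cfg$breed_founder_males)
  fs <- sample(females, 2L * cfg$breed_founder_females)
  founders <- list(
    A = c(ms[seq_len(cfg$breed_founder_males)],
          fs[seq_len(cfg$breed_founder_females)]),
    B = c(ms[-seq_len(cfg$breed_founder_males)],
          fs[-seq_len(cfg$breed_founder_females)])
  )
  out <- lapply(c(A = "A", B = "B"), function(br) {
    idx <- founders[[br]]
    cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    pop <- new_population(historical$haps[, cols, drop = FALSE],
                          id = seq_along(idx), sex = historical$sex[idx],
                          generation = "BF0", breed = br)
    pop$positions <- historical$positions
    for (t in seq_len(cfg$breed_generations)) {
      pop <- litter_generation(pop, cfg$breed_sires, cfg$breed_dams,
                               cfg$offspring_per_dam_bf, cfg,
                               paste0("BF", t))
    }
    pop
  })
  out
}

#' Expand a breed to training-population size
#'
#' `expansion_sires` sires and `expansion_dams` dams are sampled per
#' generation and each dam produces `offspring_per_dam_eg` offspring, giving
#' 1000 individuals per generation at the study-scale settings. The final
#' generation is the training population.
#'
#' @param breed a `gs_pop` from [split_and_diverge()].
#' @param cfg a [sim_config()].
#' @param keep_all if `TRUE`, return every expansion generation (list);
#'   otherwise just the final one.
#' @return A `gs_pop` (or list of them when `keep_all = TRUE`).
#' @export
expand_breed <- function(breed, cfg, keep_all = FALSE) {
  if (n_ind(breed) < cfg$expansion_sires + cfg$expansion_dams)
    abort("too few animals to found the expansion step")
  gens <- vector("list", cfg$expansion_generations)
  pop <- breed
  for (t in seq_len(cfg$expansion_generations)) {
    pop <- litter_generation(pop, cfg$expansion_sires, cfg$expansion_dams,
                             cfg$offspring_per_dam_eg, cfg, paste0("EG", t))
    gens[[t]] <- pop
  }
  if (keep_all) gens else pop
}

#' Select the SNP and QTL panels
#'
#' Draws `n_snp` marker loci and `n_qtl` QTL without replacement from the
#' candidate loci whose minor allele frequency in the last historical
#' generation is at least `maf_threshold`. Panels are disjoint; positions are
#' inherited from the candidate map.
#'
#' @param historical the final historical generation.
#' @param cfg a [sim_config()].
#' @return A tibble (`locus`, `pos`, `role`) with one row per candidate locus
#'   and `role` in `candidate`/`snp`/`qtl`.
#' @export
select_panels <- function(historical, cfg) {
  m <- maf(historical)
  eligible <- which(m >= cfg$maf_threshold)
  need <- cfg$n_snp + cfg$n_qtl
  if (length(eligible) < need)
    abort(sprintf(paste0(
      "only %d candidate loci segregate at MAF >= %.2f (need %d); ",
      "increase n_candidates (the candidate-locus multiplier)"),
      length(eligible), cfg$maf_threshold, need))
  chosen <- sample(eligible, need)
  role <- rep("candidate", length(m))
  role[chosen[seq_len(cfg$n_snp)]] <- "snp"
  role[chosen[-seq_len(cfg$n_snp)]] <- "qtl"
  tibble(locus = seq_along(m), pos = historical$positions, role = role)
}

#' Locus indices of a panel role
#' @param map a panel map from [select_panels()].
#' @param role `"snp"` or `"qtl"`.
#' @export
panel_loci <- function(map, role) {
  map$locus[map$role == role]
}

#' Single-gamete meiosis (exposed for inspection and testing)
#'
#' Crossover count is Poisson with mean equal to the chromosome map length
#' (Haldane model, no interference), crossover positions uniform; each
#' transmitted allele then flips with probability `mut_rate`.
#'
#' @param pop a `gs_pop`.
#' @param parent individual index.
#' @param mut_rate recurrent mutation probability per locus per gamete.
#' @param chrom_len chromosome length in Morgans.
#' @return Integer haplotype vector.
#' @export
make_gamete <- function(pop, parent, mut_rate = 0, chrom_len = 1) {
  drop(cpp_gamete(pop$haps, as.integer(parent - 1L), pop$positions,
                  chrom_len, mut_rate))
}
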