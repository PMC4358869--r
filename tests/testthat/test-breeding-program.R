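# small-scale program settings used throughout this file
small_pcfg <- prog_config(n_sires = 20, n_dams = 40, offspring_per_dam = 5,
                          n_generations = 3)

fake_estimates <- function(m, seed = 1) {
  withr::with_seed(seed, tibble::tibble(a_hat = rnorm(m, 0, 0.05),
                                        d_hat = rnorm(m, 0, 0.02)))
}

smoke_base <- function() {
  cached("smoke_base", {
    sim <- smoke_sim()
    arch <- withr::with_seed(121, {
      a0 <- sample_qtl_effects(sim$cfg$n_qtl,
                               qtl_loci = panel_loci(sim$map, "qtl"))
      scale_effects(a0, rep(0.5, sim$cfg$n_qtl))
    })
    base <- withr::with_seed(122,
      found_base(sim$training$A, sim$training$B, arch, trait_params(),
                 small_pcfg, sim$cfg))
    list(sim = sim, arch = arch, base = base)
  })
}

test_that("the base generation has the designed size, sexes and pedigree", {
  sb <- smoke_base()
  for (br in c("A", "B")) {
    pop <- sb$base[[br]]$pop
    expect_equal(n_ind(pop), small_pcfg$n_dams * small_pcfg$offspring_per_dam)
    expect_equal(sum(pop$sex == "M"), n_ind(pop) %/% 2L)
    expect_true(all(pop$sire %in% sb$sim$training[[br]]$id))
    expect_true(all(pop$dam %in% sb$sim$training[[br]]$id))
    expect_equal(length(sb$base[[br]]$y), n_ind(pop))
  }
  expect_error(found_base(sb$base$A$pop, sb$base$B$pop, sb$arch,
                          trait_params(), prog_config(), sb$sim$cfg),
               "too small")
})

test_that("truncation selection picks the top animals, ties broken by id", {
  sb <- smoke_base()
  pop <- sb$base$A$pop
  vals <- withr::with_seed(123, rnorm(n_ind(pop)))
  sel <- select_top(pop, vals, small_pcfg)
  expect_length(sel$males, small_pcfg$n_sires)
  expect_length(sel$females, small_pcfg$n_dams)
  expect_true(all(pop$sex[sel$males] == "M"))
  unsel_m <- setdiff(which(pop$sex == "M"), sel$males)
  expect_gte(min(vals[sel$males]), max(vals[unsel_m]))
  # all-equal criterion: the first animals by id are taken (documented rule)
  sel0 <- select_top(pop, rep(0, n_ind(pop)), small_pcfg)
  males <- which(pop$sex == "M")
  expect_identical(sel0$males,
                   males[order(pop$id[males])][seq_len(small_pcfg$n_sires)])
  expect_error(select_top(pop, vals, prog_config(n_sires = 10000)), "quota")
  expect_error(select_top(pop, c(NA, vals[-1]), small_pcfg), "finite")
})

test_that("heterosis follows the frequency-divergence identity", {
  d <- c(0.2, -0.1, 0.3)
  expect_equal(heterosis(d, c(0.5, 0.2, 0.9), c(0.5, 0.2, 0.9)), 0)
  expect_equal(heterosis(d, c(1, 0, 1), c(0, 0, 1)), 0.2)
  expect_equal(heterosis(0.4, 0.3, 0.8), 0.4 * 0.25)
})

test_that("a scenario run conserves cohort sizes and tracks its criteria", {
  sb <- smoke_base()
  est <- fake_estimates(sb$sim$cfg$n_snp, 124)
  out <- withr::with_seed(125, run_scenario(
    sb$base, sb$arch, est, est, panel_loci(sb$sim$map, "snp"),
    "GEBVC", "GEBVP", trait_params(), small_pcfg, sb$sim$cfg,
    scenario = "1"))
  expect_s3_class(out, "gs_scenario")
  expect_equal(out$generation, seq_len(small_pcfg$n_generations))
  expect_true(all(out$criterion_A == "GEBVC" & out$criterion_B == "GEBVP"))
  expect_true(all(is.finite(out$crossbred_mean)))
  expect_true(all(is.finite(out$heterosis)))
  expect_equal(out$breed_average,
               (out$mean_pheno_A + out$mean_pheno_B) / 2)
})

test_that("crossbred cohorts match the selected parents' expectation", {
  sb <- smoke_base()
  set.seed(126)
  selA <- select_top(sb$base$A$pop, rnorm(n_ind(sb$base$A$pop)), small_pcfg)
  selB <- select_top(sb$base$B$pop, rnorm(n_ind(sb$base$B$pop)), small_pcfg)
  am <- crossgs:::subset_pop(sb$base$A$pop, selA$males)
  bf <- crossgs:::subset_pop(sb$base$B$pop, selB$females)
  # many crossbred offspring from these parents
  big <- prog_config(n_sires = small_pcfg$n_sires, n_dams = small_pcfg$n_dams,
                     offspring_per_dam = 50, n_generations = 1)
  ab <- crossgs:::cross_offspring(am, bf, sb$sim$cfg, big, "AB1")
  G <- genotypic_value(genotypes(ab, sb$arch$qtl), sb$arch)
  # weight sires by their realized usage (one random sire per dam)
  usage <- tabulate(ab$sire, n_ind(am))
  tbvc_am <- breeding_value(genotypes(am, sb$arch$qtl), sb$arch$a, sb$arch$d,
                            allele_freq(bf, sb$arch$qtl))
  expect_lt(abs(mean(G) - weighted.mean(tbvc_am, usage)),
            3 * sd(G) / sqrt(length(G)) + 0.02)
  # the crossbred mean exceeds the parental average by the expected heterosis
  p_am <- drop(t(genotypes(am, sb$arch$qtl)) %*% usage) / (2 * sum(usage))
  p_bf <- allele_freq(bf, sb$arch$qtl)
  H <- heterosis(sb$arch$d, p_am, p_bf)
  exp_mid <- function(p) sum(sb$arch$a * (2 * p - 1) +
                               2 * p * (1 - p) * sb$arch$d)
  expected_cross <- (exp_mid(p_am) + exp_mid(p_bf)) / 2 + H
  expect_lt(abs(mean(G) - expected_cross),
            3 * sd(G) / sqrt(length(G)) + 0.02)
})

test_that("zero dominance removes the purebred-crossbred distinction", {
  sb <- smoke_base()
  arch0 <- sb$arch
  arch0$d <- rep(0, nrow(arch0))
  base0 <- lapply(sb$base, function(co) {
    co$G <- genotypic_value(genotypes(co$pop, arch0$qtl), arch0)
    co
  })
  rpc <- purebred_crossbred_correlation(base0, arch0)
  expect_equal(rpc$r_pc[1:2], c(1, 1), tolerance = 1e-9)
  # and heterosis is identically zero whatever the divergence
  expect_equal(heterosis(arch0$d, runif(nrow(arch0)), runif(nrow(arch0))), 0)
})
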