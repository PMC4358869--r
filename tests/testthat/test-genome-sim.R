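test_that("meiosis transmits parental haplotypes (identity, Mendel, Haldane)", {
  set.seed(1)
  # identical parental haplotypes, no mutation -> gamete equals them exactly
  h <- matrix(rep(c(0L, 1L, 1L, 0L, 1L), 2L), ncol = 2)
  pop <- toy_pop(h, positions = c(0.05, 0.2, 0.5, 0.7, 0.95))
  for (k in 1:5) expect_identical(make_gamete(pop, 1), h[, 1])

  # fully heterozygous parent: per-locus transmission frequency 1/2
  n_gam <- 2e4
  het <- cbind(rep(1L, 5), rep(0L, 5))
  pop2 <- toy_pop(het, positions = c(0.05, 0.2, 0.5, 0.7, 0.95),
                  sex = c("M"))
  gam <- crossgs:::cpp_offspring(het, rep(0L, n_gam %/% 2L),
                                 rep(0L, n_gam %/% 2L),
                                 pop2$positions, 1, 0)
  freq1 <- rowMeans(gam)
  se <- sqrt(0.25 / n_gam)
  expect_true(all(abs(freq1 - 0.5) < 3 * se))

  # recombinant fraction between loci 0.2 M apart matches Haldane's map
  n <- 1e5
  coup <- matrix(c(1L, 1L, 0L, 0L), nrow = 2) # coupling double heterozygote
  gam2 <- crossgs:::cpp_offspring(coup, rep(0L, n %/% 2L), rep(0L, n %/% 2L),
                                  c(0.4, 0.6), 1, 0)
  rec <- mean(gam2[1, ] != gam2[2, ])
  theta <- (1 - exp(-2 * 0.2)) / 2
  expect_lt(abs(rec - theta), 3 * sqrt(theta * (1 - theta) / n))
})

test_that("drift variance matches Wright's formula for a neutral locus", {
  set.seed(2)
  N <- 50L; t_gen <- 50L; runs <- 400L
  final <- replicate(runs, {
    haps <- matrix(rbinom(2L * N, 1L, 0.5), nrow = 1)
    sex <- rep(0:1, each = N %/% 2L)
    res <- crossgs:::cpp_run_phase(haps, sex, rep(N, t_gen), 0.5, 1, 0)
    mean(res$haps)
  })
  v_obs <- var(final)
  v_exp <- 0.25 * (1 - (1 - 1 / (2 * N))^t_gen)
  se <- v_exp * sqrt(2 / (runs - 1)) * 1.6 # non-normal final freqs
  expect_lt(abs(v_obs - v_exp), 3 * se)
})

test_that("fixed alleles stay fixed and frequency change is centred on zero", {
  set.seed(3)
  n_loci <- 200L
  haps <- rbind(matrix(1L, 50, 40), matrix(rbinom(150 * 40, 1, 0.5), 150, 40))
  sex <- rep(0:1, each = 10L)
  res <- crossgs:::cpp_run_phase(haps, sex, rep(20L, 30L),
                                 sort(runif(n_loci)), 1, 0)
  expect_true(all(res$haps[1:50, ] == 1L))

  # no mutation: one-generation frequency change has mean zero across loci
  p0 <- runif(n_loci, 0.2, 0.8)
  haps2 <- matrix(as.integer(runif(n_loci * 400) < p0), nrow = n_loci)
  res2 <- crossgs:::cpp_run_phase(haps2, rep(0:1, each = 100L), 200L,
                                  sort(runif(n_loci)), 1, 0)
  d <- rowMeans(res2$haps) - rowMeans(haps2)
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(n_loci))
})

test_that("historical simulation is deterministic and respects the schedule", {
  cfg <- sim_config("low", "smoke")
  h1 <- withr::with_seed(7, simulate_historical(cfg))
  h2 <- withr::with_seed(7, simulate_historical(cfg))
  expect_identical(h1$haps, h2$haps)
  expect_identical(h1$sex, h2$sex)
  expect_equal(n_ind(h1), cfg$phase2_end_size)
  expect_equal(sum(h1$sex == "M"), n_ind(h1) %/% 2L)
  # schedule reaching zero is a configuration error
  expect_error(sim_config("low", "smoke", phase1_size = 0L), "positive")
})

test_that("breed split founds two disjoint diverging breeds", {
  sim <- smoke_sim()
  br <- withr::with_seed(11, split_and_diverge(sim$historical, sim$cfg))
  expect_named(br, c("A", "B"))
  expect_equal(n_ind(br$A), sim$cfg$breed_dams * sim$cfg$offspring_per_dam_bf)
  # same seed twice -> identical breed pair
  br2 <- withr::with_seed(11, split_and_diverge(sim$historical, sim$cfg))
  expect_identical(br$A$haps, br2$A$haps)
  expect_identical(br$B$haps, br2$B$haps)
  # fixed loci remain fixed for the same allele in both breeds (mutation off)
  cfg0 <- sim$cfg; cfg0$mutation_rate <- 0
  br0 <- withr::with_seed(12, split_and_diverge(sim$historical, cfg0))
  fixed1 <- allele_freq(sim$historical) == 1
  expect_true(all(allele_freq(br0$A)[fixed1] == 1))
  expect_true(all(allele_freq(br0$B)[fixed1] == 1))
  # too few historical animals to found both breeds
  tiny <- toy_pop(matrix(rbinom(10 * 60, 1, 0.5), nrow = 10))
  expect_error(split_and_diverge(tiny, sim$cfg), "found")
})

test_that("between-breed divergence grows at the drift rate", {
  set.seed(21)
  # pairs of breeds of N individuals drifting from common frequencies p0;
  # loci within a run share a pedigree, so average the ratio to the Wright
  # expectation over independent pairs
  n_loci <- 100L; N <- 30L; T_gen <- 40L
  ratios <- replicate(6, {
    p0 <- runif(n_loci, 0.3, 0.7)
    pos <- sort(runif(n_loci))
    sexes <- rep(0:1, each = N %/% 2L)
    pp <- lapply(1:2, function(k) {
      haps <- matrix(as.integer(runif(n_loci * 2 * N) < p0), nrow = n_loci)
      rowMeans(crossgs:::cpp_run_phase(haps, sexes, rep(N, T_gen),
                                       pos, 1, 0)$haps)
    })
    d2 <- (pp[[1]] - pp[[2]])^2
    expected <- 2 * p0 * (1 - p0) * (1 - (1 - 1 / (2 * N))^T_gen)
    mean(d2) / mean(expected)
  })
  expect_lt(abs(mean(ratios) - 1), 3 * sd(ratios) / sqrt(length(ratios)))
})

test_that("expansion produces the training population with valid pedigree", {
  sim <- smoke_sim()
  br <- withr::with_seed(13, split_and_diverge(sim$historical, sim$cfg))
  gens <- withr::with_seed(14, expand_breed(br$A, sim$cfg, keep_all = TRUE))
  last <- gens[[length(gens)]]
  expect_equal(n_ind(last),
               sim$cfg$expansion_dams * sim$cfg$offspring_per_dam_eg)
  prev <- gens[[length(gens) - 1L]]
  expect_true(all(last$sire %in% prev$id))
  expect_true(all(last$dam %in% prev$id))
  expect_true(all(prev$sex[match(last$sire, prev$id)] == "M"))
  expect_true(all(prev$sex[match(last$dam, prev$id)] == "F"))
  expect_error(expand_breed(sim$historical, sim$cfg), "too few")
})

test_that("panel selection enforces the MAF threshold and panel sizes", {
  sim <- smoke_sim()
  map <- withr::with_seed(15, select_panels(sim$historical, sim$cfg))
  snp <- panel_loci(map, "snp"); qtl <- panel_loci(map, "qtl")
  expect_length(snp, sim$cfg$n_snp)
  expect_length(qtl, sim$cfg$n_qtl)
  expect_length(intersect(snp, qtl), 0)
  m <- maf(sim$historical)
  expect_true(all(m[c(snp, qtl)] >= sim$cfg$maf_threshold))
  expect_identical(map$pos, sim$historical$positions)
  # monomorphic candidates -> instructive error
  mono <- toy_pop(matrix(1L, 10, 20))
  expect_error(select_panels(mono, sim$cfg), "n_candidates")
})

test_that("random mating restores Hardy-Weinberg genotype frequencies", {
  set.seed(31)
  n_loci <- 100L
  p0 <- runif(n_loci, 0.2, 0.8)
  haps <- matrix(as.integer(runif(n_loci * 1000) < p0), nrow = n_loci)
  res <- crossgs:::cpp_run_phase(haps, rep(0:1, 250L), 1000L,
                                 sort(runif(n_loci)), 1, 0)
  pop <- toy_pop(res$haps)
  g <- genotypes(pop)
  p <- colMeans(g) / 2
  chi2 <- vapply(seq_len(n_loci), function(j) {
    obs <- tabulate(g[, j] + 1L, 3L)
    expd <- 1000 * c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2)
    sum((obs - expd)^2 / expd)
  }, 0)
  # aggregate over loci: each locus contributes ~chi-square with 1 df
  expect_lt(sum(chi2), qchisq(0.99, n_loci))
})

test_that("the high LD-phase regime yields more LD than the low regime", {
  r2 <- function(regime, seed) {
    cfg <- sim_config(regime, "smoke")
    set.seed(seed)
    h <- simulate_historical(cfg)
    loci <- which(maf(h) > 0.1)
    adjacent_r2(h, loci)
  }
  vals <- vapply(101:103, function(s) c(low = r2("low", s),
                                        high = r2("high", s)), c(0, 0))
  expect_gt(mean(vals["high", ]), mean(vals["low", ]))
})
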