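pop_from_haps <- function(counts, positions = c(0.1, 0.11)) {
  # counts: named vector over haplotypes "11","10","01","00"
  haps <- cbind(
    matrix(rep(c(1L, 1L), counts[["11"]]), nrow = 2),
    matrix(rep(c(1L, 0L), counts[["10"]]), nrow = 2),
    matrix(rep(c(0L, 1L), counts[["01"]]), nrow = 2),
    matrix(rep(c(0L, 0L), counts[["00"]]), nrow = 2)
  )
  toy_pop(haps, positions = positions)
}

test_that("signed r matches the haplotype-frequency formula", {
  # hand-computable table: AB=40, Ab=10, aB=10, ab=40 -> r = 0.6
  pop <- pop_from_haps(c("11" = 40, "10" = 10, "01" = 10, "00" = 40))
  pr <- ld_pairs(pop, 1:2)
  expect_equal(pr$r, 0.6, tolerance = 1e-12)
  expect_equal(pr$r2, 0.36, tolerance = 1e-12)
  # perfect coupling -> r = 1
  pop2 <- pop_from_haps(c("11" = 50, "10" = 0, "01" = 0, "00" = 50))
  expect_equal(ld_pairs(pop2, 1:2)$r, 1)
  # independent loci at large n: r2 of order 1/n_haplotypes
  set.seed(131)
  pop3 <- toy_pop(matrix(rbinom(4e5, 1, 0.5), nrow = 2),
                  positions = c(0.2, 0.7))
  expect_lt(ld_pairs(pop3, 1:2)$r2, 0.001)
  # monomorphic loci are excluded
  pop4 <- toy_pop(rbind(rep(1L, 100), matrix(rbinom(200, 1, 0.5), 2, 100)),
                  positions = c(0.1, 0.2, 0.3))
  expect_false(1L %in% c(ld_pairs(pop4, 1:3)$i, ld_pairs(pop4, 1:3)$j))
})

test_that("decay bins are half-open 1-cM intervals with NA for empty bins", {
  set.seed(132)
  pos <- c(0.100, 0.105, 0.125, 0.50)
  haps <- matrix(rbinom(4 * 400, 1, 0.5), nrow = 4)
  pop <- toy_pop(haps, positions = pos)
  pr <- ld_pairs(pop, 1:4, maf_min = 0.1)
  dec <- ld_decay(pr, max_cm = 50)
  # pair (1,2) at 0.5 cM and pair (1,3)/(2,3) at 2.5/2 cM
  expect_equal(dec$n_pairs[dec$bin_cm == 0], 1L)
  expect_equal(dec$mean_r2[dec$bin_cm == 0],
               pr$r2[pr$i == 1 & pr$j == 2])
  expect_true(is.na(dec$mean_r2[dec$bin_cm == 10]))
  expect_equal(sum(dec$n_pairs), nrow(pr))
})

test_that("mean r2 decays with distance (averaged over replicates)", {
  set.seed(133)
  n_loci <- 150L; N <- 40L
  bins <- replicate(10, {
    p0 <- runif(n_loci, 0.2, 0.8)
    pos <- sort(runif(n_loci))
    haps <- matrix(as.integer(runif(n_loci * 2 * N) < p0), nrow = n_loci)
    res <- crossgs:::cpp_run_phase(haps, rep(0:1, each = N %/% 2L),
                                   rep(N, 60L), pos, 1, 0)
    pr <- ld_pairs(toy_pop(res$haps, positions = pos), seq_len(n_loci),
                   maf_min = 0.1)
    ld_decay(pr, max_cm = 100)$mean_r2
  })
  avg <- rowMeans(bins, na.rm = TRUE)
  expect_gt(avg[1], avg[6])
  expect_gt(avg[6], avg[31])
})

test_that("phase persistence is 1 for identical breeds and flips with labels", {
  set.seed(134)
  n_loci <- 40L
  p0 <- runif(n_loci, 0.2, 0.8)
  haps <- matrix(as.integer(runif(n_loci * 600) < p0), nrow = n_loci)
  pos <- sort(runif(n_loci, 0, 0.4))
  a <- toy_pop(haps, positions = pos, breed = "A")
  b <- toy_pop(haps, positions = pos, breed = "B")
  pp <- phase_persistence(a, b, seq_len(n_loci))
  expect_true(all(abs(pp$R_AB[!is.na(pp$R_AB)] - 1) < 1e-12))
  expect_equal(phase_correlation_below(pp, 50), 1, tolerance = 1e-12)

  # flipping one SNP's alleles consistently in BOTH breeds leaves R_AB alone
  set.seed(135)
  b2 <- toy_pop(matrix(as.integer(runif(n_loci * 600) < p0), nrow = n_loci),
                positions = pos, breed = "B")
  base <- phase_persistence(a, b2, seq_len(n_loci))
  a_f <- a; b_f <- b2
  a_f$haps[5, ] <- 1L - a_f$haps[5, ]
  b_f$haps[5, ] <- 1L - b_f$haps[5, ]
  both <- phase_persistence(a_f, b_f, seq_len(n_loci))
  # pair-level: both breeds' signed r negate together, exactly
  p_b <- attr(base, "pairs"); p_f <- attr(both, "pairs")
  expect_equal(abs(p_f$r_a), abs(p_b$r_a), tolerance = 1e-12)
  nz <- abs(p_b$r_a) > 1e-9 & abs(p_b$r_b) > 1e-9
  expect_equal(sign(p_f$r_a * p_b$r_a)[nz], sign(p_f$r_b * p_b$r_b)[nz])
  # bin-level: the centred correlation is invariant up to the (near-zero)
  # bin means of r, so well-filled bins agree closely
  full <- !is.na(base$R_AB) & base$n_pairs >= 30
  expect_lt(max(abs(both$R_AB[full] - base$R_AB[full])), 0.1)
  # flipping in ONE breed negates that SNP's signed r there
  a_only <- phase_persistence(a_f, b2, seq_len(n_loci))
  p_base <- attr(base, "pairs"); p_one <- attr(a_only, "pairs")
  flip_rows <- which(abs(p_one$r_a + p_base$r_a) < 1e-12 &
                       abs(p_base$r_a) > 1e-9)
  expect_gt(length(flip_rows), 0)
  expect_equal(p_one$r_b, p_base$r_b, tolerance = 1e-12)

  # the "< 50 kb" statistic is the phase correlation below 0.05 cM
  pr <- attr(base, "pairs")
  sub <- pr[pr$dist < 0.05 / 100, ]
  manual <- if (nrow(sub) >= 2) cor(sub$r_a, sub$r_b) else NA_real_
  expect_equal(phase_correlation_below(base, 0.05), manual)
})
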