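#' Trait parameters
#'
#' Defaults follow the study conditions: unsigned additive QTL effects from
#' Gamma(shape 0.4, scale 1.66) with random sign, dominance degrees
#' h ~ N(0.5, 0.1) independent of the additive effects, target additive and
#' dominance variances 0.3 and 0.1, residual variance 0.6, so phenotypic
#' variance is 1, narrow-sense heritability 0.3 and broad-sense 0.4 in the
#' scaling reference population.
#'
#' @param gamma_shape,gamma_scale gamma parameters of |a|.
#' @param h_mean,h_sd normal parameters of the dominance degree.
#' @param target_V_A,target_V_D target variance components after scaling.
#' @param residual_variance environmental variance of the phenotype.
#' @return A list of class `gs_trait_params`.
#' @export
trait_params <- function(gamma_shape = 0.4, gamma_scale = 1.66,
                         h_mean = 0.5, h_sd = 0.1,
                         target_V_A = 0.3, target_V_D = 0.1,
                         residual_variance = 0.6) {
  stopifnot(gamma_shape > 0, gamma_scale > 0, h_sd >= 0,
            target_V_A > 0, target_V_D >= 0, residual_variance >= 0)
  structure(list(gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 h_mean = h_mean, h_sd = h_sd, target_V_A = target_V_A,
                 target_V_D = target_V_D,
                 residual_variance = residual_variance),
            class = "gs_trait_params")
}

#' Sample unscaled QTL effects
#'
#' `|a| ~ Gamma(shape, scale)`, sign Bernoulli(1/2); `h ~ N(h_mean, h_sd)`
#' independent of `a`; `d = h |a|` (so dominance is directional on average).
#'
#' @param n_qtl number of QTL.
#' @param params a [trait_params()].
#' @param qtl_loci optional locus indices to attach.
#' @return A tibble of class `gs_arch` with columns `qtl`, `a`, `h`, `d` and
#'   attribute `scaled = FALSE`.
#' @export
sample_qtl_effects <- function(n_qtl, params = trait_params(),
                               qtl_loci = seq_len(n_qtl)) {
  stopifnot(n_qtl >= 1)
  abs_a <- rgamma(n_qtl, shape = params$gamma_shape, scale = params$gamma_scale)
  sign_a <- ifelse(runif(n_qtl) < 0.5, -1, 1)
  h <- rnorm(n_qtl, params$h_mean, params$h_sd)
  arch <- tibble(qtl = qtl_loci, a = sign_a * abs_a, h = h, d = h * abs_a)
  attr(arch, "scaled") <- FALSE
  attr(arch, "scale_factors") <- c(a = 1, d = 1)
  class(arch) <- c("gs_arch", class(arch))
  arch
}

# Variance components of the architecture at HWE for given reference-allele
# frequencies: alpha = a + d (q - p), V_A = sum 2 p q alpha^2,
# V_D = sum (2 p q d)^2.
variance_components <- function(a, d, p) {
  q <- 1 - p
  alpha <- a + d * (q - p)
  c(V_A = sum(2 * p * q * alpha^2), V_D = sum((2 * p * q * d)^2))
}

#' Scale QTL effects to the target variance components
#'
#' Two-stage scaling at Hardy-Weinberg using the reference allele
#' frequencies: the dominance vector is scaled first (V_D is quadratic in d,
#' closed form), then the additive scale factor solves the quadratic
#' `V_A(s) = target_V_A` exactly (the average substitution effect
#' `alpha = s a + d (q - p)` makes V_A a quadratic in `s`; the positive root
#' is taken).
#'
#' @param arch a `gs_arch` from [sample_qtl_effects()].
#' @param p_ref reference-allele frequencies at the QTL in the scaling
#'   population (all strictly inside (0, 1)).
#' @param params a [trait_params()].
#' @return The scaled `gs_arch`, with attributes `scale_factors`,
#'   `reference_frequencies` and realized `V_A`/`V_D`.
#' @export
scale_effects <- function(arch, p_ref, params = trait_params()) {
  stopifnot(nrow(arch) == length(p_ref))
  if (any(p_ref <= 0 | p_ref >= 1))
    abort("a QTL is fixed in the reference population; it cannot contribute variance")
  q <- 1 - p_ref
  w <- 2 * p_ref * q
  vd0 <- sum((w * arch$d)^2)
  if (vd0 <= 0) abort("dominance effects are all zero; cannot scale V_D")
  s_d <- sqrt(params$target_V_D / vd0)
  d2 <- arch$d * s_d
  # V_A(s) = A s^2 + B s + C with alpha = s a + d2 (q - p)
  A <- sum(w * arch$a^2)
  B <- sum(w * 2 * arch$a * d2 * (q - p_ref))
  C <- sum(w * (d2 * (q - p_ref))^2)
  disc <- B^2 - 4 * A * (C - params$target_V_A)
  if (disc < 0) abort("target additive variance unreachable at these frequencies")
  s_a <- (-B + sqrt(disc)) / (2 * A)
  out <- arch
  out$a <- arch$a * s_a
  out$d <- d2
  vc <- variance_components(out$a, out$d, p_ref)
  attr(out, "scaled") <- TRUE
  attr(out, "scale_factors") <- c(a = s_a, d = s_d)
  attr(out, "reference_frequencies") <- p_ref
  attr(out, "realized_variances") <- vc
  out
}

#' Genotypic values
#'
#' `G_i = sum_j v_ij` with `v = -a` (0 copies of the reference allele), `d`
#' (heterozygote), `+a` (2 copies).
#'
#' @param geno_qtl integer dosage matrix `n_ind x n_qtl` (0/1/2).
#' @param arch a `gs_arch`.
#' @return Numeric vector of genotypic values.
#' @export
genotypic_value <- function(geno_qtl, arch) {
  if (is.null(dim(geno_qtl))) geno_qtl <- matrix(geno_qtl, nrow = 1)
  stopifnot(ncol(geno_qtl) == nrow(arch))
  if (any(!geno_qtl %in% 0:2)) abort("genotype dosages must be 0, 1 or 2")
  drop((geno_qtl - 1) %*% arch$a + (geno_qtl == 1) %*% arch$d)
}

#' Phenotypes
#'
#' Adds an independent normal residual with variance
#' `params$residual_variance` to the genotypic values.
#'
#' @param G numeric genotypic values.
#' @param params a [trait_params()].
#' @return Numeric phenotypes.
#' @export
simulate_phenotype <- function(G, params = trait_params()) {
  G + rnorm(length(G), 0, sqrt(params$residual_variance))
}

#' Fraction of overdominant QTL
#' @param arch a `gs_arch`.
#' @return Proportion of QTL with `|d| > |a|`.
#' @export
overdominance_fraction <- function(arch) {
  mean(abs(arch$d) > abs(arch$a))
}
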