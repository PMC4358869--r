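#' Hyperparameters of the Bayesian LASSO dominance model
#'
#' Residual variance prior: scaled inverse chi-square with `df_e = 3.5`,
#' `S_e = 3` (density proportional to
#' `(s2)^(-df/2 - 1) exp(-df S / (2 s2))`, i.e. S is a scale, not a sum of
#' squares). Dominance-variance prior: scaled inverse chi-square with
#' `df_d = 3`, `S_d = 5e-4`. The regularisation parameter `lambda^2` has a
#' Gamma(shape, rate) prior; the weakly-informative default (shape 0.52,
#' rate 1e-4) sits in the usual Park-Casella family and results are
#' insensitive to it within a factor of ten.
#'
#' @param df_e,S_e residual-variance prior.
#' @param df_d,S_d dominance-variance prior.
#' @param lambda2_shape,lambda2_rate gamma prior of `lambda^2`.
#' @return A list of class `gs_hyper`.
#' @export
lasso_hyperparams <- function(df_e = 3.5, S_e = 3, df_d = 3, S_d = 5e-4,
                              lambda2_shape = 0.52, lambda2_rate = 1e-4) {
  vals <- c(df_e, S_e, df_d, S_d, lambda2_shape, lambda2_rate)
  if (any(vals <= 0)) abort("all hyperparameters must be positive")
  structure(list(df_e = df_e, S_e = S_e, df_d = df_d, S_d = S_d,
                 lambda2_shape = lambda2_shape, lambda2_rate = lambda2_rate),
            class = "gs_hyper")
}

#' MCMC settings
#' @param n_iter total Gibbs iterations (default 10000).
#' @param burn_in discarded initial iterations (default 1500).
#' @export
mcmc_config <- function(n_iter = 10000L, burn_in = 1500L) {
  stopifnot(burn_in < n_iter, n_iter > 0, burn_in >= 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in)),
            class = "gs_mcmc")
}

#' Assemble training sets from purebred populations
#'
#' `X` is the reference-allele dosage (0/1/2) at the SNP panel and `Z` the
#' heterozygosity indicator (`Z = 1` exactly when `X = 1`). In `separate`
#' mode each breed yields its own training set; in `common` mode the two
#' breeds are concatenated into one (no breed term: the model has an
#' intercept only).
#'
#' @param pops named list of `gs_pop` training populations (e.g. `A`, `B`).
#' @param phenos named list of phenotype vectors matching `pops`.
#' @param snp_loci integer locus indices of the SNP panel.
#' @param mode `"separate"` or `"common"`.
#' @return A named list of `gs_train` objects (one per breed, or one `"AB"`).
#' @export
build_training_set <- function(pops, phenos, snp_loci,
                               mode = c("separate", "common")) {
  mode <- match.arg(mode)
  stopifnot(identical(names(pops), names(phenos)))
  sets <- lapply(names(pops), function(b) {
    pop <- pops[[b]]
    y <- phenos[[b]]
    if (length(y) != n_ind(pop))
      abort(sprintf("breed %s: %d phenotypes for %d individuals", b,
                    length(y), n_ind(pop)))
    X <- genotypes(pop, snp_loci)
    structure(list(y = y, X = X, Z = (X == 1L) * 1L,
                   breed = rep(b, length(y)),
                   id = paste0(b, ":", pop$id)),
              class = "gs_train")
  })
  names(sets) <- names(pops)
  if (mode == "separate") return(sets)
  comb <- structure(list(
    y = unlist(lapply(sets, `[[`, "y"), use.names = FALSE),
    X = do.call(rbind, lapply(sets, `[[`, "X")),
    Z = do.call(rbind, lapply(sets, `[[`, "Z")),
    breed = unlist(lapply(sets, `[[`, "breed"), use.names = FALSE),
    id = unlist(lapply(sets, `[[`, "id"), use.names = FALSE)),
    class = "gs_train")
  stats::setNames(list(comb), paste(names(pops), collapse = ""))
}

#' Fit the Bayesian LASSO with dominance
#'
#' Single-site Gibbs sampler for
#' `y = mu + X a + Z d + e` with marker-specific shrinkage on the additive
#' effects (`a_j ~ N(0, sigma_e^2 tau_j^2)`, `tau_j^2` exponential,
#' `lambda^2` gamma) and a common normal prior with its own variance on the
#' dominance effects. Posterior summaries are plain means of the post-burn-in
#' draws (no thinning). Zero-variance columns are sampled from their priors.
#'
#' @param train a `gs_train` from [build_training_set()].
#' @param hyper a [lasso_hyperparams()].
#' @param mcmc a [mcmc_config()].
#' @param fix_sigma_e2,fix_sigma_d2,fix_tau2 optionally freeze a variance at
#'   a given value instead of sampling it (used for validation against the
#'   conjugate closed form); `NULL` means sample.
#' @return A `gs_blasso` object; see [tidy.gs_blasso()] and
#'   [glance.gs_blasso()].
#' @export
fit_blasso <- function(train, hyper = lasso_hyperparams(),
                       mcmc = mcmc_config(), fix_sigma_e2 = NULL,
                       fix_sigma_d2 = NULL, fix_tau2 = NULL) {
  stopifnot(inherits(train, "gs_train"))
  n <- length(train$y)
  if (n < 2) abort("need at least 2 training records")
  if (any(!is.finite(train$y))) abort("non-finite phenotypes")
  res <- cpp_blasso(as.numeric(train$y),
                    matrix(as.numeric(train$X), nrow = n),
                    matrix(as.numeric(train$Z), nrow = n),
                    mcmc$n_iter, mcmc$burn_in,
                    hyper$df_e, hyper$S_e, hyper$df_d, hyper$S_d,
                    hyper$lambda2_shape, hyper$lambda2_rate,
                    ifelse(is.null(fix_sigma_e2), -1, fix_sigma_e2),
                    ifelse(is.null(fix_sigma_d2), -1, fix_sigma_d2),
                    ifelse(is.null(fix_tau2), -1, fix_tau2))
  structure(list(
    estimates = tibble(snp = seq_len(ncol(train$X)),
                       a_hat = res$a_hat, d_hat = res$d_hat,
                       a_sd = res$a_sd, d_sd = res$d_sd),
    mu_hat = res$mu_hat, sigma_e2 = res$sigma_e2, sigma_d2 = res$sigma_d2,
    lambda2 = res$lambda2, n = n, m = ncol(train$X),
    breeds = unique(train$breed), mcmc = mcmc, hyper = hyper),
    class = "gs_blasso")
}

#' @export
print.gs_blasso <- function(x, ...) {
  cat(sprintf(
    "<gs_blasso> %d markers, n = %d (breeds %s); posterior means: mu = %.3f, sigma_e2 = %.3f, sigma_d2 = %.2e\n",
    x$m, x$n, paste(x$breeds, collapse = "+"), x$mu_hat, x$sigma_e2,
    x$sigma_d2))
  invisible(x)
}

#' Tidy marker-effect estimates
#' @param x a `gs_blasso`.
#' @param ... unused.
#' @return A tibble with one row per SNP: posterior means and SDs of the
#'   additive and dominance effects.
#' @export
tidy.gs_blasso <- function(x, ...) x$estimates

#' One-row model summary
#' @param x a `gs_blasso`.
#' @param ... unused.
#' @export
glance.gs_blasso <- function(x, ...) {
  tibble(n = x$n, m = x$m, mu_hat = x$mu_hat, sigma_e2 = x$sigma_e2,
         sigma_d2 = x$sigma_d2, lambda2 = x$lambda2,
         n_iter = x$mcmc$n_iter, burn_in = x$mcmc$burn_in)
}
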