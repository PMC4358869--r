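#' Run one full replicate of the study pipeline
#'
#' Simulates the shared base (historical population, breed split, expansion,
#' panel selection, trait architecture scaled at the last historical
#' generation), fits the Bayesian LASSO per training mode, founds the base
#' selection generation once, and runs the requested scenarios on that shared
#' base. Every stage draws its seed from the master seed and a named
#' substream, so scenario comparisons are paired.
#'
#' @param master_seed integer master seed.
#' @param rep_id replicate index (enters the substream labels).
#' @param cfg [sim_config()].
#' @param params [trait_params()].
#' @param hyper [lasso_hyperparams()].
#' @param mcmc [mcmc_config()].
#' @param pcfg [prog_config()].
#' @param scenarios character subset of [scenario_table()]`$scenario`, or
#'   `NULL` to stop after founding the base generation (no MCMC), which is
#'   enough for LD and true-breeding-value summaries.
#' @return A list: `map`, `historical`, `training` (pops A, B), `arch`,
#'   `fits`, `base`, `summaries` (tibble over scenarios), `r_pc` (tibble from
#'   [purebred_crossbred_correlation()] on the base generation), `seeds`.
#' @export
run_replicate <- function(master_seed, rep_id = 1L, cfg = sim_config(),
                          params = trait_params(),
                          hyper = lasso_hyperparams(), mcmc = mcmc_config(),
                          pcfg = prog_config(),
                          scenarios = scenario_table()$scenario) {
  lab <- function(stage) substream_seed(master_seed,
                                        sprintf("rep%d:%s", rep_id, stage))
  seeds <- c(sim = lab("sim"), panels = lab("panels"), trait = lab("trait"),
             pheno = lab("pheno"), base = lab("base"))

  hist_pop <- with_seed(seeds[["sim"]], {
    h <- simulate_historical(cfg)
    breeds <- split_and_diverge(h, cfg)
    list(h = h,
         train = lapply(breeds, function(b) expand_breed(b, cfg)))
  })
  map <- with_seed(seeds[["panels"]], select_panels(hist_pop$h, cfg))
  snp_loci <- panel_loci(map, "snp")
  qtl_loci <- panel_loci(map, "qtl")

  # Effects are anchored at allele frequency one-half: the variance targets
  # are evaluated at p = q = 0.5 rather than at the realized (drifted)
  # frequencies. This keeps the additive/dominance effect-size balance fixed
  # across replicates and yields the expected 10-15% share of overdominant
  # QTL; scaling at realized frequencies would force |d| comparable to |a|
  # for almost half the QTL (see the methods vignette).
  arch <- with_seed(seeds[["trait"]], {
    a0 <- sample_qtl_effects(cfg$n_qtl, params, qtl_loci = qtl_loci)
    scale_effects(a0, rep(0.5, cfg$n_qtl), params)
  })

  training <- hist_pop$train
  train_coh <- with_seed(seeds[["pheno"]],
                         lapply(training, make_cohort, arch = arch,
                                params = params))
  base <- with_seed(seeds[["base"]],
                    found_base(training$A, training$B, arch, params, pcfg,
                               cfg))

  out <- list(map = map, historical = hist_pop$h, training = training,
              training_cohorts = train_coh, arch = arch, base = base,
              r_pc = purebred_crossbred_correlation(base, arch),
              seeds = seeds, fits = NULL, summaries = NULL)
  if (is.null(scenarios) || length(scenarios) == 0) return(out)

  sc <- scenario_table()
  sc <- sc[sc$scenario %in% scenarios, ]
  if (nrow(sc) == 0) abort("no known scenario requested")

  phenos <- lapply(train_coh, `[[`, "y")
  fits <- list()
  if (any(sc$training == "separate")) {
    ts <- build_training_set(training, phenos, snp_loci, "separate")
    fits$A <- with_seed(lab("fit:A"), fit_blasso(ts$A, hyper, mcmc))
    fits$B <- with_seed(lab("fit:B"), fit_blasso(ts$B, hyper, mcmc))
  }
  if (any(sc$training == "common")) {
    tc <- build_training_set(training, phenos, snp_loci, "common")
    fits$AB <- with_seed(lab("fit:AB"), fit_blasso(tc$AB, hyper, mcmc))
  }

  summaries <- vector("list", nrow(sc))
  for (k in seq_len(nrow(sc))) {
    row <- sc[k, ]
    est_a <- if (row$training == "common") fits$AB else fits$A
    est_b <- if (row$training == "common") fits$AB else fits$B
    summaries[[k]] <- with_seed(
      lab(paste0("scenario:", row$scenario)),
      run_scenario(base, arch, est_a, est_b, snp_loci, row$criterion_A,
                   row$criterion_B, params, pcfg, cfg,
                   scenario = row$scenario))
  }
  out$fits <- fits
  out$summaries <- dplyr::bind_rows(summaries)
  out
}

#' Run the study over replicates and aggregate
#'
#' @inheritParams run_replicate
#' @param n_replicates number of replicates.
#' @param scenarios scenarios to run per replicate.
#' @param keep_replicates keep the full per-replicate objects (memory-heavy);
#'   the per-generation summary tibbles are always kept.
#' @return A `gs_study` list: `per_rep` (summaries with `rep` column),
#'   `summary` (means and standard errors `sd/sqrt(n)` by scenario and
#'   generation), `r_pc` (per replicate), `failures`, `manifest`.
#' @export
run_study <- function(n_replicates, master_seed, cfg = sim_config(),
                      params = trait_params(), hyper = lasso_hyperparams(),
                      mcmc = mcmc_config(), pcfg = prog_config(),
                      scenarios = scenario_table()$scenario,
                      keep_replicates = FALSE) {
  per <- list(); rpcs <- list(); fails <- list(); reps <- list()
  for (k in seq_len(n_replicates)) {
    res <- tryCatch(
      run_replicate(master_seed, k, cfg, params, hyper, mcmc, pcfg,
                    scenarios),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- tibble(rep = k,
                                            message = conditionMessage(res))
      next
    }
    if (!is.null(res$summaries))
      per[[length(per) + 1L]] <- dplyr::mutate(res$summaries, rep = k)
    rpcs[[length(rpcs) + 1L]] <- dplyr::mutate(res$r_pc, rep = k)
    if (keep_replicates) reps[[k]] <- res
  }
  per_rep <- dplyr::bind_rows(per)
  summary <- NULL
  if (nrow(per_rep) > 0) {
    summary <- per_rep |>
      dplyr::group_by(.data$scenario, .data$generation) |>
      dplyr::summarise(dplyr::across(
        dplyr::where(is.numeric) & !dplyr::matches("^rep$"),
        list(mean = ~mean(.x, na.rm = TRUE),
             se = ~sd(.x, na.rm = TRUE) / sqrt(sum(!is.na(.x))))),
        .groups = "drop")
  }
  structure(list(
    per_rep = per_rep, summary = summary,
    r_pc = dplyr::bind_rows(rpcs), failures = dplyr::bind_rows(fails),
    replicates = if (keep_replicates) reps,
    manifest = study_manifest(n_replicates, master_seed, cfg, params, hyper,
                              mcmc, pcfg, scenarios)),
    class = "gs_study")
}

study_manifest <- function(n_replicates, master_seed, cfg, params, hyper,
                           mcmc, pcfg, scenarios) {
  list(
    package_version = as.character(utils::packageVersion("crossgs")),
    master_seed = master_seed, n_replicates = n_replicates,
    scenarios = scenarios,
    config = unclass(cfg), trait_params = unclass(params),
    hyperparams = unclass(hyper), mcmc = unclass(mcmc),
    program = unclass(pcfg),
    replicate_seeds = vapply(
      seq_len(n_replicates),
      function(k) substream_seed(master_seed, sprintf("rep%d:sim", k)),
      integer(1))
  )
}

#' Write a study's tables and manifest to a directory
#'
#' TSV tables plus a JSON manifest; rerunning with the same manifest settings
#' reproduces them bit-identically.
#'
#' @param study a `gs_study`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(study$per_rep) && nrow(study$per_rep)) wr(study$per_rep, "per_replicate.tsv")
  if (!is.null(study$summary)) wr(study$summary, "summary.tsv")
  if (nrow(study$r_pc)) wr(study$r_pc, "r_pc.tsv")
  if (nrow(study$failures)) wr(study$failures, "failures.tsv")
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(study$manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}
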