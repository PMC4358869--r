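# Shared fixtures are built in code and memoised across test files so heavy
# simulations run once per session.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Tiny deterministic population: n individuals, explicit haplotypes.
toy_pop <- function(haps, positions = NULL, sex = NULL, breed = "A") {
  n <- ncol(haps) %/% 2L
  if (is.null(sex)) sex <- rep(c("M", "F"), length.out = n)
  pop <- new_population(haps, id = seq_len(n), sex = sex, breed = breed)
  pop$positions <- if (is.null(positions))
    seq(0.1, 0.9, length.out = nrow(haps)) else positions
  pop
}

# A small random-mating population in HWE at given allele frequencies.
hwe_pop <- function(n_ind, p, positions = NULL, breed = "A") {
  n_loci <- length(p)
  haps <- matrix(as.integer(runif(n_loci * 2L * n_ind) < p), nrow = n_loci)
  toy_pop(haps, positions = positions, breed = breed)
}

# Smoke-profile simulation shared by several files.
smoke_sim <- function() {
  cached("smoke_sim", {
    set.seed(402)
    cfg <- sim_config("low", "smoke")
    h <- simulate_historical(cfg)
    breeds <- split_and_diverge(h, cfg)
    training <- lapply(breeds, expand_breed, cfg = cfg)
    map <- select_panels(h, cfg)
    list(cfg = cfg, historical = h, training = training, map = map)
  })
}
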