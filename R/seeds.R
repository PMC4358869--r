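#' Derive a named seed substream from a master seed
#'
#' Every stochastic stage of a study run draws its seed from the master seed
#' and a stage label, so that reruns are bit-identical and paired comparisons
#' between scenarios reuse the same base-population randomness.
#'
#' @param master integer master seed.
#' @param label character stage label, e.g. `"rep3:sim"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- as.double(master) %% 2147483647
  for (k in utf8ToInt(paste0(label, ":"))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
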