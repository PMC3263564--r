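#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages of a pipeline draw their RNG seed from one master
#' seed through this function, keyed by an operation name (and optionally a
#' replicate index). The scheme is a fixed polynomial hash of the key mixed
#' into the master seed modulo 2^31 - 1, so any stage can be re-run in
#' isolation and still reproduce its draws.
#'
#' @param master Integer master seed.
#' @param key Character operation name (e.g. `"genotypes"`, `"outcomes"`).
#' @param index Optional non-negative integer (replicate number).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42L, "outcomes")
#' derive_seed(42L, "outcomes", index = 3)
derive_seed <- function(master, key, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, prime; all arithmetic exact in doubles
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% m
  as.integer((abs(master) + h + index * 7919) %% m)
}

# run expr with a locally-set RNG seed, leaving the caller's RNG untouched
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_glue <- function(...) {
  stop(paste0(...), call. = FALSE)
}
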