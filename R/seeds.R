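#' Derive a stream seed from a master seed
#'
#' All generators in the package draw their randomness from one master seed
#' through this splitting rule, so that an end-to-end run is reproducible and
#' the per-stage streams are decoupled (changing, say, the number of food
#' items does not perturb the microbiome stream). The rule is a fixed-odd-
#' multiplier congruential hash of `(seed, stream)` kept strictly below
#' 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed master seed (single integer).
#' @param stream stream index (non-negative integer) or a known stream name:
#'   one of `"covariates"`, `"fooddb"`, `"recalls"`, `"tree"`,
#'   `"microbiome"`, `"rarefy"`, `"permanova"`, `"procrustes"`, `"rf"`.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' split_seed(42, "recalls")
split_seed <- function(seed, stream = 0L) {
  streams <- c(covariates = 1, fooddb = 2, recalls = 3, tree = 4,
               microbiome = 5, rarefy = 6, permanova = 7, procrustes = 8,
               rf = 9)
  if (is.character(stream)) {
    if (!stream %in% names(streams))
      stop("unknown stream name: ", stream)
    stream <- streams[[stream]]
  }
  m <- 2147483647  # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m) * 48271 %% m
  s <- (s + as.numeric(stream) * 16807) %% m
  as.integer(s)
}
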