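#' Derive a child seed from a root seed
#'
#' Deterministically mixes a root seed with one or more stream indices into a
#' new seed in `[1, 2^31 - 2]`. Every stage of a run (initialisation, each
#' simulated year, each resample) draws from its own child stream, so results
#' are reproducible piecewise: re-running any stage with its derived seed
#' reproduces it exactly, independent of the surrounding stages.
#'
#' @param seed Integer root seed.
#' @param ... Integer stream indices (e.g. replicate number, year).
#' @return A single integer seed.
#' @examples
#' child_seed(1, 3, 7)
#' @export
child_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  stopifnot(length(ks) >= 1L, all(is.finite(ks)))
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- 1
  for (k in ks) {
    h <- (h * 1664525 + (as.numeric(k) %% m) + 1013904223) %% m
    h <- (h * 69069 + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
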