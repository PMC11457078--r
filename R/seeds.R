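#' Derive a child seed from a global seed and a label
#'
#' Experiment drivers expand one global seed into independent per-component
#' seeds (environment generation, each walk, each resampling stage) so that,
#' for example, adding walks to a run does not perturb environment
#' generation. The rule is a splitmix-style integer hash of the seed and a
#' string label, reduced modulo 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param key character label (or integer index) naming the component.
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' child_seed(42, "environment")
#' child_seed(42, "walk:17")
#' @export
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  key <- as.character(key)
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  # one multiplicative mixing round (Knuth constant mod m)
  h <- (h * 48271) %% m
  as.integer(h %% (m - 2) + 1)
}
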