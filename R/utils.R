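#' Derive a per-stage seed from a base seed
#'
#' Pipeline stages draw from independent streams derived from the single
#' user-facing seed by a fixed counter scheme, so adding a stage never
#' shifts the draws of earlier stages.  The result always lies in
#' [0, 2^31 - 2].
#'
#' @param seed integer base seed.
#' @param offset integer stage counter.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + as.numeric(offset) * 16807) %% m)
}
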