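#' Derive a stage-specific random seed from a global seed
#'
#' A single pipeline seed fans out deterministically to per-stage (and
#' per-run) seeds by hashing the stage label into the 31-bit integer range,
#' so any stage can be re-run in isolation and reproduce its in-pipeline
#' behaviour.
#'
#' @param seed integer global seed.
#' @param stage character label, e.g. `"simulate"` or `"be_run_3"`.
#' @return An integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "simulate")
#' derive_seed(1, "be_run_1") != derive_seed(1, "be_run_2")
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1 (Mersenne prime)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  # mix the global seed in with a multiplier small enough that the product
  # stays exactly representable as a double
  h <- (h + (abs(seed) %% m) * 48271) %% m
  as.integer(h)
}
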