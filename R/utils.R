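# Seed handling ---------------------------------------------------------

#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from a single master seed and a stage label, so a run
#' is reproducible end to end while stages stay independent of each other's
#' random-number consumption.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage label (e.g. `"simulate"`, `"holdout"`).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- abs(as.numeric(master_seed)) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# assert helper: stop with a classed condition so callers/tests can match
stop_lipidmoe <- function(message, class) {
  abort(message, class = c(class, "lipidmoe_error"))
}

`%||%` <- rlang::`%||%`
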