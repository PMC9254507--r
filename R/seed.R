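#' Derive a stage seed from a master seed
#'
#' Every randomized stage of the pipeline consumes a seed derived
#' deterministically from the master seed and a stage label, so a single
#' master seed reproduces the full run while stages remain decoupled.
#'
#' @param seed Integer master seed.
#' @param label Character stage label (e.g. `"impute"`, `"split17"`).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# evaluate `code` under a fixed RNG seed, restoring global RNG state after
with_rng <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}
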