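# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators are pure functions of
# (config, seed) without clobbering the session RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a stage seed from a master seed
#'
#' Deterministic, documented derivation so every pipeline stage gets an
#' independent stream: a 31-bit multiplicative string hash of the stage name
#' folded with the master seed. Stable across platforms and versions.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name.
#' @return An integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(as.numeric(master_seed)) %% m
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer(max(1, h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)
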