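# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All randomness in the package flows through
# explicit integer seeds via this helper; nothing touches global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` child seeds from a master seed, each a valid 32-bit R seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_degenerate <- function(msg, case_id = NULL) {
  if (!is.null(case_id)) msg <- sprintf("[case %s] %s", case_id, msg)
  cond <- structure(class = c("collateralq_degenerate", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
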