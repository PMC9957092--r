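# Internal helpers shared across modules.

# Signalled conditions carry a subclass so callers (and derive_all_signatures)
# can distinguish recoverable per-drug failures from real errors.
scdr_abort <- function(msg, class = character()) {
  stop(errorCondition(msg, class = unique(c(class, "scdr_error"))))
}

scdr_usage_abort <- function(msg) {
  scdr_abort(msg, class = "scdr_usage_error")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never perturbs a user's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Collapse a character vector for an error message without flooding it.
oxford_head <- function(x, n = 5L) {
  if (length(x) > n) {
    paste0(paste(x[seq_len(n)], collapse = ", "), ", ... (", length(x), " total)")
  } else {
    paste(x, collapse = ", ")
  }
}
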