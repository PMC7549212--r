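# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the prior
#' RNG state afterwards, so library functions never perturb a user's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
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
  code
}

# Deterministic 31-bit hash of a seed plus arbitrary label tokens; used to
# give every plant / assay / stream its own reproducible substream.
derive_seed <- function(seed, ...) {
  tokens <- vapply(list(...), function(x) paste(format(x), collapse = ","),
                   character(1))
  s <- as.numeric(seed) %% 2147483647
  for (tok in tokens) {
    for (ch in utf8ToInt(tok)) {
      s <- (s * 31 + ch) %% 2147483647
    }
  }
  as.integer(s)
}

# Short deterministic fingerprint of an R object (for run manifests).
config_fingerprint <- function(x) {
  sprintf("%08x", derive_seed(0, paste(deparse(x), collapse = "")))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

# Clamp numeric vector into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
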