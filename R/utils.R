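#' @keywords internal
"_PACKAGE"

## Seed plumbing -------------------------------------------------------------

# Deterministic 31-bit hash of (seed, ...tags); used to derive independent
# RNG streams for peers, epochs, validation splits and per-design runs.
# Stays below 2^31 so the result is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (tag in list(...)) {
    for (ch in utf8ToInt(paste0("|", as.character(tag)))) {
      h <- (h * 131 + ch) %% mod
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Small argument checks -----------------------------------------------------

stopifnot_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single numeric value", name), call. = FALSE)
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop(sprintf("'%s' must be %s %s", name,
                 if (strict) "greater than" else "at least", lower),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
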