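# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards, so package functions that
#' need their own reproducible randomness do not disturb the user's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic small hash of a character string, for deriving per-child
# seeds from a master seed. Plain polynomial rolling hash mod a Mersenne
# prime; stable across platforms and R versions (no serialization involved).
stable_hash <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

# Derive a child-level seed below 2^31 from a master seed and an id string.
derive_seed <- function(master_seed, id, offset = 0L) {
  as.integer((as.numeric(master_seed) * 2654435761 + stable_hash(id) +
                as.numeric(offset) * 97003) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) &&
    (!positive || x > 0)
}

abort_parse <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
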