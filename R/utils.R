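#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded at `seed`,
#' then restores the previous RNG state, so seeded package internals never
#' disturb a caller's random stream. A `NULL` seed evaluates `code` as-is.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed; keeps results < 2^31 and decorrelates
# the package's internal stages without consuming the caller's stream.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ecg <- function(...) stop(sprintf(...), call. = FALSE)
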