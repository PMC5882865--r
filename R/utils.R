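# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded package functions
#' do not disturb the user's random stream. A NULL seed evaluates the
#' expression under the current stream.
#' @noRd
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a dependent seed from a master seed, kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  (abs(as.numeric(seed)) * 7919 + offset) %% 2147483647
}

# Stable identifier for a set of species labels.
group_id <- function(labels) {
  paste(sort(labels), collapse = "+")
}
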