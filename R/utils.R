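# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed` so that library code never leaks
#' RNG state into the caller's session.  All randomness in this package
#' flows through an explicit seed argument and this helper.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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

#' Normalize a read identifier to its pair-shared canonical form
#'
#' Strips any whitespace-delimited comment and a trailing `/1` or `/2`
#' mate suffix, so that both mates of a pair (and their alignment
#' records) share one canonical id.  Read binning and mate rescue match
#' ids across FASTQ and SAM files through this normalization.
#'
#' @param ids character vector of raw read ids.
#' @return character vector of canonical ids.
#' @examples
#' normalize_read_id(c("r1/1", "r1/2", "r2 comment text", "r3"))
#' @export
normalize_read_id <- function(ids) {
  ids <- sub("[ \t].*$", "", ids)
  sub("/[12]$", "", ids)
}

# stop() wrapper for malformed external input; keeps messages uniform.
format_error <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Closed-interval membership, vectorized.
in_range <- function(x, range) {
  x >= range[1] & x <= range[2]
}
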