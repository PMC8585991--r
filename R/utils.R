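# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' then restores the caller's RNG state, so package functions are
#' deterministic without clobbering the user's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
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

# Expand one user-facing seed into independent sub-stream seeds, one per
# named stage, so e.g. the bootstrap does not share a stream with the
# permutation null. Seeds stay below 2^31 - 1.
derive_seeds <- function(seed, stages) {
  subs <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(stages)))
  stats::setNames(as.integer(subs), stages)
}

# Validation that names the offending field, per the generator contract.
check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d (got %s)",
                 field, min, deparse(x)), call. = FALSE)
  }
  as.integer(x)
}

check_scalar <- function(x, field, min = -Inf, max = Inf,
                         min_open = FALSE, max_open = FALSE) {
  ok <- length(x) == 1L && is.finite(x) &&
    (if (min_open) x > min else x >= min) &&
    (if (max_open) x < max else x <= max)
  if (!ok) {
    stop(sprintf("'%s' must be a single finite number in %s%s, %s%s (got %s)",
                 field, if (min_open) "(" else "[", format(min),
                 format(max), if (max_open) ")" else "]", deparse(x)),
         call. = FALSE)
  }
  as.numeric(x)
}

check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("%s contains missing or non-finite values", what),
         call. = FALSE)
  }
  invisible(x)
}
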