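# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded generators never leak global state. `seed = NULL` leaves the RNG
#' untouched.
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Euclidean segment lengths between consecutive rows of an n x 3 matrix.
seg_lengths <- function(xyz) {
  if (nrow(xyz) < 2L) return(numeric(0))
  sqrt(rowSums((xyz[-1L, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
}

# Lateral surface of a tapered cable given per-point diameters (um^2).
# Uses the cylinder-with-mean-diameter rule per point pair, which is additive
# under subdivision of a linearly tapering piece.
frusta_area <- function(xyz, diam) {
  l <- seg_lengths(xyz)
  if (!length(l)) return(0)
  sum(pi * (diam[-1L] + diam[-length(diam)]) / 2 * l)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)
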