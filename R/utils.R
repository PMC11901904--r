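#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same subjects:
#' 1 for identical partitions (up to label permutation), approximately 0 for
#' independent ones. Thin wrapper around [mclust::adjustedRandIndex()].
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in (-1, 1].
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  mclust::adjustedRandIndex(a, b)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness flows through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive a reproducible sub-seed from a parent seed and a stream name, kept
# below 2^31 so it is a valid R integer.
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
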