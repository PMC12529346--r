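# Internal helpers shared across modules.

#' Derive a child seed from a base seed
#'
#' All stochastic stages draw their seeds deterministically from one base
#' seed so that a whole pipeline run is reproducible from a single integer.
#' Results stay below 2^31 - 1 so they are valid R integer seeds.
#'
#' @param base integer base seed.
#' @param offset integer stream offset (stage, k, replicate index, ...).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(base, offset) {
  stopifnot(is.numeric(base), length(base) == 1, is.numeric(offset))
  as.integer((abs(as.numeric(base)) * 48271 + 1000003 * as.numeric(offset)) %% 2147483647)
}

# Evaluate expr under a local RNG state; the caller's .Random.seed is
# restored afterwards so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Row-standardize a matrix so each row has zero mean and unit L2 norm.
# After this transform, tcrossprod(A, B) gives Pearson correlations between
# rows, and 1 - corr equals half the squared Euclidean distance: correlation-
# distance k-means becomes spherical k-means on the standardized rows.
standardize_rows <- function(x, what = "frame") {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  bad <- which(nrm < 1e-12)
  if (length(bad)) {
    stop(sprintf("zero-variance %s(s) (correlation undefined): %s",
                 what, paste(utils::head(bad, 5), collapse = ", ")))
  }
  x / nrm
}

# Stop unless all names are present in a list-like object.
need_fields <- function(x, fields, what) {
  miss <- setdiff(fields, names(x))
  if (length(miss)) stop(sprintf("%s missing field(s): %s", what, paste(miss, collapse = ", ")))
  invisible(x)
}
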