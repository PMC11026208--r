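# Internal helpers shared across modules.

#' Derive a reproducible child seed from a root seed
#'
#' All stochastic stages of the pipeline draw their own seed from the root
#' seed by a fixed integer mix, so that an end-to-end run is a pure function
#' of the root seed while stages stay independently reproducible.
#'
#' @param seed Integer root seed.
#' @param offset Integer stage offset (each stage uses a distinct one).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, offset) {
  # 64-bit-safe multiplicative mix kept below 2^31 (R integers are 32-bit)
  s <- (as.numeric(seed) %% 2147483647) + 1
  o <- (as.numeric(offset) %% 2147483647) + 1
  v <- (s * 48271 + o * 69621) %% 2147483647
  as.integer(v)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so library calls never disturb the
#' caller's RNG stream.
#' @noRd
with_local_seed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Remove the channel mean from each column (sample) of a channels x samples
# matrix, i.e. re-reference each time sample to the common average.
center_samples <- function(x) {
  sweep(x, 2L, colMeans(x), `-`)
}

# Zero-mean and L2-normalise the rows of a matrix (maps, peak topographies).
# Rows with zero variance raise an error unless `allow_zero` is TRUE.
normalize_rows <- function(x, allow_zero = FALSE) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  if (!allow_zero && any(nrm == 0)) {
    stop("zero-variance topography cannot be normalised", call. = FALSE)
  }
  nrm[nrm == 0] <- 1
  x / nrm
}

# Fix the sign of each row so the channel with the largest |loading| is
# positive. Display convention only; all comparisons are polarity-invariant.
fix_map_signs <- function(x) {
  sgn <- vapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  x * sgn
}

`%||%` <- function(a, b) if (is.null(a)) b else a
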