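# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the random number generator seeded to `seed`, restoring the
#' caller's RNG state afterwards. All randomness in the package flows through
#' this helper so that a root seed reproduces every output.
#'
#' @param seed Integer seed (kept below 2^31 - 1).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed derivation from one root seed. Offsets keep the
# substreams (phantom, split, cv, ...) distinct; result stays within 32-bit
# integer range.
derive_seed <- function(seed, stream) {
  offsets <- c(phantom = 11L, subject = 23L, split = 37L, cv = 53L,
               stats = 71L, noise = 89L)
  off <- offsets[[stream]]
  as.integer((as.double(seed) * 1103L + off * 7919L) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0) stopf("'%s' must be > 0", name)
  if (nonneg && x < 0) stopf("'%s' must be >= 0", name)
  invisible(x)
}

# Centered moving average with window shrinking at the profile ends, so the
# smoothed series has the same length and no edge NA.
moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  n <- length(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
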