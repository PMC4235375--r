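#' @keywords internal
"_PACKAGE"

## Deterministic substream seeds: every stochastic stage derives its own seed
## from the master seed and a stage name, so stages can be re-run in isolation.

#' Derive a substream seed from a master seed and a stream name
#'
#' A small multiplicative string hash folded into the master seed, kept below
#' 2^31 so the result is always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param stream character scalar naming the substream (e.g. "fnirs-noise").
#' @return an integer seed.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(stream))
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 2147483629
  as.integer((abs(as.numeric(master)) %% 2147483629 * 31 + h + 1) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a private RNG state
#'
#' Sets the seed, evaluates, and restores the caller's random stream, so
#' seeded library code never disturbs user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_param <- function(...) stop(..., call. = FALSE)

## Smallest 5-smooth FFT length >= n (mixed-radix FFTs at these sizes are
## much faster than padding all the way to the next power of two).
fft_length <- function(n) stats::nextn(n, c(2, 3, 5))

## Centered moving average via cumulative sums (O(n)); edges use shrinking
## windows clipped to the signal.
fast_ma <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  half_l <- (k - 1L) %/% 2L
  half_r <- k - 1L - half_l
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
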