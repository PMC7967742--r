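#' @useDynLib habscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Largest-remainder rounding: integer vector with the same total as round(sum(x)).
# Used wherever fractional class areas must become whole cells without
# gaining or losing any.
largest_remainder_round <- function(x, total = NULL) {
  stopifnot(all(is.finite(x)), all(x >= -1e-9))
  x <- pmax(x, 0)
  if (is.null(total)) total <- as.integer(round(sum(x)))
  fl <- floor(x)
  rem <- as.integer(total - sum(fl))
  if (rem < 0) {
    # total below the floors: remove cells from the largest entries
    ord <- order(fl, decreasing = TRUE)
    k <- -rem
    i <- 1L
    while (k > 0L) {
      j <- ord[((i - 1L) %% length(x)) + 1L]
      if (fl[j] > 0) {
        fl[j] <- fl[j] - 1L
        k <- k - 1L
      }
      i <- i + 1L
    }
    return(as.integer(fl))
  }
  if (rem > 0L) {
    frac <- x - fl
    ord <- order(frac, decreasing = TRUE)
    take <- ord[seq_len(rem)]
    fl[take] <- fl[take] + 1L
  }
  as.integer(fl)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# deterministic per-stage seed derived from one global seed; stays < 2^31
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(stage)) %% 9973L
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
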