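#' Cross-tabulate land-class transitions between two dates
#'
#' @param lu_t0,lu_t1 Aligned [land_use_map()]s (same shape, class table and
#'   nodata mask).
#' @return K x K integer matrix; entry (a, b) counts cells that were class
#'   `a` at t0 and class `b` at t1. The grand total equals the non-nodata
#'   cell count.
#' @export
crosstab_transitions <- function(lu_t0, lu_t1) {
  stopifnot(inherits(lu_t0, "land_use_map"), inherits(lu_t1, "land_use_map"))
  if (!identical(dim(lu_t0$codes), dim(lu_t1$codes)))
    stop("maps must share one shape")
  if (!identical(lu_t0$class_table, lu_t1$class_table))
    stop("maps must share one class table")
  if (!identical(lu_t0$nodata, lu_t1$nodata))
    stop("maps must share one nodata mask")
  k <- lu_t0$class_table$code
  ok <- !lu_t0$nodata
  a <- factor(lu_t0$codes[ok], levels = k)
  b <- factor(lu_t1$codes[ok], levels = k)
  ct <- table(a, b)
  m <- matrix(as.integer(ct), nrow = length(k), dimnames = list(k, k))
  m
}

#' Estimate the transition-probability matrix from a transition cross-tab
#'
#' Rows are normalized by their totals; classes absent at t0 (zero row)
#' receive an identity row so the matrix stays row-stochastic.
#'
#' @param crosstab K x K count matrix from [crosstab_transitions()].
#' @param interval_years Calibration span in years.
#' @return A [transition_matrix()].
#' @export
estimate_transition_matrix <- function(crosstab, interval_years) {
  crosstab <- as.matrix(crosstab)
  rs <- rowSums(crosstab)
  P <- crosstab / ifelse(rs > 0, rs, 1)
  absent <- rs == 0
  if (any(absent)) {
    P[absent, ] <- 0
    diag(P)[absent] <- 1
  }
  classes <- rownames(crosstab) %||% seq_len(nrow(crosstab))
  transition_matrix(P, classes = classes, interval_years = interval_years)
}

# Fractional matrix power via eigendecomposition. Falls back to linear
# interpolation between consecutive integer powers when the eigen branch
# yields entries that are negative or non-real beyond tolerance.
matrix_power <- function(P, n, tol = 1e-9) {
  K <- nrow(P)
  if (n == 0) return(diag(K))
  if (n == round(n)) {
    out <- diag(K)
    base <- P
    k <- as.integer(round(n))
    while (k > 0) {
      if (k %% 2L == 1L) out <- out %*% base
      base <- base %*% base
      k <- k %/% 2L
    }
    return(out)
  }
  e <- eigen(P)
  Pn <- tryCatch({
    lam <- as.complex(e$values)^n
    V <- e$vectors
    Re_part <- V %*% diag(lam, nrow = K) %*% solve(V)
    Re_part
  }, error = function(err) NULL)
  ok <- !is.null(Pn) && max(abs(Im(Pn))) <= tol && min(Re(Pn)) >= -tol
  if (ok) {
    Pn <- Re(Pn)
    Pn[Pn < 0] <- 0
    Pn <- Pn / rowSums(Pn)
    return(Pn)
  }
  warning("fractional matrix power undefined on the eigen branch; ",
          "falling back to linear interpolation between integer powers")
  lo <- floor(n); hi <- ceiling(n); f <- n - lo
  Plo <- matrix_power(P, lo)
  Phi <- matrix_power(P, hi)
  (1 - f) * Plo + f * Phi
}

#' Project class demands forward with the Markov chain
#'
#' Computes `S_t P^n` and rounds to integer cell counts that conserve the
#' landscape total (largest-remainder rule). `n_steps` is expressed in
#' multiples of the calibration interval and may be fractional (e.g. a
#' 13-year horizon over an 8-year calibration span is `13/8` steps),
#' evaluated through a fractional matrix power.
#'
#' @param S_t Named numeric vector of current per-class cell counts (or a
#'   [demand_vector()]).
#' @param P A [transition_matrix()].
#' @param n_steps Number of calibration intervals to project (>= 0, may be
#'   fractional).
#' @return A [demand_vector()] at the horizon.
#' @export
project_state <- function(S_t, P, n_steps = 1) {
  stopifnot(inherits(P, "transition_matrix"), n_steps >= 0)
  if (inherits(S_t, "demand_vector")) S_t <- S_t$counts
  stopifnot(length(S_t) == nrow(P$P), all(S_t >= 0))
  total <- as.integer(round(sum(S_t)))
  Pn <- matrix_power(P$P, n_steps)
  proj <- as.numeric(S_t %*% Pn)
  counts <- largest_remainder_round(proj, total = total)
  demand_vector(counts, P$classes)
}
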