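#' Neighborhood-effect raster for one class
#'
#' For every cell, the fraction of its N x N window (focal cell excluded)
#' occupied by class `p`, scaled by that class's neighborhood weight:
#' `Omega = count_p / (N^2 - 1) * omega_p`. Neighbors outside the raster or
#' in nodata contribute zero while the denominator stays `N^2 - 1`, a
#' documented edge bias.
#'
#' @param lu A [land_use_map()].
#' @param p Class code.
#' @param omega_p Neighborhood weight for class `p` in [0, 1].
#' @param window Odd window size N >= 3 (default 3).
#' @return Numeric matrix in [0, omega_p]; NA at nodata cells.
#' @export
neighborhood_effect <- function(lu, p, omega_p, window = 3L) {
  stopifnot(inherits(lu, "land_use_map"), omega_p >= 0, omega_p <= 1)
  counts <- neighbor_counts(lu$codes == p & !lu$nodata, window)
  out <- counts / (window^2 - 1) * omega_p
  out[lu$nodata] <- NA_real_
  out
}

# Count TRUE neighbors within the (window x window) - 1 ring around each cell
# (center excluded), via shifted additions.
neighbor_counts <- function(ind, window = 3L) {
  if (window %% 2L != 1L || window < 3L) stop("window must be odd and >= 3")
  ind <- ind & !is.na(ind)
  nr <- nrow(ind); nc <- ncol(ind)
  half <- (window - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (di in -half:half) {
    for (dj in -half:half) {
      if (di == 0L && dj == 0L) next
      src_r <- max(1L, 1L - di):min(nr, nr - di)
      src_c <- max(1L, 1L - dj):min(nc, nc - dj)
      out[src_r, src_c] <- out[src_r, src_c] +
        ind[src_r + di, src_c + dj]
    }
  }
  out
}

# All-class neighborhood stack as an n_cell x K matrix (column-major cell
# order), already scaled by the per-class weights.
neighborhood_stack <- function(lu, omega, window = 3L) {
  k <- lu$class_table$code
  ncell <- length(lu$codes)
  out <- matrix(0, ncell, length(k))
  for (j in seq_along(k)) {
    m <- neighbor_counts(lu$codes == k[j] & !lu$nodata, window)
    out[, j] <- as.numeric(m) / (window^2 - 1) * omega[j]
  }
  out
}

#' Self-adaptive inertia update
#'
#' Per class: keep the inertia when the absolute demand gap is not worsening
#' (`|D^(t-1)| <= |D^(t-2)|`); when both gaps are negative and worsening
#' scale by `D^(t-2) / D^(t-1)` (shrinks the coefficient of an
#' over-allocated class); when both are positive and worsening scale by
#' `D^(t-1) / D^(t-2)` (boosts an under-allocated class). The coefficient is
#' clamped to [1e-3, 1e3]. Gaps use the convention D = demand - allocated.
#'
#' @param inertia Per-class inertia coefficients (> 0).
#' @param d_prev1 Per-class gap at iteration t-1.
#' @param d_prev2 Per-class gap at iteration t-2.
#' @return Updated inertia vector.
#' @export
update_inertia <- function(inertia, d_prev1, d_prev2) {
  stopifnot(length(inertia) == length(d_prev1),
            length(inertia) == length(d_prev2), all(inertia > 0))
  out <- inertia
  worsening <- abs(d_prev1) > abs(d_prev2)
  over  <- worsening & d_prev1 < d_prev2 & d_prev2 < 0
  under <- worsening & d_prev1 > d_prev2 & d_prev2 > 0
  out[over]  <- inertia[over]  * d_prev2[over]  / d_prev1[over]
  out[under] <- inertia[under] * d_prev1[under] / d_prev2[under]
  clamp(out, 1e-3, 1e3)
}

#' Combined transition probability
#'
#' Per cell and candidate class: suitability x neighborhood effect x class
#' inertia x (1 - conversion cost), where the cost is 0 for an allowed
#' transition and 1 for a forbidden one, so forbidden transitions score
#' exactly zero. Self-transitions are always allowed and therefore always
#' scored.
#'
#' @param sp A `suitability_stack` from [predict_suitability()].
#' @param omega n_cell x K neighborhood-effect matrix (or a single matrix for
#'   one class as from [neighborhood_effect()]).
#' @param inertia Per-class inertia coefficients.
#' @param allow A [conversion_matrix()].
#' @param lu Current [land_use_map()] supplying each cell's class c.
#' @return n_cell x K score matrix (column-major cell order), NA at nodata.
#' @export
combined_probability <- function(sp, omega, inertia, allow, lu) {
  k <- lu$class_table$code
  K <- length(k)
  spm <- sapply(sp$sp[as.character(k)], as.numeric)
  if (is.matrix(omega) && ncol(omega) != K) omega <- as.numeric(omega)
  if (!is.matrix(omega)) omega <- matrix(omega, nrow = length(lu$codes), ncol = K)
  cur <- match(lu$codes, k)
  allowed <- allow$allow[cbind(rep(cur, K), rep(seq_len(K), each = length(cur)))]
  allowed <- matrix(allowed, ncol = K)
  tp <- spm * omega * matrix(inertia, nrow = nrow(spm), ncol = K, byrow = TRUE) *
    allowed
  tp[lu$nodata, ] <- NA_real_
  tp
}

#' Allocate land use toward a demand by iterative competition
#'
#' Iterates the cellular automaton until every class's allocated cell count
#' is within `tol` of its demand or `max_iter` is reached. Each iteration
#' recomputes the neighborhood effect from the current map, updates the
#' per-class inertia from the last two demand gaps, scores the combined
#' probability, and visits the mutable cells in a seeded random order. A
#' visited cell whose class holds more cells than its demand competes for a
#' new one, drawn by roulette wheel over the positive scores of the classes
#' whose demand is not yet met (`rule = "argmax"` picks the best-scoring
#' class instead); every executed move transfers a cell from a surplus class
#' to a deficit class, so the residual gap is non-increasing across
#' iterations and change spreads from existing patches through the
#' neighborhood term. Frozen cells never change. The run stops early, not
#' converged, if a sweep executes no move (every surplus cell is blocked by
#' the allowances or a zero neighborhood effect).
#'
#' @param sp `suitability_stack` for the landscape.
#' @param lu_t Starting [land_use_map()].
#' @param demand A [demand_vector()] over the mutable cells only (frozen
#'   cells' classes must already be subtracted; see [run_scenario()]).
#' @param weights Per-class neighborhood weights (named or in class order).
#' @param allow A [conversion_matrix()].
#' @param frozen Optional [restricted_mask()] (or logical matrix).
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @param tol Convergence tolerance in cells; default 0.1% of mutable cells.
#' @param max_iter Iteration cap (default 300).
#' @param window Neighborhood window size (odd, default 3).
#' @param rule `"roulette"` (default) or `"argmax"`.
#' @return Object of class `allocation_result`: `landuse`, `iterations`,
#'   `residual_gap` (named per-class |D|), `trajectory` (per-iteration max
#'   residual and per-class gaps), `converged`.
#' @export
run_allocation <- function(sp, lu_t, demand, weights, allow, frozen = NULL,
                           seed = 1L, tol = NULL, max_iter = 300L,
                           window = 3L, rule = c("roulette", "argmax")) {
  rule <- match.arg(rule)
  stopifnot(inherits(lu_t, "land_use_map"), inherits(demand, "demand_vector"),
            inherits(allow, "conversion_matrix"))
  k <- lu_t$class_table$code
  K <- length(k)
  if (inherits(frozen, "restricted_mask")) frozen <- frozen$frozen
  if (is.null(frozen)) frozen <- matrix(FALSE, nrow(lu_t$codes), ncol(lu_t$codes))
  mutable <- !lu_t$nodata & !frozen
  idx_mut <- which(mutable)
  n_mut <- length(idx_mut)
  dem <- as.integer(demand$counts)
  if (sum(dem) != n_mut) {
    stop(sprintf(paste0("infeasible demand: totals %d cells but the landscape ",
                        "has %d mutable cells"), sum(dem), n_mut))
  }
  if (is.null(tol)) tol <- max(1L, as.integer(round(0.001 * n_mut)))

  cur_idx <- match(lu_t$codes, k)
  # feasibility: every demanded class must be reachable under the allowances
  reach <- vapply(seq_len(K), function(p) {
    sum(allow$allow[cur_idx[idx_mut], p] == 1L)
  }, integer(1))
  bad <- which(dem > reach)
  if (length(bad) > 0) {
    stop("infeasible demand under the conversion allowances: ",
         paste(sprintf("class %s needs %d cells but only %d are reachable",
                       k[bad], dem[bad], reach[bad]), collapse = "; "))
  }

  spm <- sapply(sp$sp[as.character(k)], as.numeric)
  spm[is.na(spm)] <- 0
  codes <- lu_t$codes
  codes_idx <- cur_idx
  codes_idx[is.na(codes_idx)] <- 1L   # placeholder at nodata; never visited

  alloc <- tabulate(codes_idx[idx_mut], nbins = K)
  D <- dem - alloc
  best_res <- max(abs(D))
  inertia <- rep(1, K)
  d_hist <- list(D, D)   # t-1, t-2
  traj <- list()
  set.seed(seed)
  it <- 0L
  stalled <- FALSE
  relax <- FALSE
  last_gain <- 0L
  w_ord <- weights_in_order(weights, k)
  while (best_res > tol && it < max_iter && !stalled) {
    it <- it + 1L
    if (it > 2L) inertia <- update_inertia(inertia, d_hist[[1]], d_hist[[2]])
    lu_cur <- lu_t
    lu_cur$codes <- codes
    omega <- neighborhood_stack(lu_cur, w_ord, window)
    visit <- sample(idx_mut)
    u <- stats::runif(n_mut)
    swept <- allocation_sweep(spm, omega, inertia,
                              allow$allow, codes_idx, visit - 1L,
                              D, u, if (rule == "argmax") 1L else 0L,
                              as.integer(relax))
    codes_idx <- swept$codes
    codes[] <- k[codes_idx]
    codes[lu_t$nodata] <- NA_integer_
    new_alloc <- tabulate(codes_idx[idx_mut], nbins = K)
    stopifnot(sum(new_alloc) == n_mut)   # conservation at every iteration
    D <- dem - new_alloc
    stopifnot(identical(as.integer(D), as.integer(swept$gap)))
    new_res <- max(abs(D))
    if (new_res < best_res) last_gain <- it
    best_res <- new_res
    if (swept$moves == 0L) {
      if (relax) stalled <- TRUE          # nothing movable even through chains
      relax <- TRUE                       # open two-step transfer chains
    }
    if (it - last_gain >= 25L) stalled <- TRUE
    d_hist <- list(D, d_hist[[1]])
    traj[[it]] <- c(iter = it, max_gap = best_res, moves = swept$moves,
                    stats::setNames(D, k))
  }
  out_lu <- lu_t
  out_lu$codes <- codes
  final_alloc <- tabulate(codes_idx[idx_mut], nbins = K)
  residual <- stats::setNames(abs(dem - final_alloc), k)
  structure(
    list(landuse = out_lu, iterations = it,
         residual_gap = residual,
         trajectory = do.call(rbind, traj),
         converged = best_res <= tol, tol = tol),
    class = "allocation_result"
  )
}

weights_in_order <- function(weights, k) {
  if (!is.null(names(weights))) {
    nm <- names(weights)
    if (all(as.character(k) %in% nm)) return(as.numeric(weights[as.character(k)]))
    cls <- habscape_classes()
    if (all(cls$name %in% nm)) return(as.numeric(weights[cls$name[match(k, cls$code)]]))
  }
  stopifnot(length(weights) == length(k))
  as.numeric(weights)
}

#' Validate a simulated map against an observed one
#'
#' Overall accuracy is the cellwise agreement fraction; kappa corrects it for
#' the chance agreement implied by the two maps' marginal class shares.
#'
#' @param simulated,observed Aligned [land_use_map()]s.
#' @return List with `overall`, `kappa` (NA when chance agreement is 1) and
#'   the `confusion` matrix.
#' @export
validate_map <- function(simulated, observed) {
  conf <- crosstab_transitions(observed, simulated)
  n <- sum(conf)
  p_o <- sum(diag(conf)) / n
  p_e <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (abs(1 - p_e) < 1e-12) NA_real_ else (p_o - p_e) / (1 - p_e)
  list(overall = p_o, kappa = kappa, confusion = conf)
}
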