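#' Specification of a synthetic landscape
#'
#' Bundles the knobs of the synthetic-input generator: grid shape, cell size
#' (30 m, the resolution of the land-use rasters the pipeline is built for),
#' starting class proportions (delta-plain mix dominated by cultivated land,
#' water and wetland), a known transition matrix driving the t0 -> t1 pair,
#' the driver-field model (15 layers: 3 terrain-like fields, 8 distance
#' surfaces, 2 socioeconomic and 2 climate fields) and the restricted-area
#' fraction.
#'
#' @param shape `c(rows, cols)`.
#' @param cell_size Cell edge in meters.
#' @param seed Integer master seed; every fixture is reproducible from
#'   (spec, seed) alone.
#' @param proportions Named per-class shares at t0 (sum to 1).
#' @param P_true Row-stochastic 8 x 8 transition matrix for one calibration
#'   interval; [default_transition()] when `NULL`.
#' @param smoothing Gaussian smoothing scale (cells) of the random fields.
#' @param n_seed_points Seed-point count of each distance surface.
#' @param restricted_fraction Share of the landscape frozen as the
#'   ecological-redline mask.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(120L, 120L), cell_size = 30, seed = 42L,
                           proportions = c(cultivated = 0.285, garden = 0.005,
                                           forest = 0.027, grassland = 0.007,
                                           construction = 0.157, water = 0.225,
                                           wetland = 0.141, unused = 0.153),
                           P_true = NULL, smoothing = 6, n_seed_points = 5L,
                           restricted_fraction = 0.05) {
  stopifnot(length(shape) == 2L, all(shape >= 1L), cell_size > 0,
            length(proportions) == 8L, abs(sum(proportions) - 1) < 1e-8,
            restricted_fraction >= 0, restricted_fraction < 1)
  if (is.null(P_true)) P_true <- default_transition()
  if (any(abs(rowSums(P_true) - 1) > 1e-9)) stop("P_true must be row-stochastic")
  structure(list(shape = as.integer(shape), cell_size = cell_size,
                 seed = as.integer(seed), proportions = proportions,
                 P_true = P_true, smoothing = smoothing,
                 n_seed_points = as.integer(n_seed_points),
                 restricted_fraction = restricted_fraction),
            class = "synthetic_spec")
}

#' Default calibration-interval transition matrix of the generator
#'
#' Diagonal-dominant, with the conversions that shape a developing delta
#' plain: reclamation of unused land to cultivated land, urban expansion onto
#' cultivated land, and water/wetland exchange.
#'
#' @return 8 x 8 row-stochastic matrix (classes in canonical order).
#' @export
default_transition <- function() {
  k <- habscape_classes()$name
  P <- diag(8) * 0
  dimnames(P) <- list(k, k)
  P["cultivated", ] <- c(0.90, 0, 0.02, 0, 0.06, 0.02, 0, 0)
  P["garden", ]     <- c(0.08, 0.90, 0, 0, 0.02, 0, 0, 0)
  P["forest", ]     <- c(0.05, 0, 0.90, 0, 0.05, 0, 0, 0)
  P["grassland", ]  <- c(0.06, 0, 0, 0.90, 0.04, 0, 0, 0)
  P["construction", ] <- c(0.04, 0, 0, 0, 0.96, 0, 0, 0)
  P["water", ]      <- c(0.04, 0, 0, 0, 0, 0.92, 0.04, 0)
  P["wetland", ]    <- c(0.04, 0, 0, 0, 0, 0.04, 0.92, 0)
  P["unused", ]     <- c(0.10, 0, 0, 0, 0.04, 0, 0, 0.86)
  P
}

#' Spatially autocorrelated random field
#'
#' White noise smoothed by a periodic Gaussian kernel of scale `smoothing`
#' cells, rescaled to [0, 1]. `smoothing = 0` returns the rescaled white
#' noise itself.
#'
#' @param shape `c(rows, cols)`.
#' @param smoothing Gaussian sigma in cells (>= 0).
#' @param seed Integer seed.
#' @return Numeric matrix in [0, 1].
#' @export
random_field <- function(shape, smoothing = 6, seed = 1L) {
  stopifnot(smoothing >= 0)
  set.seed(seed)
  z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  if (smoothing > 0) {
    nr <- shape[1]; nc <- shape[2]
    di <- pmin(seq_len(nr) - 1L, nr - seq_len(nr) + 1L)
    dj <- pmin(seq_len(nc) - 1L, nc - seq_len(nc) + 1L)
    kern <- exp(-outer(di^2, dj^2, "+") / (2 * smoothing^2))
    kern <- kern / sum(kern)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) /
      (nr * nc)
  }
  r <- range(z)
  if (r[2] == r[1]) return(matrix(0.5, shape[1], shape[2]))
  (z - r[1]) / (r[2] - r[1])
}

#' Euclidean-distance surface to random seed points
#'
#' Emulates the distance-to-feature drivers (roads, rivers, towns): per-cell
#' center-to-center Euclidean distance in meters to the nearest of `n_seeds`
#' random cells.
#'
#' @param shape `c(rows, cols)`.
#' @param n_seeds Number of seed cells (>= 1).
#' @param seed Integer seed.
#' @param cell_size Cell edge in meters.
#' @return Numeric matrix of distances (0 at seed cells).
#' @export
distance_surface <- function(shape, n_seeds = 5L, seed = 1L, cell_size = 30) {
  stopifnot(n_seeds >= 1L)
  set.seed(seed)
  cells <- sample.int(prod(shape), n_seeds)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d <- matrix(Inf, shape[1], shape[2])
  for (s in cells) {
    sr <- rows[s]; sc <- cols[s]
    d <- pmin(d, sqrt((rows - sr)^2 + (cols - sc)^2))
  }
  d * cell_size
}

# The 15 synthetic driver layers, named after the real-data categories they
# emulate.
synthetic_drivers <- function(spec) {
  sh <- spec$shape; cs <- spec$cell_size; sm <- spec$smoothing
  sd0 <- spec$seed
  dist_names <- c("dist_builtup", "dist_town", "dist_railway", "dist_highway",
                  "dist_state_road", "dist_provincial_road",
                  "dist_county_road", "dist_river")
  layers <- list(
    elevation = random_field(sh, sm, derive_seed(sd0, "elevation")),
    slope = random_field(sh, sm / 2, derive_seed(sd0, "slope")),
    aspect = random_field(sh, sm / 2, derive_seed(sd0, "aspect"))
  )
  for (i in seq_along(dist_names)) {
    layers[[dist_names[i]]] <- distance_surface(
      sh, spec$n_seed_points, derive_seed(sd0, dist_names[i]), cs)
  }
  layers$population <- random_field(sh, 2 * sm, derive_seed(sd0, "population"))
  layers$gdp <- random_field(sh, 2 * sm, derive_seed(sd0, "gdp"))
  layers$temperature <- random_field(sh, 3 * sm, derive_seed(sd0, "temperature"))
  layers$precipitation <- random_field(sh, 3 * sm, derive_seed(sd0, "precipitation"))
  driver_stack(layers, cell_size = cs)
}

#' Generate a full synthetic input bundle
#'
#' Produces aligned inputs for every pipeline stage: the 15-layer driver
#' stack; a t0 land-use map whose classes are assigned from known monotone
#' scores of the drivers (each class claims its top-scoring cells, so a
#' suitability model can be validated against the generating rule); a t1 map
#' obtained by applying `P_true` to the mutable cells with
#' neighborhood-weighted selection of the converting cells (change arrives in
#' patches, not salt-and-pepper); a threat-subtype raster partitioning
#' construction into urban/rural/transport/mining and unused land into
#' saline-alkali/other; and the redline and permanent-farmland masks.
#' Restricted (redline) cells are identical in t0 and t1.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `drivers`, `lu_t0`, `lu_t1`, `subtype`, `masks` (list of
#'   [restricted_mask()]: `redline`, `farmland`), `P_true`, `spec`.
#' @export
generate_landscape_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cls <- habscape_classes()
  drivers <- synthetic_drivers(spec)
  norm <- normalize_drivers(drivers)
  sh <- spec$shape
  ncell <- prod(sh)

  # class scores: fixed random monotone loadings on the drivers
  set.seed(derive_seed(spec$seed, "class_scores"))
  X <- vapply(norm$layers, as.numeric, numeric(ncell))
  W <- matrix(stats::rnorm(ncol(X) * 8), ncol(X), 8)
  score <- X %*% W
  smoothness <- random_field(sh, spec$smoothing, derive_seed(spec$seed, "tiebreak"))
  score <- score + 0.01 * as.numeric(smoothness)

  # each class claims its top-scoring cells, rarest classes first
  target <- largest_remainder_round(spec$proportions * ncell, total = ncell)
  codes <- integer(ncell)
  unassigned <- rep(TRUE, ncell)
  for (j in order(target)) {
    if (target[j] == 0L) next
    pool <- which(unassigned)
    take <- pool[order(score[pool, j], decreasing = TRUE)[seq_len(min(target[j], length(pool)))]]
    codes[take] <- cls$code[j]
    unassigned[take] <- FALSE
  }
  codes[unassigned] <- cls$code[which.max(target)]
  t0 <- land_use_map(matrix(codes, sh[1], sh[2]), cls, spec$cell_size)

  # restricted masks
  red_field <- random_field(sh, spec$smoothing, derive_seed(spec$seed, "redline"))
  redline <- red_field >= stats::quantile(red_field, 1 - spec$restricted_fraction)
  if (spec$restricted_fraction == 0) redline[] <- FALSE
  farm_field <- random_field(sh, spec$smoothing, derive_seed(spec$seed, "farmland"))
  farmland <- farm_field >= stats::quantile(farm_field, 0.8)

  # t1: apply P_true to the non-redline cells, clustering the conversions
  set.seed(derive_seed(spec$seed, "transition"))
  t1_codes <- codes
  frozen_vec <- as.logical(redline)
  nbr <- lapply(cls$code, function(p)
    as.numeric(neighbor_counts(t0$codes == p, 3L)))
  for (a in seq_len(8)) {
    idx <- which(codes == cls$code[a] & !frozen_vec)
    if (length(idx) == 0L) next
    n_ab <- largest_remainder_round(spec$P_true[a, ] * length(idx),
                                    total = length(idx))
    remaining <- idx
    for (b in setdiff(order(n_ab), a)) {
      if (n_ab[b] == 0L || length(remaining) == 0L) next
      w <- nbr[[b]][remaining] + 0.1
      pick <- if (length(remaining) == 1L) remaining
              else remaining[sample.int(length(remaining), min(n_ab[b], length(remaining)),
                                        prob = w)]
      t1_codes[pick] <- cls$code[b]
      remaining <- setdiff(remaining, pick)
    }
    # the rest stay class a
  }
  t1 <- land_use_map(matrix(t1_codes, sh[1], sh[2]), cls, spec$cell_size)

  # subtype raster on t1: construction and unused partitions
  sub_field <- random_field(sh, spec$smoothing, derive_seed(spec$seed, "subtype"))
  subtype <- matrix(0L, sh[1], sh[2])
  con <- which(t1$codes == cls$code[cls$name == "construction"])
  if (length(con) > 0) {
    qs <- stats::quantile(sub_field[con], c(0.5, 0.7, 0.85))
    subtype[con] <- 1L + findInterval(sub_field[con], qs)  # 1..4
  }
  un <- which(t1$codes == cls$code[cls$name == "unused"])
  if (length(un) > 0) {
    subtype[un] <- ifelse(sub_field[un] <= stats::quantile(sub_field[un], 0.7),
                          5L, 6L)
  }

  list(drivers = drivers, lu_t0 = t0, lu_t1 = t1, subtype = subtype,
       masks = list(redline = restricted_mask(matrix(redline, sh[1], sh[2])),
                    farmland = restricted_mask(matrix(farmland, sh[1], sh[2]))),
       P_true = spec$P_true, spec = spec)
}

#' Oracle fixtures for the habitat-quality equations
#'
#' Returns inputs together with the expected degradation and quality rasters
#' computed by the literal brute-force double sum, so optimized routes can be
#' checked against them.
#'
#' * `no_threat`: all-forest map, no sources; expected quality is the forest
#'   habitat suitability (0.9) everywhere.
#' * `single_threat`: all-forest map with one central construction cell
#'   sourcing the urban threat under the packaged tables.
#' * `worked`: one linear threat of unit weight with maximum distance of two
#'   cells, sensitivity and suitability 1: a cell one cell away from the
#'   single source must have degradation exactly 0.5.
#'
#' @param kind `"no_threat"`, `"single_threat"` or `"worked"`.
#' @param shape `c(rows, cols)` (odd extents center the source cell).
#' @param cell_size Cell edge in meters.
#' @return List with `lu`, `sources`, `threats`, `sens`, `expected_D`,
#'   `expected_Q`.
#' @export
generate_quality_fixture <- function(kind = c("no_threat", "single_threat", "worked"),
                                     shape = c(9L, 9L), cell_size = 30) {
  kind <- match.arg(kind)
  cls <- habscape_classes()
  params <- read_parameter_tables()
  forest <- cls$code[cls$name == "forest"]
  constr <- cls$code[cls$name == "construction"]
  codes <- matrix(forest, shape[1], shape[2])
  if (kind == "no_threat") {
    lu <- land_use_map(codes, cls, cell_size)
    threats <- params$threats
    sens <- params$sensitivity
    sources <- derive_threat_sources(lu, threats = threats)
  } else {
    ctr <- c((shape[1] + 1L) %/% 2L, (shape[2] + 1L) %/% 2L)
    codes[ctr[1], ctr[2]] <- constr
    lu <- land_use_map(codes, cls, cell_size)
    if (kind == "single_threat") {
      threats <- params$threats
      sens <- params$sensitivity
      sources <- derive_threat_sources(lu, threats = threats)
    } else {
      threats <- data.frame(threat = "urban", max_distance_km = 2 * cell_size / 1000,
                            weight = 1, decay = "linear",
                            stringsAsFactors = FALSE)
      S <- matrix(1, 8, 1, dimnames = list(cls$name, "urban"))
      S["construction", ] <- 0
      H <- stats::setNames(rep(1, 8), cls$name)
      H["construction"] <- 0
      sens <- list(H = H, S = S)
      sources <- derive_threat_sources(lu, threats = threats,
                                       mapping = c(urban = "class:construction"))
    }
  }
  D <- degradation_index(sources, threats, sens, lu, method = "brute")
  Q <- quality_map(D, lu, sens$H)
  list(lu = lu, sources = sources, threats = threats, sens = sens,
       expected_D = D, expected_Q = Q)
}
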