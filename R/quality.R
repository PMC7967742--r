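#' Default land-class to threat mapping
#'
#' The threat catalogue (urban, rural residential, transportation, mining,
#' cultivated, saline-alkali) is finer than the 8 land classes. Without a
#' subtype raster, construction sources the urban threat, cultivated land the
#' cultivated threat and unused land the saline-alkali threat; the rural,
#' transportation and mining threats have no sources. With a subtype raster
#' (codes 1 = urban, 2 = rural, 3 = transport, 4 = mining, 5 = saline-alkali,
#' 6 = other unused, 0/NA = none) the four construction subtypes and the
#' saline part of unused land are resolved explicitly.
#'
#' @param with_subtype Whether a subtype raster will be supplied.
#' @return Named character vector: threat name -> source rule.
#' @export
default_threat_mapping <- function(with_subtype = FALSE) {
  if (with_subtype) {
    c(urban = "subtype:1", rural = "subtype:2", transport = "subtype:3",
      mining = "subtype:4", cultivated = "class:cultivated",
      saline = "subtype:5")
  } else {
    c(urban = "class:construction", rural = "none", transport = "none",
      mining = "none", cultivated = "class:cultivated",
      saline = "class:unused")
  }
}

#' Derive per-threat source rasters from a land-use map
#'
#' @param lu A [land_use_map()].
#' @param subtype Optional integer raster resolving construction into
#'   urban/rural/transport/mining and unused land into saline-alkali/other
#'   (see [default_threat_mapping()] for the codes).
#' @param threats Threat table (see [read_parameter_tables()]).
#' @param mapping Named rules threat -> one of `"class:<name>"`,
#'   `"subtype:<code>"`, `"none"`; defaults per [default_threat_mapping()].
#' @return Named list of logical matrices (TRUE = source cell), one per
#'   threat.
#' @export
derive_threat_sources <- function(lu, subtype = NULL,
                                  threats = read_parameter_tables()$threats,
                                  mapping = NULL) {
  stopifnot(inherits(lu, "land_use_map"))
  if (is.null(mapping)) mapping <- default_threat_mapping(!is.null(subtype))
  missing <- setdiff(threats$threat, names(mapping))
  if (length(missing) > 0)
    stop("no mapping rule for threat(s): ", paste(missing, collapse = ", "))
  cls <- lu$class_table
  out <- lapply(threats$threat, function(tr) {
    rule <- mapping[[tr]]
    src <- if (rule == "none") {
      matrix(FALSE, nrow(lu$codes), ncol(lu$codes))
    } else if (startsWith(rule, "class:")) {
      nm <- sub("^class:", "", rule)
      code <- cls$code[cls$name == nm]
      if (length(code) != 1L) stop("unknown class in mapping rule: ", rule)
      lu$codes == code & !lu$nodata
    } else if (startsWith(rule, "subtype:")) {
      if (is.null(subtype)) stop("mapping rule ", rule, " needs a subtype raster")
      code <- as.integer(sub("^subtype:", "", rule))
      !is.na(subtype) & subtype == code & !lu$nodata
    } else stop("unknown mapping rule: ", rule)
    src[is.na(src)] <- FALSE
    src
  })
  names(out) <- threats$threat
  out
}

#' Distance-decayed threat influence
#'
#' Linear decay falls as `1 - d/d_max` and reaches 0 at the maximum
#' effective distance; exponential decay falls as `exp(-2.99 d / d_max)`
#' (about 0.0503 at `d_max`) and is truncated to 0 beyond it.
#'
#' @param d_m Distance(s) in meters, >= 0.
#' @param d_max_km Maximum effective distance in kilometers.
#' @param decay `"linear"` or `"exponential"`.
#' @return Influence value(s) in [0, 1].
#' @export
decay_influence <- function(d_m, d_max_km, decay = c("linear", "exponential")) {
  decay <- match.arg(decay)
  if (any(d_m < 0)) stop("distance must be non-negative")
  d_max <- d_max_km * 1000
  if (decay == "linear") {
    pmax(0, 1 - d_m / d_max)
  } else {
    ifelse(d_m <= d_max, exp(-2.99 * d_m / d_max), 0)
  }
}

# Finite convolution kernel for one threat: influence at every integer cell
# offset within the maximum effective distance (center-to-center metric
# distances).
threat_kernel <- function(d_max_km, decay, cell_size) {
  r <- floor(d_max_km * 1000 / cell_size)
  off <- -r:r
  d <- cell_size * sqrt(outer(off^2, off^2, "+"))
  k <- matrix(decay_influence(as.numeric(d), d_max_km, decay), nrow = length(off))
  k
}

# 2-D "same" convolution by zero-padded FFT; kern has odd dimensions.
conv2_same <- function(a, kern) {
  nr <- nrow(a); nc <- ncol(a)
  kr <- nrow(kern); kc <- ncol(kern)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  A <- matrix(0, pr, pc); A[1:nr, 1:nc] <- a
  K <- matrix(0, pr, pc); K[1:kr, 1:kc] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  hr <- (kr - 1L) %/% 2L; hc <- (kc - 1L) %/% 2L
  full[(hr + 1L):(hr + nr), (hc + 1L):(hc + nc)]
}

#' Habitat-degradation index
#'
#' For each cell x of class j, sums the influence of every source cell of
#' every threat r: `D_xj = sum_r sum_y (w_r / sum_w) i_r(d_xy) beta_x S_jr`,
#' with the influence given by the threat's decay law and truncated at its
#' maximum effective distance. Weights are normalized over the full threat
#' catalogue. The default computation convolves each threat's source raster
#' with a finite decay kernel via FFT; `method = "brute"` evaluates the
#' literal double sum and is the reference implementation.
#'
#' @param sources Named list of logical source rasters from
#'   [derive_threat_sources()].
#' @param threats Threat table with `threat`, `max_distance_km`, `weight`,
#'   `decay`.
#' @param sens Sensitivity list with `S` (class x threat matrix) from
#'   [read_parameter_tables()].
#' @param lu A [land_use_map()] (supplies each cell's class and cell size).
#' @param beta Optional accessibility raster in [0, 1]; default 1 everywhere
#'   (the accessibility factor multiplies degradation as printed in the
#'   model, so smaller values shelter a cell).
#' @param method `"fft"` (default) or `"brute"`.
#' @param normalize_kernels If TRUE, each threat's decay kernel is divided by
#'   its own total weight, turning the exposure into a decay-weighted mean of
#'   source presence in [0, 1] instead of the literal sum over sources. The
#'   default FALSE follows the printed model; the normalized variant keeps
#'   the index from saturating on landscapes whose source patches are much
#'   larger than one cell.
#' @return Object of class `degradation_map` with `values` (>= 0, NA at
#'   nodata) and `cell_size`.
#' @export
degradation_index <- function(sources, threats, sens, lu, beta = NULL,
                              method = c("fft", "brute"),
                              normalize_kernels = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(lu, "land_use_map"))
  wsum <- sum(threats$weight)
  if (wsum <= 0) stop("threat weights sum to zero")
  if (is.null(beta)) beta <- matrix(1, nrow(lu$codes), ncol(lu$codes))
  beta <- as.matrix(beta)
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta must lie in [0,1]")
  S <- sens$S
  cls <- lu$class_table
  cur <- match(lu$codes, cls$code)
  D <- matrix(0, nrow(lu$codes), ncol(lu$codes))
  for (i in seq_len(nrow(threats))) {
    tr <- threats$threat[i]
    src <- sources[[tr]]
    if (is.null(src)) stop("no source raster for threat ", tr)
    if (!any(src)) next
    kern <- threat_kernel(threats$max_distance_km[i], threats$decay[i],
                          lu$cell_size)
    expo <- if (method == "fft") {
      conv2_same(src * 1, kern)
    } else {
      brute_exposure(src, threats$max_distance_km[i], threats$decay[i],
                     lu$cell_size)
    }
    expo[expo < 0] <- 0   # FFT round-off guard
    if (normalize_kernels) expo <- expo / sum(kern)
    sj <- matrix(S[cbind(cur, match(tr, colnames(S)))], nrow(D), ncol(D))
    D <- D + (threats$weight[i] / wsum) * expo * sj
  }
  D <- D * beta
  D[lu$nodata] <- NA_real_
  structure(list(values = D, cell_size = lu$cell_size, nodata = lu$nodata),
            class = "degradation_map")
}

# Literal double sum over source cells; the independent reference route.
brute_exposure <- function(src, d_max_km, decay, cell_size) {
  nr <- nrow(src); nc <- ncol(src)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  out <- matrix(0, nr, nc)
  for (s in which(src)) {
    sr <- rows[s]; sc <- cols[s]
    d <- cell_size * sqrt((rows - sr)^2 + (cols - sc)^2)
    out <- out + decay_influence(d, d_max_km, decay)
  }
  out
}

#' Habitat quality from degradation
#'
#' `Q_xj = H_j (1 - D^z / (D^z + k^z))` with scale constant `z = 2.5` and
#' half-saturation constant `k = 0.5`: quality equals the class's habitat
#' suitability where degradation is zero and loses half its maximum loss
#' where `D = k`.
#'
#' @param D A [degradation_index()] result (or numeric matrix >= 0).
#' @param lu A [land_use_map()].
#' @param H Named per-class habitat-suitability vector in [0, 1] (names are
#'   class names).
#' @param z Scale constant (default 2.5).
#' @param k Half-saturation constant (default 0.5).
#' @return Object of class `quality_map` with `values` in [0, 1].
#' @export
quality_map <- function(D, lu, H, z = 2.5, k = 0.5) {
  if (inherits(D, "degradation_map")) D <- D$values
  stopifnot(inherits(lu, "land_use_map"), all(D >= 0, na.rm = TRUE))
  cls <- lu$class_table
  if (is.null(names(H))) names(H) <- cls$name
  hj <- matrix(H[cls$name[match(lu$codes, cls$code)]],
               nrow(lu$codes), ncol(lu$codes))
  Dz <- D^z
  Q <- hj * (1 - Dz / (Dz + k^z))
  zero <- !is.na(D) & D == 0
  Q[zero] <- hj[zero]  # exact limit even when k = 0
  Q[lu$nodata] <- NA_real_
  structure(list(values = Q, cell_size = lu$cell_size, nodata = lu$nodata,
                 z = z, k = k),
            class = "quality_map")
}

#' Grade a quality map and tabulate grade areas
#'
#' Lower-inclusive bins over the default edges (0.1, 0.4, 0.6, 0.7) give the
#' five grades Lower [0, 0.1), Low [0.1, 0.4), Middle [0.4, 0.6),
#' High [0.6, 0.7) and Higher [0.7, 1].
#'
#' @param Q A [quality_map()] (or numeric matrix in [0, 1]).
#' @param edges Strictly increasing interior bin edges (default
#'   `c(0.1, 0.4, 0.6, 0.7)`).
#' @return List with `grades` (integer raster 1..5), `labels`, and `table`
#'   (data.frame of per-grade cell counts and percentages summing to 100).
#' @export
classify_grades <- function(Q, edges = c(0.1, 0.4, 0.6, 0.7)) {
  if (inherits(Q, "quality_map")) Q <- Q$values
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  labels <- if (length(edges) == 4) c("Lower", "Low", "Middle", "High", "Higher")
            else paste0("G", seq_len(length(edges) + 1L))
  g <- matrix(findInterval(Q, edges) + 1L, nrow(Q), ncol(Q))
  g[is.na(Q)] <- NA_integer_
  counts <- tabulate(g[!is.na(g)], nbins = length(labels))
  tab <- data.frame(grade = labels, cells = counts,
                    percent = 100 * counts / sum(counts))
  list(grades = g, labels = labels, table = tab)
}

#' Summary statistics of a quality map
#'
#' @param Q A [quality_map()] (or numeric matrix).
#' @param edges Grade edges passed to [classify_grades()].
#' @return List with `mean`, `sd` (population standard deviation) and
#'   `grades` (percentage table), all over non-nodata cells.
#' @export
summarize_quality <- function(Q, edges = c(0.1, 0.4, 0.6, 0.7)) {
  vals <- if (inherits(Q, "quality_map")) Q$values else Q
  v <- vals[!is.na(vals)]
  if (length(v) == 0L) stop("empty quality raster")
  list(mean = mean(v),
       sd = sqrt(mean((v - mean(v))^2)),
       grades = classify_grades(Q, edges)$table)
}

#' One-call habitat quality for a land-use map
#'
#' Derives threat sources, computes the degradation index and scores habitat
#' quality with the packaged threat and sensitivity tables (or user
#' overrides).
#'
#' @inheritParams derive_threat_sources
#' @inheritParams degradation_index
#' @param params Parameter bundle from [read_parameter_tables()].
#' @return List with `D` ([degradation_index()]) and `Q` ([quality_map()]).
#' @export
habitat_quality <- function(lu, subtype = NULL, beta = NULL,
                            params = read_parameter_tables(),
                            method = "fft") {
  sources <- derive_threat_sources(lu, subtype = subtype,
                                   threats = params$threats)
  D <- degradation_index(sources, params$threats, params$sensitivity, lu,
                         beta = beta, method = method)
  Q <- quality_map(D, lu, params$sensitivity$H)
  list(D = D, Q = Q)
}
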