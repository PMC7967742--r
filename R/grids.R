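#' The eight land-use classes
#'
#' Canonical class table for the coastal-delta landscapes the package models:
#' cultivated, garden, forest, grassland, construction, water body, wetland
#' and unused (saline-alkali) land, coded 1 to 8.
#'
#' @return A data.frame with columns `code` (integer) and `name` (character).
#' @export
habscape_classes <- function() {
  data.frame(
    code = 1:8,
    name = c("cultivated", "garden", "forest", "grassland",
             "construction", "water", "wetland", "unused"),
    stringsAsFactors = FALSE
  )
}

#' Categorical land-use raster
#'
#' @param codes Integer matrix of class codes; `NA` marks nodata cells.
#' @param class_table data.frame with `code` and `name` columns; every
#'   non-nodata code must appear in it.
#' @param cell_size Cell edge length in meters (> 0).
#' @return An object of class `land_use_map` with fields `codes`,
#'   `class_table`, `cell_size` and `nodata` (logical matrix, TRUE = nodata).
#' @export
land_use_map <- function(codes, class_table = habscape_classes(), cell_size = 30) {
  codes <- as.matrix(codes)
  if (nrow(codes) < 1L || ncol(codes) < 1L) stop("raster must be at least 1x1")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive scalar")
  vals <- codes[!is.na(codes)]
  if (any(vals != round(vals))) stop("land-use codes must be integers")
  unknown <- setdiff(unique(vals), class_table$code)
  if (length(unknown) > 0)
    stop("unknown class code: ", paste(unknown, collapse = ", "))
  storage.mode(codes) <- "integer"
  structure(
    list(codes = codes, class_table = class_table,
         cell_size = as.numeric(cell_size), nodata = is.na(codes)),
    class = "land_use_map"
  )
}

#' @export
print.land_use_map <- function(x, ...) {
  cat(sprintf("<land_use_map> %d x %d cells, %g m, %d classes, %d nodata\n",
              nrow(x$codes), ncol(x$codes), x$cell_size,
              nrow(x$class_table), sum(x$nodata)))
  tab <- class_counts(x)
  print(stats::setNames(tab, x$class_table$name))
  invisible(x)
}

#' Per-class cell counts of a land-use map
#'
#' @param lu A [land_use_map()].
#' @return Named integer vector over all classes in the class table
#'   (zero for absent classes), nodata excluded.
#' @export
class_counts <- function(lu) {
  stopifnot(inherits(lu, "land_use_map"))
  k <- lu$class_table$code
  tab <- tabulate(match(lu$codes[!lu$nodata], k), nbins = length(k))
  stats::setNames(as.integer(tab), as.character(k))
}

#' Stack of continuous driver rasters
#'
#' @param layers Named list of numeric matrices, all the same shape.
#' @param cell_size Cell edge length in meters.
#' @return Object of class `driver_stack` with fields `layers`, `cell_size`,
#'   `nodata` (shared mask) and `bounds` (per-layer min/max recorded by
#'   [normalize_drivers()], `NULL` until then).
#' @export
driver_stack <- function(layers, cell_size = 30) {
  stopifnot(is.list(layers), length(layers) >= 1L, !is.null(names(layers)),
            all(nzchar(names(layers))))
  layers <- lapply(layers, as.matrix)
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all driver layers must share one shape")
  masks <- vapply(layers, function(m) is.na(m), FUN.VALUE = is.na(layers[[1]]))
  nodata <- is.na(layers[[1]])
  for (m in layers) {
    if (!identical(is.na(m), nodata))
      stop("all driver layers must share one nodata mask")
  }
  structure(
    list(layers = layers, cell_size = as.numeric(cell_size),
         nodata = nodata, bounds = NULL),
    class = "driver_stack"
  )
}

#' Min-max normalize a driver stack to [0, 1]
#'
#' Records the per-layer bounds so that prediction-time inputs can be scaled
#' identically (values outside the stored bounds are clamped with a warning
#' at prediction time).
#'
#' @param drivers A [driver_stack()].
#' @return The stack with every layer rescaled to [0, 1] and `bounds` filled.
#' @export
normalize_drivers <- function(drivers) {
  stopifnot(inherits(drivers, "driver_stack"))
  bounds <- lapply(drivers$layers, function(m) {
    r <- range(m, na.rm = TRUE)
    if (!all(is.finite(r))) stop("non-finite driver values")
    r
  })
  drivers$layers <- mapply(function(m, b) {
    span <- b[2] - b[1]
    if (span == 0) m[] <- 0 else m <- (m - b[1]) / span
    m
  }, drivers$layers, bounds, SIMPLIFY = FALSE)
  drivers$bounds <- bounds
  drivers
}

#' Land-class transition-probability matrix
#'
#' @param P Row-stochastic K x K matrix of transition probabilities.
#' @param classes Ordered class codes labelling rows/columns.
#' @param interval_years Calibration span in years.
#' @return Object of class `transition_matrix`.
#' @export
transition_matrix <- function(P, classes, interval_years) {
  P <- as.matrix(P)
  stopifnot(nrow(P) == ncol(P), length(classes) == nrow(P), interval_years > 0)
  if (any(P < -1e-12) || any(P > 1 + 1e-12)) stop("entries must lie in [0,1]")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-9)) stop("every row must sum to 1")
  dimnames(P) <- list(classes, classes)
  structure(list(P = P, classes = classes, interval_years = interval_years),
            class = "transition_matrix")
}

#' Per-class demand (target cell counts)
#'
#' @param counts Non-negative integer cell counts per class.
#' @param classes Ordered class codes.
#' @return Object of class `demand_vector`.
#' @export
demand_vector <- function(counts, classes) {
  stopifnot(length(counts) == length(classes), all(counts >= 0),
            all(counts == round(counts)))
  structure(list(counts = stats::setNames(as.integer(counts), as.character(classes)),
                 classes = classes),
            class = "demand_vector")
}

#' Binary conversion-allowance matrix
#'
#' `allow[c, p] = 1` when class `c` may convert to class `p` in a scenario;
#' the diagonal is forced to 1 (a class may always remain itself).
#'
#' @param allow K x K matrix of 0/1 entries.
#' @param classes Ordered class codes.
#' @return Object of class `conversion_matrix`.
#' @export
conversion_matrix <- function(allow, classes = habscape_classes()$code) {
  allow <- as.matrix(allow)
  stopifnot(nrow(allow) == ncol(allow), nrow(allow) == length(classes))
  if (!all(allow %in% c(0, 1))) stop("allowance entries must be 0 or 1")
  if (any(diag(allow) != 1)) stop("diagonal must be 1: a class may remain itself")
  storage.mode(allow) <- "integer"
  dimnames(allow) <- list(classes, classes)
  structure(list(allow = allow, classes = classes), class = "conversion_matrix")
}

#' Restricted-area mask
#'
#' @param frozen Logical matrix; TRUE cells may not change class during
#'   allocation.
#' @return Object of class `restricted_mask`.
#' @export
restricted_mask <- function(frozen) {
  frozen <- as.matrix(frozen)
  storage.mode(frozen) <- "logical"
  frozen[is.na(frozen)] <- FALSE
  structure(list(frozen = frozen), class = "restricted_mask")
}

# ---- ESRI ASCII grid I/O ------------------------------------------------

#' Write a raster to an ESRI ASCII grid
#'
#' Integer rasters round-trip bit-faithfully; continuous rasters are written
#' with 15 significant digits. Nodata cells are written as the `NODATA_value`.
#'
#' @param grid A numeric/integer matrix (NA = nodata), a [land_use_map()], or
#'   any habscape raster object with a `$values`/`$codes` matrix field.
#' @param path Output file path.
#' @param cell_size Cell size in meters; taken from the object when present.
#' @param nodata_value Sentinel written for nodata cells.
#' @return The path, invisibly.
#' @export
write_raster <- function(grid, path, cell_size = NULL, nodata_value = -9999) {
  if (inherits(grid, "land_use_map")) {
    m <- grid$codes; cell_size <- cell_size %||% grid$cell_size
  } else if (is.list(grid) && !is.null(grid$values)) {
    m <- grid$values; cell_size <- cell_size %||% grid$cell_size
  } else {
    m <- as.matrix(grid)
  }
  cell_size <- cell_size %||% 30
  is_int <- is.integer(m) || all(m[!is.na(m)] == round(m[!is.na(m)]))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write raster to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.10g", cell_size),
    sprintf("NODATA_value %.10g", nodata_value)
  ), con)
  out <- m
  out[is.na(out)] <- nodata_value
  fmt <- if (is_int) "%d" else "%.15g"
  for (i in seq_len(nrow(out))) {
    row <- if (is_int) sprintf(fmt, as.integer(out[i, ])) else sprintf(fmt, out[i, ])
    writeLines(paste(row, collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return A list with `values` (matrix, NA at nodata), `cell_size`, `nrows`,
#'   `ncols`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing ", paste(setdiff(need, names(hdr)),
                                                   collapse = ", "), "): ", path)
  nodata <- hdr[["nodata_value"]] %||% -9999
  body <- paste(lines[i:length(lines)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  list(values = m, cell_size = hdr$cellsize, nrows = nr, ncols = nc)
}

#' Read a categorical land-use raster
#'
#' @param path ESRI ASCII grid of integer class codes.
#' @param class_table Class table validating the codes.
#' @return A [land_use_map()].
#' @export
read_landuse <- function(path, class_table = habscape_classes()) {
  g <- read_raster(path)
  vals <- g$values[!is.na(g$values)]
  if (any(vals != round(vals))) stop("land-use raster must hold integer codes")
  land_use_map(g$values, class_table = class_table, cell_size = g$cell_size)
}
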