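#' Read the packaged (or user-supplied) parameter tables
#'
#' Loads the demand areas, neighborhood weights, conversion allowances,
#' threat specifications and habitat-sensitivity table. With `dir = NULL`
#' the copies shipped with the package are used. User overrides must carry
#' the same headers and are validated against the type invariants.
#'
#' @param dir Directory holding `demand_areas.csv`,
#'   `neighborhood_weights.csv`, `conversion_s1s2.csv`, `conversion_s3s4.csv`,
#'   `threats.csv` and `sensitivity.csv`; `NULL` for the packaged defaults.
#' @return A list with elements `demand_areas` (data.frame, hm^2 per class per
#'   scenario), `weights` (data.frame per scenario), `conversion` (named list
#'   of [conversion_matrix()]), `threats` (data.frame), `sensitivity` (list
#'   with `H` named habitat-suitability vector and `S` class x threat matrix).
#' @export
read_parameter_tables <- function(dir = NULL) {
  pth <- function(f) {
    if (is.null(dir)) system.file("extdata", f, package = "habscape")
    else file.path(dir, f)
  }
  classes <- habscape_classes()
  cn <- classes$name

  demand <- utils::read.csv(pth("demand_areas.csv"), check.names = FALSE)
  if (!identical(names(demand), c("scenario", cn)))
    stop("demand_areas.csv: header must be scenario,", paste(cn, collapse = ","))
  if (any(demand[cn] < 0)) stop("demand_areas.csv: negative area")

  weights <- utils::read.csv(pth("neighborhood_weights.csv"), check.names = FALSE)
  if (!identical(names(weights), c("scenario", cn)))
    stop("neighborhood_weights.csv: header mismatch")
  wvals <- as.matrix(weights[cn])
  if (any(wvals < 0 | wvals > 1)) {
    bad <- which(wvals < 0 | wvals > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("neighborhood weight out of [0,1] at scenario %s, class %s",
                 weights$scenario[bad[1]], cn[bad[2]]))
  }

  conv <- lapply(c(s1s2 = "conversion_s1s2.csv", s3s4 = "conversion_s3s4.csv"),
                 function(f) {
    tab <- utils::read.csv(pth(f), check.names = FALSE)
    if (!identical(names(tab), c("from", cn)) || !identical(tab$from, cn))
      stop(f, ": rows/columns must list the 8 classes in canonical order")
    conversion_matrix(as.matrix(tab[cn]), classes = classes$code)
  })

  threats <- utils::read.csv(pth("threats.csv"), stringsAsFactors = FALSE)
  need <- c("threat", "max_distance_km", "weight", "decay")
  if (!identical(names(threats), need)) stop("threats.csv: header mismatch")
  if (any(threats$max_distance_km <= 0)) stop("threats.csv: max distance must be > 0")
  if (any(threats$weight < 0 | threats$weight > 1))
    stop("threats.csv: weight out of [0,1]")
  if (!all(threats$decay %in% c("linear", "exponential")))
    stop("threats.csv: decay must be linear or exponential")

  sens <- utils::read.csv(pth("sensitivity.csv"), check.names = FALSE)
  if (!identical(sens$class, cn))
    stop("sensitivity.csv: class column must list the 8 classes in order")
  if (!all(threats$threat %in% names(sens)))
    stop("sensitivity.csv: missing threat column(s): ",
         paste(setdiff(threats$threat, names(sens)), collapse = ", "))
  H <- stats::setNames(sens$habitat, cn)
  S <- as.matrix(sens[, threats$threat, drop = FALSE])
  rownames(S) <- cn
  vals <- c(H, S)
  if (any(vals < 0 | vals > 1)) {
    stop("sensitivity.csv: value out of [0,1] (first offender: ",
         signif(vals[which(vals < 0 | vals > 1)[1]], 3), ")")
  }
  if (H["construction"] != 0)
    stop("sensitivity.csv: construction habitat suitability must be 0")

  list(demand_areas = demand, weights = weights, conversion = conv,
       threats = threats, sensitivity = list(H = H, S = S))
}

#' Convert areas in hectares to whole-cell demands
#'
#' Internally all demands are integer cell counts. Areas are converted with
#' `cells = area_hm2 * 10000 / cell_size^2`; when `total_cells` is given the
#' converted vector is rescaled proportionally so the counts sum exactly to
#' the landscape total, with the rounding residue resolved by the
#' largest-remainder rule.
#'
#' @param areas_hm2 Named numeric vector of areas (hm^2) per class.
#' @param cell_size Cell edge in meters.
#' @param total_cells Optional target total (e.g. mutable cell count of the
#'   landscape the demand will be applied to).
#' @param classes Ordered class codes.
#' @return A [demand_vector()].
#' @export
demand_from_areas <- function(areas_hm2, cell_size, total_cells = NULL,
                              classes = habscape_classes()$code) {
  stopifnot(length(areas_hm2) == length(classes), all(areas_hm2 >= 0))
  cells <- as.numeric(areas_hm2) * 10000 / cell_size^2
  if (!is.null(total_cells)) {
    if (sum(cells) == 0) stop("cannot rescale an all-zero demand")
    cells <- cells / sum(cells) * total_cells
    counts <- largest_remainder_round(cells, total = as.integer(total_cells))
  } else {
    counts <- largest_remainder_round(cells, total = as.integer(round(sum(cells))))
  }
  demand_vector(counts, classes)
}
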