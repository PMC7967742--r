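#' Sample training cells for the suitability network
#'
#' Draws a reproducible sample of non-nodata cells and returns their
#' normalized driver values and observed land classes. Stratified sampling
#' draws equal counts per class where possible, which protects rare classes;
#' a class with zero cells is skipped with a warning.
#'
#' @param lu A [land_use_map()] aligned with `drivers`.
#' @param drivers A [driver_stack()]; normalized with [normalize_drivers()]
#'   first if it has no stored bounds.
#' @param fraction Fraction of non-nodata cells to sample (0 < f <= 1).
#' @param strategy `"stratified"` (default) or `"uniform"`.
#' @param seed Integer seed; the same seed yields the identical sample.
#' @return A list with `features` (n x L matrix, one column per driver),
#'   `labels` (factor over all class codes) and `cells` (sampled cell indices).
#' @export
sample_training_cells <- function(lu, drivers, fraction = 0.05,
                                  strategy = c("stratified", "uniform"),
                                  seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(lu, "land_use_map"), inherits(drivers, "driver_stack"),
            fraction > 0, fraction <= 1)
  if (!identical(dim(lu$codes), dim(drivers$layers[[1]])))
    stop("land-use map and drivers must share one shape")
  if (is.null(drivers$bounds)) drivers <- normalize_drivers(drivers)
  idx_all <- which(!lu$nodata & !drivers$nodata)
  n_want <- max(1L, floor(fraction * length(idx_all)))
  codes <- lu$codes[idx_all]
  set.seed(seed)
  if (fraction == 1) {
    take <- idx_all
  } else if (strategy == "uniform") {
    take <- sort(sample(idx_all, n_want))
  } else {
    k <- lu$class_table$code
    per <- ceiling(n_want / length(k))
    take <- integer(0)
    for (cl in k) {
      pool <- idx_all[codes == cl]
      if (length(pool) == 0L) {
        warning("class ", cl, " has zero cells; skipped in stratified sample")
        next
      }
      take <- c(take, if (length(pool) <= per) pool
                else sample(pool, per))
    }
    take <- sort(take)
  }
  feats <- vapply(drivers$layers, function(m) m[take], numeric(length(take)))
  feats <- matrix(feats, nrow = length(take),
                  dimnames = list(NULL, names(drivers$layers)))
  labels <- factor(lu$codes[take], levels = lu$class_table$code)
  list(features = feats, labels = labels, cells = take)
}

#' Train the one-hidden-layer suitability network
#'
#' Fits a single-hidden-layer feed-forward network (sigmoid hidden and output
#' units, cross-entropy objective) mapping normalized driver values to
#' per-class occurrence indicators. Training is deterministic given the seed.
#'
#' @param features n x L matrix of normalized driver values (named columns).
#' @param labels Factor of observed classes (levels = all class codes).
#' @param hidden_size Hidden-neuron count; default 12.
#' @param seed Integer seed for weight initialization.
#' @param maxit Training-epoch cap; default 200.
#' @param bounds Optional per-layer normalization bounds (from
#'   [normalize_drivers()]) stored for prediction-time scaling.
#' @return Object of class `suitability_model` holding the fitted `nnet`,
#'   `input_names`, `hidden_size`, `classes`, `bounds` and `seed`.
#' @export
train_suitability_model <- function(features, labels, hidden_size = 12L,
                                    seed = 1L, maxit = 200L, bounds = NULL) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  if (any(!is.finite(features))) stop("non-finite driver values in features")
  classes <- levels(labels)
  y <- matrix(0, nrow = length(labels), ncol = length(classes),
              dimnames = list(NULL, classes))
  y[cbind(seq_along(labels), as.integer(labels))] <- 1
  set.seed(seed)
  fit <- nnet::nnet(x = features, y = y, size = hidden_size,
                    entropy = TRUE, maxit = maxit, trace = FALSE,
                    MaxNWts = 100000L)
  structure(
    list(net = fit, input_names = colnames(features),
         hidden_size = as.integer(hidden_size), classes = classes,
         bounds = bounds, seed = as.integer(seed)),
    class = "suitability_model"
  )
}

#' Predict per-class suitability probability surfaces
#'
#' Applies the trained network to every non-nodata cell and renormalizes the
#' raw sigmoid outputs so the per-cell probabilities sum to exactly 1 across
#' classes. Driver layers are matched to the model by name, so layer order is
#' irrelevant; values outside the stored normalization bounds are clamped
#' with a warning.
#'
#' @param model A [train_suitability_model()] fit.
#' @param drivers A [driver_stack()] with the model's input layers. Raw
#'   (unnormalized) stacks are scaled with the model's stored bounds.
#' @return Object of class `suitability_stack`: list with `sp` (named list of
#'   K probability matrices), `classes`, `nodata`.
#' @export
predict_suitability <- function(model, drivers) {
  stopifnot(inherits(model, "suitability_model"), inherits(drivers, "driver_stack"))
  missing <- setdiff(model$input_names, names(drivers$layers))
  if (length(missing) > 0)
    stop("driver stack lacks model inputs: ", paste(missing, collapse = ", "))
  layers <- drivers$layers[model$input_names]
  if (is.null(drivers$bounds)) {
    if (!is.null(model$bounds)) {
      layers <- mapply(function(m, b) {
        span <- b[2] - b[1]
        if (span == 0) m[] <- 0 else m <- (m - b[1]) / span
        m
      }, layers, model$bounds[model$input_names], SIMPLIFY = FALSE)
    }
  }
  rng <- range(unlist(lapply(layers, range, na.rm = TRUE)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    warning("driver values outside normalization bounds; clamped to [0,1]")
    layers <- lapply(layers, clamp, 0, 1)
  }
  ok <- !drivers$nodata
  X <- vapply(layers, function(m) m[ok], numeric(sum(ok)))
  X <- matrix(X, nrow = sum(ok), dimnames = list(NULL, model$input_names))
  raw <- stats::predict(model$net, X)
  raw <- pmax(raw, 1e-12)           # keep the roulette strictly positive
  prob <- raw / rowSums(raw)
  shape <- dim(drivers$layers[[1]])
  sp <- lapply(seq_along(model$classes), function(j) {
    m <- matrix(NA_real_, shape[1], shape[2])
    m[ok] <- prob[, j]
    m
  })
  names(sp) <- model$classes
  structure(list(sp = sp, classes = model$classes, nodata = drivers$nodata),
            class = "suitability_stack")
}
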