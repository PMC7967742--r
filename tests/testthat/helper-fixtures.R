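# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- build()
  .fixture_env[[key]]
}

# mid-sized synthetic landscape with a trained suitability model
fixture_land <- function() {
  cached("land80", function() {
    spec <- synthetic_spec(shape = c(80L, 80L), seed = 7L)
    land <- generate_landscape_pair(spec)
    drv <- normalize_drivers(land$drivers)
    samp <- sample_training_cells(land$lu_t1, drv, fraction = 0.05, seed = 3L)
    model <- train_suitability_model(samp$features, samp$labels,
                                     seed = 3L, bounds = drv$bounds)
    land$drivers_norm <- drv
    land$model <- model
    land$sp <- predict_suitability(model, drv)
    land
  })
}

fixture_params <- function() cached("params", read_parameter_tables)

# small land-use map from a vector of codes
tiny_lu <- function(codes, nr, nc, cell_size = 30) {
  land_use_map(matrix(codes, nr, nc), cell_size = cell_size)
}

# a landscape whose class is a deterministic function of two drivers
fixture_two_driver <- function(shape = c(90L, 90L)) {
  cached("twodrv", function() {
    f1 <- random_field(shape, 6, 11L)
    f2 <- random_field(shape, 6, 12L)
    idx <- pmin(1L + findInterval(f1, c(1 / 3, 2 / 3)) +
                  3L * findInterval(f2, 0.5), 8L)
    lu <- land_use_map(matrix(c(1L, 3L, 5L, 6L, 7L, 8L)[idx],
                              shape[1], shape[2]))
    drv <- normalize_drivers(driver_stack(list(a = f1, b = f2)))
    list(lu = lu, drivers = drv)
  })
}
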