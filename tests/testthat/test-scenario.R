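test_that("packaged scenarios reproduce the printed planning parameters", {
  p <- fixture_params()
  s1 <- load_scenario("S1", p)
  s2 <- load_scenario("S2", p)
  s3 <- load_scenario("S3", p)
  s4 <- load_scenario("S4", p)

  expect_equal(s1$demand_source, "markov")
  expect_equal(unname(s2$weights["construction"]), 0.9)
  expect_equal(unname(s3$weights[c("cultivated", "construction", "forest",
                                   "water", "wetland")]),
               c(0.2, 0.9, 0.3, 0.2, 0.2))
  expect_equal(unname(s4$weights[c("cultivated", "construction")]), c(0.4, 0.9))

  # wetland -> unused land is forbidden in the ecological configurations
  expect_equal(unname(s3$allow$allow["7", "8"]), 0L)
  expect_identical(s3$allow$allow, s4$allow$allow)
  expect_identical(s1$allow$allow, s2$allow$allow)

  expect_equal(s1$restricted, character(0))
  expect_equal(s3$restricted, "redline")
  expect_equal(sort(s4$restricted), c("farmland", "redline"))

  expect_equal(unname(s3$demand_areas["construction"]), 159390)
  expect_equal(unname(s2$demand_areas["cultivated"]), 233273)
})

test_that("the four scenarios differ only where the planning tables differ", {
  p <- fixture_params()
  cfgs <- lapply(c("S1", "S2", "S3", "S4"), load_scenario, params = p)
  names(cfgs) <- c("S1", "S2", "S3", "S4")
  # S1 vs S2: demand source, demand and the construction weight only
  expect_equal(cfgs$S1$weights[-5], cfgs$S2$weights[-5])
  expect_identical(cfgs$S1$conversion_id, cfgs$S2$conversion_id)
  expect_identical(cfgs$S1$restricted, cfgs$S2$restricted)
  # S3 vs S4: weights, demand and masks differ; conversion matrix shared
  expect_identical(cfgs$S3$conversion_id, cfgs$S4$conversion_id)
  expect_false(identical(cfgs$S3$weights, cfgs$S4$weights))
})

test_that("custom configurations are validated field by field", {
  p <- fixture_params()
  expect_error(load_scenario("/tmp/does-not-exist.yaml", p), "not found")

  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.yaml")
  writeLines(c("name: X", "demand_source: wishful", "conversion: s1s2"), bad)
  expect_error(load_scenario(bad, p), "demand_source")

  writeLines(c("name: X", "demand_source: markov", "conversion: nope",
               "weights_row: S1"), bad)
  expect_error(load_scenario(bad, p), "conversion")

  writeLines(c("name: X", "demand_source: markov", "conversion: s1s2"), bad)
  expect_error(load_scenario(bad, p), "weights_row")

  writeLines(c("name: X", "demand_source: table", "conversion: s1s2",
               "weights_row: S1"), bad)
  expect_error(load_scenario(bad, p), "demand_areas")
})

test_that("a scenario demanding the current composition leaves quality unchanged", {
  land <- fixture_land()
  p <- fixture_params()
  cc <- class_counts(land$lu_t1)
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "noop.yaml")
  # areas proportional to the current counts (any common unit)
  areas <- paste(sprintf("  %s: %d", habscape_classes()$name, as.integer(cc)),
                 collapse = "\n")
  writeLines(sprintf(
    "name: NOOP\ndemand_source: table\nconversion: s1s2\nweights_row: S1\ndemand_areas:\n%s",
    areas), cfg_path)
  cfg <- load_scenario(cfg_path, p)
  out <- run_scenario(cfg, land$lu_t1, land$model, land$drivers_norm,
                      params = p, seed = 3, tol = 0)
  expect_identical(out$allocation$landuse$codes, land$lu_t1$codes)
  base <- habitat_quality(land$lu_t1, params = p)
  expect_equal(out$Q$values, base$Q$values)
})

test_that("scenario runs are deterministic and their grade rows sum to 100", {
  land <- fixture_land()
  p <- fixture_params()
  ct <- crosstab_transitions(land$lu_t0, land$lu_t1)
  P <- estimate_transition_matrix(ct, 8)
  cfg <- load_scenario("S3", p)
  r1 <- run_scenario(cfg, land$lu_t1, land$model, land$drivers_norm,
                     masks = land$masks, P = P, params = p, seed = 7)
  r2 <- run_scenario(cfg, land$lu_t1, land$model, land$drivers_norm,
                     masks = land$masks, P = P, params = p, seed = 7)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$allocation$landuse$codes, r2$allocation$landuse$codes)
  grade_cols <- c("Lower", "Low", "Middle", "High", "Higher")
  expect_equal(sum(r1$summary[, grade_cols]), 100, tolerance = 1e-4)
})

test_that("scenario comparison bins changes and ranks by mean quality", {
  base <- matrix(0.5, 6, 6)
  same <- base
  up <- base; up[2, 2] <- 1.0    # +0.5 lands in the top change class
  down <- base - 0.2             # uniform moderate decrease
  cmp <- compare_scenarios(base, list(same = same, up = up, down = down))

  expect_true(all(cmp$change$same$delta == 0))
  expect_equal(cmp$change$same$class_table$percent[3], 100)
  expect_equal(cmp$change$up$classes[2, 2], 5L)
  expect_equal(cmp$change$down$class_table$percent[2], 100)

  expect_equal(cmp$ranking$scenario,
               names(sort(sapply(list(same = same, up = up, down = down),
                                 mean), decreasing = TRUE)))
  expect_error(compare_scenarios(base, list(bad = matrix(0.5, 3, 3))),
               "share one shape")
})
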