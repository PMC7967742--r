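test_that("neighborhood effect counts the window ring and scales by the weight", {
  # center surrounded by 8 cells of class 5
  lu <- tiny_lu(c(5, 5, 5, 5, 1, 5, 5, 5, 5), 3, 3)
  om <- neighborhood_effect(lu, 5L, omega_p = 1)
  expect_equal(om[2, 2], 1)

  # 4 of 8 neighbors, weight 0.5
  lu2 <- tiny_lu(c(5, 1, 5, 1, 1, 1, 5, 1, 5), 3, 3)
  expect_equal(neighborhood_effect(lu2, 5L, omega_p = 0.5)[2, 2], 0.25)

  # no neighbor of the class
  expect_equal(neighborhood_effect(lu2, 7L, omega_p = 1)[2, 2], 0)

  # edges keep the full denominator: a corner has at most 3 live neighbors
  lu3 <- tiny_lu(rep(5, 9), 3, 3)
  expect_equal(neighborhood_effect(lu3, 5L, omega_p = 1)[1, 1], 3 / 8)
  expect_error(neighborhood_effect(lu3, 5L, 1, window = 4), "odd")
})

test_that("inertia keeps still when gaps shrink and scales by the printed ratios", {
  # shrinking gap: unchanged
  expect_equal(update_inertia(1, d_prev1 = 10, d_prev2 = 20), 1)
  # worsening under-allocation doubles
  expect_equal(update_inertia(1, d_prev1 = 20, d_prev2 = 10), 2)
  # worsening over-allocation shrinks by |D2|/|D1|
  expect_equal(update_inertia(1, d_prev1 = -30, d_prev2 = -20), 2 / 3)
  # zero current gap never divides
  expect_equal(update_inertia(2, d_prev1 = 0, d_prev2 = 5), 2)
  # sign flip without |D| decrease: no printed case applies, keep
  expect_equal(update_inertia(1.5, d_prev1 = -10, d_prev2 = 5), 1.5)
  # clamping
  expect_equal(update_inertia(900, d_prev1 = 50, d_prev2 = 10), 1e3)
  expect_equal(update_inertia(0.002, d_prev1 = -50, d_prev2 = -10), 1e-3)
})

test_that("combined probability is the four-factor product with hard zeros on forbidden moves", {
  lu <- tiny_lu(rep(1L, 4), 2, 2)
  K <- 8
  spm <- lapply(1:K, function(i) matrix(0.5, 2, 2))
  names(spm) <- as.character(1:8)
  sp <- structure(list(sp = spm, classes = as.character(1:8),
                       nodata = matrix(FALSE, 2, 2)),
                  class = "suitability_stack")
  omega <- matrix(0.25, 4, K)
  allow <- conversion_matrix(matrix(1, 8, 8))
  tp <- combined_probability(sp, omega, rep(1, K), allow, lu)
  expect_equal(tp, matrix(0.125, 4, K), ignore_attr = TRUE)

  # forbidden transition scores exactly zero, self-transition stays scored
  a <- matrix(1, 8, 8); a[1, 5] <- 0
  tp2 <- combined_probability(sp, omega, rep(1, K), conversion_matrix(a), lu)
  expect_true(all(tp2[, 5] == 0))
  expect_true(all(tp2[, 1] == 0.125))

  # all factors one gives one
  spm1 <- lapply(1:K, function(i) matrix(1, 2, 2))
  names(spm1) <- as.character(1:8)
  sp1 <- structure(list(sp = spm1, classes = as.character(1:8),
                        nodata = matrix(FALSE, 2, 2)),
                   class = "suitability_stack")
  expect_equal(combined_probability(sp1, matrix(1, 4, K), rep(1, K), allow, lu),
               matrix(1, 4, K), ignore_attr = TRUE)
})

test_that("allocation satisfies its contract on a synthetic demand shift", {
  land <- fixture_land()
  k <- habscape_classes()
  cc <- class_counts(land$lu_t1)
  shift <- round(0.05 * sum(cc))
  dem <- cc
  dem["8"] <- dem["8"] - shift
  dem["1"] <- dem["1"] + shift
  p <- fixture_params()
  w <- setNames(as.numeric(p$weights[1, k$name]), k$name)

  # frozen cells keep their class, so their counts leave the demand first
  frz_counts <- tabulate(match(land$lu_t1$codes[land$masks$redline$frozen],
                               k$code), 8)
  dem <- pmax(dem - frz_counts, 0)
  n_mut <- sum(!land$lu_t1$nodata & !land$masks$redline$frozen)
  dem[1] <- dem[1] + (n_mut - sum(dem))

  res <- run_allocation(land$sp, land$lu_t1, demand_vector(dem, k$code), w,
                        p$conversion$s1s2, frozen = land$masks$redline,
                        seed = 11)
  expect_true(res$converged)
  expect_lte(max(res$residual_gap), res$tol)

  # frozen cells unchanged
  frz <- land$masks$redline$frozen
  expect_identical(res$landuse$codes[frz], land$lu_t1$codes[frz])

  # no forbidden transition anywhere
  moved <- which(res$landuse$codes != land$lu_t1$codes)
  from <- land$lu_t1$codes[moved]
  to <- res$landuse$codes[moved]
  expect_true(all(p$conversion$s1s2$allow[cbind(from, to)] == 1))

  # count conservation and monotone residual across iterations
  expect_equal(sum(class_counts(res$landuse)), sum(cc))
  gaps <- res$trajectory[, "max_gap"]
  expect_true(all(diff(gaps) <= 0))

  # determinism
  res2 <- run_allocation(land$sp, land$lu_t1, demand_vector(dem, k$code), w,
                         p$conversion$s1s2, frozen = land$masks$redline,
                         seed = 11)
  expect_identical(res2$landuse$codes, res$landuse$codes)
})

test_that("a demand equal to the current composition changes nothing", {
  land <- fixture_land()
  k <- habscape_classes()
  p <- fixture_params()
  w <- setNames(as.numeric(p$weights[1, k$name]), k$name)
  res <- run_allocation(land$sp, land$lu_t1,
                        demand_vector(class_counts(land$lu_t1), k$code), w,
                        p$conversion$s1s2, seed = 5, tol = 0)
  expect_identical(res$landuse$codes, land$lu_t1$codes)
  expect_equal(res$iterations, 0)
})

test_that("infeasible demands fail with a diagnosis", {
  land <- fixture_land()
  k <- habscape_classes()
  p <- fixture_params()
  w <- setNames(as.numeric(p$weights[1, k$name]), k$name)
  cc <- class_counts(land$lu_t1)

  # totals that do not match the mutable-cell count
  bad <- cc; bad["1"] <- bad["1"] + 10
  expect_error(run_allocation(land$sp, land$lu_t1, demand_vector(bad, k$code),
                              w, p$conversion$s1s2, seed = 1),
               "infeasible demand")

  # everything frozen but a demand that requires change
  all_frozen <- matrix(TRUE, 80, 80)
  shifted <- cc; shifted["1"] <- shifted["1"] + 5; shifted["8"] <- shifted["8"] - 5
  expect_error(run_allocation(land$sp, land$lu_t1,
                              demand_vector(shifted, k$code), w,
                              p$conversion$s1s2, frozen = all_frozen, seed = 1),
               "infeasible")
})

test_that("map agreement scores match hand-computed kappa", {
  lu <- tiny_lu(rep(c(1L, 6L), 8), 4, 4)
  v <- validate_map(lu, lu)
  expect_equal(v$overall, 1)
  expect_equal(v$kappa, 1)

  # confusion [[45,5],[5,45]] on 100 cells: overall 0.9, p_e 0.5, kappa 0.8
  obs <- tiny_lu(c(rep(1L, 50), rep(6L, 50)), 10, 10)
  sim <- tiny_lu(c(rep(1L, 45), rep(6L, 5), rep(1L, 5), rep(6L, 45)), 10, 10)
  v2 <- validate_map(sim, obs)
  expect_equal(v2$overall, 0.9)
  expect_equal(v2$kappa, 0.8)

  # independent random maps agree only by chance
  set.seed(31)
  a <- tiny_lu(sample(1:8, 1e4, replace = TRUE), 100, 100)
  b <- tiny_lu(sample(1:8, 1e4, replace = TRUE), 100, 100)
  expect_lt(abs(validate_map(a, b)$kappa), 0.02)

  # degenerate marginals make kappa undefined
  mono <- tiny_lu(rep(3L, 4), 2, 2)
  expect_true(is.na(validate_map(mono, mono)$kappa))
})
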