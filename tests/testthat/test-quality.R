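test_that("decay kernels hit their closed-form anchor points", {
  expect_equal(decay_influence(0, 2, "linear"), 1)
  expect_equal(decay_influence(0, 2, "exponential"), 1)
  expect_equal(decay_influence(2000, 2, "linear"), 0)
  expect_equal(decay_influence(2000, 2, "exponential"), exp(-2.99))
  expect_equal(decay_influence(2001, 2, "exponential"), 0)  # truncated
  expect_equal(decay_influence(1000, 2, "linear"), 0.5)
  expect_error(decay_influence(-1, 2, "linear"), "non-negative")
})

test_that("threat sources follow the class/subtype mapping", {
  p <- fixture_params()
  lu <- tiny_lu(c(5L, 1L, 8L, 6L), 2, 2)
  src <- derive_threat_sources(lu, threats = p$threats)
  expect_equal(which(src$urban), 1L)
  expect_equal(which(src$cultivated), 2L)
  expect_equal(which(src$saline), 3L)
  expect_false(any(src$rural) || any(src$transport) || any(src$mining))

  # all-water map sources nothing
  water <- tiny_lu(rep(6L, 9), 3, 3)
  src_w <- derive_threat_sources(water, threats = p$threats)
  expect_false(any(vapply(src_w, any, logical(1))))

  # subtype raster splits construction into its four threat types
  lu2 <- tiny_lu(rep(5L, 4), 2, 2)
  subtype <- matrix(c(1L, 2L, 3L, 4L), 2, 2)
  src2 <- derive_threat_sources(lu2, subtype = subtype, threats = p$threats)
  expect_equal(vapply(src2[c("urban", "rural", "transport", "mining")],
                      sum, numeric(1)),
               c(urban = 1, rural = 1, transport = 1, mining = 1))

  expect_error(derive_threat_sources(lu, threats = p$threats,
                                     mapping = c(urban = "class:construction")),
               "no mapping rule")
})

test_that("the worked single-source case degrades by exactly one half at one cell away", {
  fx <- generate_quality_fixture("worked", shape = c(9L, 9L))
  D <- fx$expected_D$values
  # linear decay, d_max two cells: one cell from the source gives 1 - 1/2
  expect_equal(D[5, 6], 0.5)
  expect_equal(D[5, 7], 0)          # exactly at d_max
  expect_equal(D[4, 6], 1 - sqrt(2) / 2)
  # source cell itself: construction, sensitivity 0
  expect_equal(D[5, 5], 0)
  # quality on the degraded neighbor: H = 1, D = k = 0.5 gives exactly 1/2
  expect_equal(fx$expected_Q$values[5, 6], 0.5)
})

test_that("kernel and brute-force degradation agree everywhere", {
  p <- fixture_params()
  set.seed(21)
  for (n in c(16L, 33L, 64L)) {
    lu <- tiny_lu(sample(1:8, n * n, replace = TRUE), n, n, cell_size = 30)
    src <- derive_threat_sources(lu, threats = p$threats)
    d_fft <- degradation_index(src, p$threats, p$sensitivity, lu, method = "fft")
    d_brt <- degradation_index(src, p$threats, p$sensitivity, lu, method = "brute")
    expect_lt(max(abs(d_fft$values - d_brt$values)), 1e-6)
  }
})

test_that("zero sensitivity nullifies a threat's contribution", {
  p <- fixture_params()
  # unused land is insensitive to the cultivated threat
  lu <- tiny_lu(c(1L, 8L, 8L, 8L), 2, 2)
  threats <- p$threats[p$threats$threat == "cultivated", ]
  src <- derive_threat_sources(lu, threats = threats,
                               mapping = c(cultivated = "class:cultivated"))
  d <- degradation_index(src, threats, p$sensitivity, lu)
  expect_equal(d$values[c(2, 3, 4)], rep(0, 3))
})

test_that("quality follows the half-saturation curve and its limits", {
  p <- fixture_params()
  H <- p$sensitivity$H
  lu <- tiny_lu(1:8, 2, 4)
  D0 <- matrix(0, 2, 4)
  q0 <- quality_map(D0, lu, H)
  expect_equal(as.numeric(q0$values), unname(H))  # D = 0 recovers H_j exactly

  # D = k with H = 1 halves the quality, to machine precision
  H1 <- setNames(rep(1, 8), habscape_classes()$name)
  qk <- quality_map(matrix(0.5, 2, 4), lu, H1, z = 2.5, k = 0.5)
  expect_lt(max(abs(qk$values - 0.5)), 1e-12)

  # construction land scores zero regardless of degradation
  con <- tiny_lu(rep(5L, 4), 2, 2)
  expect_true(all(quality_map(matrix(runif(4), 2, 2), con, H)$values == 0))

  expect_error(quality_map(matrix(-0.1, 2, 4), lu, H), "D >= 0")
})

test_that("grades bin lower-inclusively and partition the map", {
  q <- matrix(c(0.05, 0.65, 0.4, 0.1, 0.7, 1, 0, 0.39), 2, 4)
  g <- classify_grades(q)
  expect_equal(g$labels[g$grades[1, 1]], "Lower")   # 0.05
  expect_equal(g$labels[g$grades[2, 1]], "High")    # 0.65
  expect_equal(g$labels[g$grades[1, 2]], "Middle")  # 0.40 inclusive
  expect_equal(g$labels[g$grades[2, 2]], "Low")     # 0.10 inclusive
  expect_equal(g$labels[g$grades[1, 3]], "Higher")  # 0.70 inclusive
  expect_equal(sum(g$table$percent), 100)
  expect_error(classify_grades(q, edges = c(0.4, 0.1)), "increasing")
})

test_that("quality summaries use population statistics over live cells", {
  s <- summarize_quality(matrix(0.9, 3, 3))
  expect_equal(s$mean, 0.9)
  expect_equal(s$sd, 0)

  half <- summarize_quality(matrix(c(rep(0, 8), rep(1, 8)), 4, 4))
  expect_equal(half$mean, 0.5)
  expect_equal(half$sd, 0.5)
  expect_equal(sum(half$grades$percent), 100, tolerance = 1e-4)

  withna <- matrix(c(0.2, NA, 0.4, NA), 2, 2)
  expect_equal(summarize_quality(withna)$mean, 0.3)
  expect_error(summarize_quality(matrix(NA_real_, 2, 2)), "empty")
})

test_that("adding a threat source never raises quality anywhere", {
  p <- fixture_params()
  set.seed(77)
  for (trial in 1:25) {
    lu <- tiny_lu(sample(1:8, 144, replace = TRUE), 12, 12)
    src <- derive_threat_sources(lu, threats = p$threats)
    d0 <- degradation_index(src, p$threats, p$sensitivity, lu)
    q0 <- quality_map(d0, lu, p$sensitivity$H)
    # plant one extra urban source on a random non-source cell
    free <- which(!src$urban)
    src2 <- src
    src2$urban[sample(free, 1)] <- TRUE
    d1 <- degradation_index(src2, p$threats, p$sensitivity, lu)
    q1 <- quality_map(d1, lu, p$sensitivity$H)
    expect_true(all(q1$values <= q0$values + 1e-12))
    expect_true(all(d1$values >= d0$values - 1e-12))
  }
})

test_that("quality is resolution-invariant for a fixed point source", {
  # one source cell; halving the cell size while doubling the grid keeps the
  # metric distances, hence Q, at corresponding points
  p <- fixture_params()
  mk <- function(n, cs) {
    codes <- matrix(3L, n, n)
    codes[1, 1] <- 5L
    lu <- land_use_map(codes, cell_size = cs)
    src <- derive_threat_sources(lu, threats = p$threats)
    quality_map(degradation_index(src, p$threats, p$sensitivity, lu),
                lu, p$sensitivity$H)
  }
  q_coarse <- mk(12, 60)
  q_fine <- mk(24, 30)
  # diagonal cell (i, i) of the coarse grid and (2i-1, 2i-1) of the fine grid
  # lie at the same metric distance sqrt(2) * 60 * (i - 1) from the source
  fine_idx <- 2 * seq_len(12) - 1
  expect_equal(diag(q_coarse$values)[-1], diag(q_fine$values)[fine_idx][-1],
               tolerance = 1e-3)
})
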