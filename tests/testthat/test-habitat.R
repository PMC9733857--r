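# single-threat roster used where weight normalisation should be trivial
urban_only <- function() {
  tibble::tibble(name = "urban_settlement", max_dist_km = 10, weight = 1,
                 decay = "exponential", source = "codes:51")
}

test_that("decay_factor: on-source maximum, linear midpoint, exponential tail", {
  expect_equal(decay_factor(0, 1000, "linear"), 1)
  expect_equal(decay_factor(0, 1000, "exponential"), 1)
  expect_equal(decay_factor(500, 1000, "linear"), 0.5)
  expect_equal(decay_factor(1000, 1000, "exponential"), exp(-2.99))
  expect_equal(decay_factor(1500, 1000, "exponential"), 0)  # truncated
  expect_equal(decay_factor(1500, 1000, "linear"), 0)
  expect_error(decay_factor(10, -1), "> 0")
})

test_that("threat_sources turns land-use codes and rasters into indicators", {
  codes <- matrix(c(12, 12, 21, 21,
                    12, 12, 21, 51), 2, 4, byrow = TRUE)
  lu <- eco_landuse(codes, cell_size = 30)
  arable <- list(name = "arable_land", source = "codes:11|12")
  src <- threat_sources(lu, arable)
  expect_equal(sum(src$values), 4)  # exactly the four arable cells
  road <- g30(matrix(c(0, 1, 0, 0, 0, 0, 1, 0), 2, 4, byrow = TRUE))
  via_raster <- threat_sources(lu, list(name = "way", source = "raster:road"),
                               list(road = road))
  expect_equal(via_raster$values, road$values)
  expect_error(threat_sources(lu, list(name = "x", source = "codes:99")),
               "not in code table")
  expect_error(threat_sources(lu, list(name = "way", source = "raster:road")),
               "external raster")
})

test_that("degradation matches the hand-evaluated decay chain on a strip", {
  # urban source in cell 1, woodland 5 km away, d_max 10 km, exponential,
  # single threat so the weight normalises to 1, beta = 1, S = 0.6
  codes <- matrix(c(51, rep(21, 10)), 1, 11)
  lu <- eco_landuse(codes, cell_size = 500)
  D <- degradation(lu, urban_only())
  expect_equal(D$values[1, 11], exp(-2.99 * 0.5) * 0.6, tolerance = 1e-12)
  # and on the source cell: construction has sensitivity 0 -> D = 0
  expect_equal(D$values[1, 1], 0)
})

test_that("degradation is zero with no sources or no sensitivity", {
  lu <- uniform_landuse(3, 3)      # woodland everywhere, no threat sources
  D <- degradation(lu, urban_only())
  expect_true(all(D$values == 0))

  sens0 <- sensitivity_table()
  sens0[setdiff(names(sens0), c("class", "habitat"))] <- 0
  codes <- matrix(c(51, rep(21, 8)), 3, 3)
  lu2 <- eco_landuse(codes, cell_size = 30)
  D2 <- degradation(lu2, urban_only(), sens = sens0)
  expect_true(all(D2$values == 0))
})

test_that("rescaling all threat weights leaves degradation unchanged", {
  codes <- matrix(c(51, 12, rep(21, 14)), 4, 4)
  lu <- eco_landuse(codes, cell_size = 100)
  th <- threat_table()[c(1, 5), ]          # arable + urban, no road needed
  D1 <- degradation(lu, th)
  th2 <- th; th2$weight <- th2$weight / 2  # uniform rescale
  D2 <- degradation(lu, th2)
  expect_equal(D1$values, D2$values, tolerance = 1e-12)
})

test_that("missing sensitivity column is reported by threat name", {
  lu <- uniform_landuse(2, 2)
  th <- urban_only(); th$name <- "quarry"
  th$source <- "codes:21"
  expect_error(degradation(lu, th), "quarry")
})

test_that("habitat quality: zero-degradation identity and half-saturation", {
  lu <- uniform_landuse(2, 2)                      # woodland, H = 1
  q0 <- habitat_quality(g30(matrix(0, 2, 2)), lu)
  expect_true(all(q0$values == 1))
  p <- habitat_params(k = 0.5)
  qk <- habitat_quality(g30(matrix(0.5, 2, 2)), lu, params = p)
  expect_equal(qk$values, matrix(0.5, 2, 2), tolerance = 1e-12)  # H/2

  arable <- uniform_landuse(2, 2, code = 12)       # H = 0.5
  qa <- habitat_quality(g30(matrix(0.5, 2, 2)), arable, params = p)
  expect_equal(qa$values, matrix(0.25, 2, 2), tolerance = 1e-12)
})

test_that("construction land has quality 0 regardless of degradation", {
  lu <- uniform_landuse(2, 3, code = 53)
  for (d in c(0, 0.2, 5)) {
    q <- habitat_quality(g30(matrix(d, 2, 3)), lu)
    expect_true(all(q$values == 0))
  }
})

test_that("quality is monotone non-increasing in degradation and in [0, 1]", {
  set.seed(21)
  lu1 <- uniform_landuse(1, 1)
  for (i in 1:200) {
    k <- runif(1, 0.05, 2)
    d <- sort(runif(2, 0, 3))
    p <- habitat_params(k = k)
    q <- vapply(d, function(di)
      habitat_quality(eco_grid(matrix(di, 1, 1), 30), lu1, params = p)$values[1, 1],
      numeric(1))
    expect_true(q[2] <= q[1] + 1e-12)
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("quality rises with distance from a point source, then plateaus", {
  codes <- matrix(c(51, rep(21, 29)), 1, 30)
  lu <- eco_landuse(codes, cell_size = 500)     # d_max 10 km = 20 cells
  q <- habitat_stage(lu, urban_only())$quality$values[1, -1]
  expect_true(all(diff(q[1:20]) > 0))
  expect_equal(length(unique(round(q[21:29], 12))), 1L)  # beyond d_max
})
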