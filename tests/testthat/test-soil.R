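monthly_uniform <- function(p_month, nr = 2, nc = 2, cell = 30) {
  lapply(rep(p_month, 12), function(x) eco_grid(matrix(x, nr, nc), cell))
}

test_that("erosivity matches the closed-form scalar oracle", {
  r <- rainfall_erosivity(monthly_uniform(100), si_convert = FALSE)
  # independent scalar evaluation: 12 equal months of 100 mm, P = 1200 mm
  term <- 1.735 * 10^(1.5 * log10(100^2 / 1200) - 0.8188)
  expect_equal(r$values, matrix(12 * term, 2, 2), tolerance = 1e-12)
  r_si <- rainfall_erosivity(monthly_uniform(100))
  expect_equal(r_si$values, r$values * 17.02, tolerance = 1e-12)
  expect_true(attr(r_si, "si_convert"))
})

test_that("erosivity: zero rainfall gives zero; negative rainfall rejected", {
  expect_true(all(rainfall_erosivity(monthly_uniform(0))$values == 0))
  bad <- monthly_uniform(10)
  bad[[3]]$values[1, 1] <- -5
  expect_error(rainfall_erosivity(bad), ">= 0")
})

test_that("doubling all monthly rainfall scales every term by 2^1.5", {
  set.seed(9)
  months <- lapply(1:12, function(i) g30(matrix(runif(9, 0, 200), 3, 3)))
  r1 <- rainfall_erosivity(months)
  r2 <- rainfall_erosivity(lapply(months, function(g) grid_like(g, g$values * 2)))
  expect_equal(r2$values, r1$values * 2^1.5, tolerance = 1e-9)
})

test_that("EPIC erodibility matches a term-by-term scalar evaluation", {
  k <- soil_erodibility(g30(matrix(40, 1, 1)), g30(matrix(30, 1, 1)),
                        g30(matrix(30, 1, 1)), g30(matrix(1, 1, 1)))
  f1 <- 0.2 + 0.3 * exp(-0.0256 * 40 * (1 - 30 / 100))
  f2 <- (30 / (30 + 30))^0.3
  f3 <- 1 - 0.25 * 1 / (1 + exp(3.72 - 2.95 * 1))
  sn1 <- 1 - 40 / 100
  f4 <- 1 - 0.7 * sn1 / (sn1 + exp(22.9 * sn1 - 5.51))
  expect_equal(k$values[1, 1], f1 * f2 * f3 * f4, tolerance = 1e-12)
  expect_gt(k$values[1, 1], 0)
})

test_that("erodibility edge cases: pure sand, vanishing silt+clay", {
  # SAN = 100 -> SN1 = 0 -> fourth factor exactly 1
  k100 <- soil_erodibility(g30(matrix(100, 1, 1)), g30(matrix(50, 1, 1)),
                           g30(matrix(50, 1, 1)), g30(matrix(1, 1, 1)))
  k_expected <- (0.2 + 0.3 * exp(-0.0256 * 100 * 0.5)) * (0.5)^0.3 *
    (1 - 0.25 / (1 + exp(3.72 - 2.95)))
  expect_equal(k100$values[1, 1], k_expected, tolerance = 1e-12)
  k0 <- soil_erodibility(g30(matrix(100, 1, 1)), g30(matrix(0, 1, 1)),
                         g30(matrix(0, 1, 1)), g30(matrix(1, 1, 1)))
  expect_true(is.na(k0$values[1, 1]))
  expect_error(soil_erodibility(g30(matrix(120, 1, 1)), g30(matrix(30, 1, 1)),
                                g30(matrix(30, 1, 1)), g30(matrix(1, 1, 1))),
               "\\[0, 100\\]")
})

test_that("erodibility strictly decreases with organic carbon", {
  oc <- seq(0.1, 3, by = 0.1)
  k <- vapply(oc, function(c_) soil_erodibility(
    g30(matrix(40, 1, 1)), g30(matrix(30, 1, 1)), g30(matrix(30, 1, 1)),
    g30(matrix(c_, 1, 1)))$values[1, 1], numeric(1))
  expect_true(all(diff(k) < 0))
})

test_that("LS is zero on a flat DEM and one at the USLE reference cell", {
  expect_warning(ls_flat <- ls_factor(g30(matrix(100, 4, 4))), "constant DEM")
  expect_true(all(ls_flat$values == 0))

  # crest cell with accumulation 1, slope sin(theta) = 0.0896, 22.13 m cell
  cs <- 22.13
  t <- 0.0896 / sqrt(1 - 0.0896^2)         # tan of the reference angle
  z <- c(2 * cs * t, 5, 0, -1, -2, -3)
  ls <- ls_factor(eco_grid(matrix(z, 1, 6), cs))
  expect_equal(ls$values[1, 2], 1, tolerance = 1e-12)
})

test_that("LS grows downslope along a uniform ramp until the length cap", {
  z <- seq(600, 600 - 19 * 3, by = -3)     # 1 x 20 ramp, 30 m cells
  ls <- ls_factor(eco_grid(matrix(z, 1, 20), 30))$values[1, ]
  interior <- 2:19
  lambda_capped <- which(interior * 30 >= 333)
  expect_true(all(diff(ls[2:11]) > 0))          # accumulating slope length
  expect_equal(length(unique(round(ls[12:19], 10))), 1L)  # capped at 333 m
  expect_error(ls_factor(g30(matrix(c(1, NA, 2, 3), 2, 2))), "nodata")
})

test_that("USLE stack honours the C/P table and its algebraic identities", {
  codes <- matrix(c(66, 42, 21, 12), 2, 2)
  lu <- eco_landuse(codes, cell_size = 30)
  r <- g30(matrix(1000, 2, 2)); k <- g30(matrix(0.25, 2, 2))
  ls <- g30(matrix(c(0.5, 1, 2, 4), 2, 2))
  st <- usle_stack(r, k, ls, lu)
  expect_equal(st$sd$values[codes == 66], 0)            # unused: C = P = 1
  expect_equal(st$usle$values[codes == 42], 0)          # waters: C = P = 0
  expect_equal(st$sd$values[codes == 42], st$rkls$values[codes == 42])
  cp <- cp_table()
  cpm <- matrix(cp$c_factor[match(landuse_primary(lu), cp$class)] *
                  cp$p_factor[match(landuse_primary(lu), cp$class)], 2, 2)
  expect_equal(st$sd$values, st$rkls$values * (1 - cpm), tolerance = 1e-12)
  expect_true(all(st$sd$values >= 0))
  expect_true(all(st$usle$values <= st$rkls$values + 1e-12))
})

test_that("erosion quantities are linear in R and K; totals conserve", {
  b <- worked_strip(10)
  s1 <- soil_stage(b$landuse, b$precip_monthly, b$dem, b$san, b$sil, b$cla,
                   b$oc)
  r2 <- grid_like(s1$r, s1$r$values * 3)
  st2 <- usle_stack(r2, s1$k, s1$ls, b$landuse)
  expect_equal(st2$usle$values, s1$usle$values * 3, tolerance = 1e-9)
  expect_equal(sum(s1$sd$values), sum(s1$rkls$values) - sum(s1$usle$values),
               tolerance = 1e-9)
})
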