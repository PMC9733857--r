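four_services <- function(nr = 3, nc = 3, seed = 1) {
  set.seed(seed)
  list(habitat = g30(matrix(runif(nr * nc), nr, nc)),
       carbon = g30(matrix(runif(nr * nc, 0, 200), nr, nc)),
       water = g30(matrix(runif(nr * nc, 0, 800), nr, nc)),
       soil = g30(matrix(runif(nr * nc, 0, 50), nr, nc)))
}

test_that("build_matrix intersects masks and scatters back losslessly", {
  sv <- four_services()
  sv$carbon$values[2, 2] <- NA
  m <- build_matrix(sv)
  expect_equal(nrow(m$values), 8)                 # 9 cells minus one nodata
  expect_identical(m$indicators, names(sv))       # column order persisted
  back <- matrix_to_grid(m, "water")
  expect_equal(back$values[-5], sv$water$values[-5])
  expect_true(is.na(back$values[2, 2]))
  sv_allna <- lapply(sv, function(g) grid_like(g, NA_real_))
  expect_error(build_matrix(sv_allna), "no cells")
})

test_that("min-max normalisation: endpoints, reflection, constant columns", {
  sv <- list(a = g30(matrix(c(2, 4, 6), 1, 3)),
             b = g30(matrix(c(2, 4, 6), 1, 3)),
             c = g30(matrix(5, 1, 3)))
  m <- build_matrix(sv)
  expect_warning(nb <- normalize_indicators(m), "constant")
  expect_equal(sort(nb$values[, "a"]), c(0, 0.5, 1))
  expect_equal(nb$values[, "c"], rep(0.5, 3))     # flagged convention
  expect_identical(nb$constant, "c")
  m2 <- build_matrix(sv[1:2])
  nc_ <- normalize_indicators(m2, orientation = c("benefit", "cost"))
  expect_equal(sort(nc_$values[, "b"]), c(0, 0.5, 1))
  expect_equal(nc_$values[, "a"], 1 - nc_$values[, "b"])
})

test_that("entropy weights: symmetry, normalisation, hand oracle", {
  # identical columns share the weight equally
  set.seed(19)
  col <- runif(4)
  sv <- list(a = g30(matrix(col, 4, 1)),
             b = g30(matrix(col, 4, 1)),
             c = g30(matrix(col, 4, 1)))
  w <- entropy_weights(normalize_indicators(build_matrix(sv)))
  expect_equal(w$weight, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)

  # 4 x 2 hand-computed oracle: one all-or-nothing column, one constant
  sv2 <- list(spread = g30(matrix(c(0, 0, 0, 1), 4, 1)),
              flat = g30(matrix(1, 4, 1)))
  suppressWarnings(nm2 <- normalize_indicators(build_matrix(sv2)))
  w2 <- entropy_weights(nm2)
  expect_equal(w2$weight, c(1, 0), tolerance = 1e-12)
  expect_equal(w2$entropy, c(0, 1), tolerance = 1e-12)
  expect_equal(w2$weight,
               entropy_weights_oracle(nm2$values), tolerance = 1e-12)
})

test_that("entropy weights are equivariant under indicator relabelling", {
  sv <- four_services(4, 4, seed = 8)
  w1 <- entropy_weights(normalize_indicators(build_matrix(sv)))
  perm <- c("soil", "habitat", "water", "carbon")
  w2 <- entropy_weights(normalize_indicators(build_matrix(sv[perm])))
  expect_equal(w2$weight[match(w1$indicator, w2$indicator)], w1$weight,
               tolerance = 1e-12)
})

test_that("tidy and glance on weights expose the report columns", {
  w <- entropy_weights(normalize_indicators(build_matrix(four_services())))
  td <- tidy(w)
  expect_named(td, c("indicator", "entropy", "weight"))
  expect_equal(glance(w)$n_cells, 9L)
})

test_that("importance score is the weighted sum, bounded by [0, 1]", {
  sv <- four_services(5, 5, seed = 2)
  m <- normalize_indicators(build_matrix(sv))
  w <- entropy_weights(m)
  sc <- importance_score(m, w)
  expect_equal(sc$values[m$cells], as.vector(m$values %*% w$weight),
               tolerance = 1e-12)
  expect_true(all(sc$values >= 0 & sc$values <= 1))
  ones <- m; ones$values[] <- 1
  expect_equal(importance_score(ones, w)$values[m$cells], rep(1, 25))
  zeros <- m; zeros$values[] <- 0
  expect_equal(importance_score(zeros, w)$values[m$cells], rep(0, 25))
  wbad <- tidy(w); wbad$weight <- wbad$weight * 2
  expect_error(importance_score(m, wbad), "sum to 1")
})

test_that("a cell strong in the heaviest service outscores one strong in the lightest", {
  # reported ordering of the study's weights, used as a fixture
  w <- tibble::tibble(
    indicator = c("soil", "carbon", "water", "habitat"),
    weight = c(0.33, 0.26, 0.17, 0.14) / 0.9)
  m <- structure(list(
    values = matrix(c(1, 0, 0, 0, 0, 0, 0, 1), 2, 4,
                    dimnames = list(NULL, w$indicator)),
    indicators = w$indicator, cells = 1:2,
    template = g30(matrix(NA_real_, 1, 2)), normalized = TRUE),
    class = "eco_indicators")
  sc <- importance_score(m, w)
  expect_gt(sc$values[1, 1], sc$values[1, 2])   # soil-strong beats habitat-strong
})

test_that("jenks recovers well-separated bunches and is order invariant", {
  x <- c(1, 2, 3, 10, 11, 12, 20, 21, 22, 30, 31, 33)
  jc <- jenks_classify(x, 4)
  expect_equal(jc$classes, rep(1:4, each = 3))
  expect_equal(jc$breaks, c(3, 12, 22))
  set.seed(3)
  jc2 <- jenks_classify(sample(x), 4)
  expect_equal(jc2$breaks, jc$breaks)
  jc1 <- jenks_classify(x, 1)
  expect_equal(jc1$breaks, numeric(0))
  expect_true(all(jc1$classes == 1L))
  expect_error(jenks_classify(rep(1:3, 5), 4), "distinct")
})

test_that("jenks DP equals the exhaustive-search optimum on small vectors", {
  set.seed(14)
  for (trial in 1:40) {
    n <- sample(6:20, 1)
    x <- round(runif(n, 0, 100), 2)
    if (length(unique(x)) < 4) next
    jc <- jenks_classify(x, 4)
    s <- sort(x)
    dp_ssd <- partition_ssd(s, cumsum(tabulate(jc$classes[order(x)], 4))[1:3])
    expect_equal(dp_ssd, jenks_exhaustive_ssd(x, 4), tolerance = 1e-9)
  }
})

test_that("tier areas partition the valid area and sum to 100 percent", {
  tier <- g30(matrix(c(1, 1, 2, 3, 4, 4, NA, 2, 3), 3, 3))
  ta <- tier_areas(tier, importance_labels())
  expect_equal(sum(ta$n_cells), 8L)
  expect_equal(sum(ta$percent), 100, tolerance = 1e-9)
  expect_equal(ta$area_km2, ta$n_cells * 30^2 / 1e6, tolerance = 1e-12)
  ta100 <- tier_areas(eco_grid(matrix(1, 10, 10), 30))
  expect_equal(ta100$area_km2, 0.09, tolerance = 1e-12)
})

test_that("the score map is invariant to positive rescaling of the layers", {
  sv <- four_services(6, 6, seed = 10)
  r1 <- assess_importance(sv)
  sv2 <- purrr::map2(sv, c(3, 0.01, 7, 100),
                     function(g, a) grid_like(g, g$values * a))
  r2 <- assess_importance(sv2)
  expect_equal(r2$score$values, r1$score$values, tolerance = 1e-9)
  expect_equal(r2$areas$percent, r1$areas$percent)
})

test_that("assess_importance returns a coherent result object", {
  sv <- four_services(8, 8, seed = 11)
  res <- assess_importance(sv)
  expect_s3_class(res, "eco_importance")
  expect_length(res$breaks, 3)
  expect_true(all(diff(res$breaks) > 0))
  expect_equal(sum(res$areas$percent), 100, tolerance = 1e-9)
  expect_equal(tidy(res), res$areas)
  expect_equal(glance(res)$n_tiers, 4L)
  # tiers ordered by ascending score
  sc <- res$score$values[!is.na(res$score$values)]
  ti <- res$tier$values[!is.na(res$tier$values)]
  expect_true(max(sc[ti == 1]) <= min(sc[ti == 4]))
})
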