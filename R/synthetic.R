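#' Specification of a synthetic mountain landscape
#'
#' Parameters of the seeded generator that emulates the study conditions of
#' a temperate mountain protected area: a six-class, woodland-dominated
#' land-use mosaic (woodland ~70\% of the area), strong relief (~800-3750 m),
#' spatially autocorrelated climate and soil fields, a monsoon-shaped monthly
#' rainfall profile, and rainfall increasing with elevation (orographic
#' trend).
#'
#' @param seed Integer RNG seed; identical seeds give bit-identical bundles.
#' @param n_rows,n_cols Grid dimensions.
#' @param cell_size Cell size in metres (default 30).
#' @param class_fractions Named target area fractions over the six primary
#'   classes; must sum to 1 (±0.01).
#' @param elevation_range Min/max elevation in metres, attained exactly.
#' @param precip_mean,precip_sd Annual rainfall mean and spatial sd (mm/yr).
#' @param et0_mean Reference evapotranspiration at the lowest elevation
#'   (mm/yr); declines ~30\% toward the summit.
#' @param awc_range Plant-available water capacity range (mm).
#' @param soil_san_range,soil_cla_range Sand and clay content ranges (\%);
#'   silt takes the remainder so the three always sum to 100.
#' @param oc_range Organic-carbon content range (\%).
#' @param z_coeff Budyko seasonality constant carried into the water stage.
#' @param smooth_sigma Gaussian smoothing radius of the random fields, in
#'   cells; controls patch size.
#' @return A list of class `landscape_spec`.
#' @export
landscape_spec <- function(seed = 1L,
                           n_rows = 200L, n_cols = 200L, cell_size = 30,
                           class_fractions = c(waters = 0.02,
                                               construction = 0.04,
                                               arable = 0.10,
                                               grassland = 0.12,
                                               woodland = 0.70,
                                               unused = 0.02),
                           elevation_range = c(808, 3748),
                           precip_mean = 900, precip_sd = 150,
                           et0_mean = 950,
                           awc_range = c(50, 250),
                           soil_san_range = c(25, 55),
                           soil_cla_range = c(15, 30),
                           oc_range = c(0.4, 3),
                           z_coeff = 10,
                           smooth_sigma = 8) {
  stopifnot(setequal(names(class_fractions), primary_classes()))
  if (abs(sum(class_fractions) - 1) > 0.01)
    stop("class fractions must sum to 1 (got ", sum(class_fractions), ")",
         call. = FALSE)
  stopifnot(length(elevation_range) == 2L,
            elevation_range[2] > elevation_range[1])
  structure(as.list(environment()), class = "landscape_spec")
}

# Row/column Gaussian band smoother: K %*% m %*% t(Kc) with rows normalised,
# so edges are handled by weight renormalisation rather than padding.
smoother_matrix <- function(n, sigma) {
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  K <- exp(-0.5 * (d / sigma)^2)
  K[d > 3 * sigma] <- 0
  K / rowSums(K)
}

smooth_field <- function(n_rows, n_cols, sigma) {
  noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  smoother_matrix(n_rows, sigma) %*% noise %*% t(smoother_matrix(n_cols, sigma))
}

rescale01 <- function(m) {
  r <- range(m)
  if (r[1] == r[2]) return(matrix(0.5, nrow(m), ncol(m)))
  (m - r[1]) / (r[2] - r[1])
}

# Monsoon-shaped monthly rainfall shares (Jan..Dec), summing to 1: a dry
# winter, a July-August peak carrying ~1/3 of the annual total.
monsoon_profile <- function() {
  c(0.015, 0.02, 0.04, 0.06, 0.09, 0.13, 0.17, 0.16, 0.12, 0.09, 0.06, 0.045)
}

#' Generate a complete synthetic input bundle
#'
#' Draws seeded white noise, smooths it into autocorrelated fields, and
#' derives every layer the pipeline needs: DEM (rescaled exactly to the
#' requested elevation range), a land-use mosaic carved from a smooth
#' "naturalness" surface by quantile slices (waters and settlements low,
#' woodland mid-high, bare unused land at the top) so realised class
#' fractions match the targets to within one cell, annual rainfall positively
#' correlated with elevation, a fixed monsoon monthly profile, reference
#' evapotranspiration declining with elevation, AWC, soil texture summing to
#' 100\%, organic carbon elevated under woodland, and a sinuous road mask.
#' All layers are aligned and nodata-free.
#'
#' @param spec A [landscape_spec()].
#' @return A list of class `eco_bundle`: `dem`, `landuse` (an
#'   [eco_landuse]), `precip_annual`, `precip_monthly` (list of 12), `et0`,
#'   `awc`, `san`, `sil`, `cla`, `oc`, `road` (`eco_grid`s), and `spec`.
#' @export
generate_landscape <- function(spec = landscape_spec()) {
  stopifnot(inherits(spec, "landscape_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  nr <- spec$n_rows; nc <- spec$n_cols; sg <- spec$smooth_sigma
  g <- function(values) eco_grid(values, spec$cell_size)

  f_dem <- smooth_field(nr, nc, sg)
  f_lu <- smooth_field(nr, nc, sg)
  f_pre <- smooth_field(nr, nc, sg)
  f_et0 <- smooth_field(nr, nc, sg)
  f_awc <- smooth_field(nr, nc, sg)
  f_san <- smooth_field(nr, nc, sg)
  f_cla <- smooth_field(nr, nc, sg)
  f_oc <- smooth_field(nr, nc, sg)
  f_sub <- smooth_field(nr, nc, max(2, sg / 2))

  dem01 <- rescale01(f_dem)
  dem <- g(spec$elevation_range[1] +
             dem01 * diff(spec$elevation_range))

  # land use: slice a smooth naturalness surface by target-fraction quantiles
  s <- 0.55 * dem01 + 0.45 * rescale01(f_lu)
  order_cls <- c("waters", "construction", "arable", "grassland",
                 "woodland", "unused")
  fr <- spec$class_fractions[order_cls]
  n_cells <- nr * nc
  counts <- round(fr * n_cells)
  counts[length(counts)] <- n_cells - sum(counts[-length(counts)])
  rk <- rank(s, ties.method = "first")
  upper <- cumsum(counts)
  cls_idx <- findInterval(rk - 1L, c(0L, upper), left.open = FALSE,
                          rightmost.closed = TRUE)
  primary <- matrix(order_cls[cls_idx], nr, nc)

  # secondary codes: split some primaries on an independent fine field
  codes <- matrix(NA_real_, nr, nc)
  sub01 <- rescale01(f_sub)
  split_by <- function(mask, breaks, values) {
    v <- sub01[mask]
    q <- stats::quantile(v, breaks, names = FALSE, type = 7)
    codes[mask] <<- values[findInterval(v, q, left.open = TRUE,
                                        rightmost.closed = FALSE) + 1L]
  }
  split_by(primary == "arable", 0.3, c(11, 12))          # paddy | dry land
  split_by(primary == "woodland", c(0.75, 0.9), c(21, 22, 23))
  split_by(primary == "grassland", 0.5, c(32, 31))
  codes[primary == "waters"] <- 42
  split_by(primary == "construction", c(1 / 3, 2 / 3), c(51, 52, 53))
  codes[primary == "unused"] <- 66
  landuse <- eco_landuse(g(codes))

  # annual rainfall: autocorrelated + orographic uplift with elevation
  z_pre <- f_pre / stats::sd(f_pre)
  precip <- spec$precip_mean +
    spec$precip_sd * (0.7 * z_pre + 0.9 * (2 * dem01 - 1))
  precip <- pmax(precip, 150)
  precip_annual <- g(precip)
  precip_monthly <- lapply(monsoon_profile(), function(w) g(w * precip))

  z_et0 <- f_et0 / stats::sd(f_et0)
  et0 <- g(pmax(spec$et0_mean * (1 - 0.3 * dem01) + 40 * z_et0, 200))
  awc <- g(spec$awc_range[1] + rescale01(f_awc) * diff(spec$awc_range))

  san_v <- spec$soil_san_range[1] +
    rescale01(f_san) * diff(spec$soil_san_range)
  cla_v <- spec$soil_cla_range[1] +
    rescale01(f_cla) * diff(spec$soil_cla_range)
  sil_v <- 100 - san_v - cla_v
  oc_v <- spec$oc_range[1] +
    rescale01(f_oc + 0.6 * (primary == "woodland")) * diff(spec$oc_range)

  # sinuous east-west road: deterministic given the grid shape
  road_v <- matrix(0, nr, nc)
  cols <- seq_len(nc)
  rows <- round(nr * (0.55 + 0.2 * sin(2 * pi * cols / nc * 1.5) +
                        0.1 * (cols / nc - 0.5)))
  rows <- pmin(pmax(rows, 1L), nr)
  road_v[cbind(rows, cols)] <- 1

  structure(list(dem = dem, landuse = landuse, precip_annual = precip_annual,
                 precip_monthly = precip_monthly, et0 = et0, awc = awc,
                 san = g(san_v), sil = g(sil_v), cla = g(cla_v), oc = g(oc_v),
                 road = g(road_v), spec = spec),
            class = "eco_bundle")
}

#' Hand-checkable one-row landscape
#'
#' A 1 x `n_cols` strip built for worked examples and oracle tests: an urban
#' settlement source in the first cell, woodland along the strip with two
#' unused-land cells at the far end, a monotone east-sloping DEM, and uniform
#' climate and soil, so every stage of the pipeline can be verified cell by
#' cell on paper.
#'
#' @param n_cols Strip length (>= 8).
#' @param cell_size Cell size in metres (default 100).
#' @return An `eco_bundle` (see [generate_landscape()]).
#' @export
worked_strip <- function(n_cols = 12L, cell_size = 100) {
  stopifnot(n_cols >= 8L)
  g <- function(x) eco_grid(matrix(x, 1L, n_cols), cell_size)
  codes <- c(51, rep(21, n_cols - 3L), 66, 66)
  landuse <- eco_landuse(g(codes))
  dem <- g(seq(2000, 2000 - 5 * (n_cols - 1L), by = -5))
  precip <- g(1000)
  structure(list(
    dem = dem, landuse = landuse, precip_annual = precip,
    precip_monthly = lapply(monsoon_profile(), function(w) g(w * 1000)),
    et0 = g(900), awc = g(150), san = g(40), sil = g(30), cla = g(30),
    oc = g(1), road = g(rep(0, n_cols)),
    spec = structure(list(seed = NA_integer_, n_rows = 1L, n_cols = n_cols,
                          cell_size = cell_size, z_coeff = 10),
                     class = "landscape_spec")),
    class = "eco_bundle")
}

#' Realised primary-class fractions of a bundle
#'
#' @param bundle An `eco_bundle`.
#' @return A tibble with `class` and `fraction`.
#' @export
class_fractions <- function(bundle) {
  pri <- landuse_primary(bundle$landuse)
  tab <- table(pri)
  tibble::tibble(class = names(tab),
                 fraction = as.numeric(tab) / sum(tab))
}

bundle_layer_names <- function() {
  c("dem", "landuse", "precip_annual",
    sprintf("precip_m%02d", 1:12), "et0", "awc",
    "san", "sil", "cla", "oc", "road")
}

#' Write a bundle to a directory of ASCII rasters
#'
#' One `.asc` file per layer plus `manifest.json` echoing the generator
#' specification and seed. [read_bundle()] restores it exactly.
#'
#' @param bundle An `eco_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lay <- c(list(dem = bundle$dem, landuse = bundle$landuse$grid,
                precip_annual = bundle$precip_annual),
           stats::setNames(bundle$precip_monthly, sprintf("precip_m%02d", 1:12)),
           list(et0 = bundle$et0, awc = bundle$awc, san = bundle$san,
                sil = bundle$sil, cla = bundle$cla, oc = bundle$oc,
                road = bundle$road))
  for (nm in names(lay)) write_grid(lay[[nm]], file.path(dir, paste0(nm, ".asc")))
  spec <- bundle$spec
  spec_out <- lapply(unclass(spec), function(x)
    if (is.numeric(x) || is.character(x) || is.logical(x)) x else NULL)
  jsonlite::write_json(
    list(layers = names(lay), spec = spec_out),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir Directory holding the `.asc` layers.
#' @param code_table Land-use legend (defaults to the packaged one).
#' @return An `eco_bundle`.
#' @export
read_bundle <- function(dir, code_table = landuse_code_table()) {
  rg <- function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    if (!file.exists(p))
      stop("bundle layer missing: ", p, call. = FALSE)
    read_grid(p)
  }
  structure(list(
    dem = rg("dem"),
    landuse = eco_landuse(rg("landuse"), code_table),
    precip_annual = rg("precip_annual"),
    precip_monthly = lapply(sprintf("precip_m%02d", 1:12), rg),
    et0 = rg("et0"), awc = rg("awc"), san = rg("san"), sil = rg("sil"),
    cla = rg("cla"), oc = rg("oc"), road = rg("road"),
    spec = NULL), class = "eco_bundle")
}
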