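#' Rainfall erosivity from monthly totals
#'
#' Wischmeier-style monthly aggregation: each month contributes
#' `1.735 * 10^(1.5 * log10(p_i^2 / P) - 0.8188)` where `p_i` is the monthly
#' and `P` the annual rainfall (mm); the twelve terms are summed and, by
#' default, multiplied by 17.02 to convert to SI erosivity units
#' (MJ mm ha^-1 h^-1 yr^-1). Months with zero rainfall contribute nothing;
#' cells with zero annual rainfall get erosivity 0.
#'
#' @param monthly List of 12 aligned `eco_grid`s of monthly rainfall (mm).
#' @param si_convert Multiply by 17.02 for SI units (default `TRUE`); recorded
#'   as an attribute on the result.
#' @return An `eco_grid` of erosivity R.
#' @export
rainfall_erosivity <- function(monthly, si_convert = TRUE) {
  stopifnot(is.list(monthly), length(monthly) == 12L,
            all(vapply(monthly, is_grid, logical(1))))
  assert_aligned(monthly)
  for (m in monthly) {
    v <- m$values
    if (any(v[!is.na(v)] < 0))
      stop("monthly rainfall must be >= 0", call. = FALSE)
  }
  P <- Reduce(`+`, lapply(monthly, function(g) g$values))
  R <- matrix(0, nrow(P), ncol(P))
  pos <- !is.na(P) & P > 0
  for (m in monthly) {
    pi_ <- m$values
    term <- matrix(0, nrow(P), ncol(P))
    use <- pos & pi_ > 0
    # 1.735 * 10^(1.5*log10(pi^2/P) - 0.8188) == 1.735e-0.8188 * (pi^2/P)^1.5
    term[use] <- 1.735 * 10^(-0.8188) * (pi_[use]^2 / P[use])^1.5
    R <- R + term
  }
  if (si_convert) R <- R * 17.02
  R[is.na(P)] <- NA_real_
  out <- grid_like(monthly[[1L]], R)
  attr(out, "si_convert") <- si_convert
  out
}

#' EPIC soil erodibility
#'
#' Williams' erosion-productivity impact calculator (EPIC) erodibility from
#' texture and organic carbon, the product of four factors: a coarse-fragment
#' term `0.2 + 0.3 exp(-sand_coef * SAN * (1 - SIL/100))`, a silt/clay ratio
#' term `(SIL / (CLA + SIL))^0.3`, an organic-carbon correction
#' `1 - 0.25 C / (C + exp(3.72 - 2.95 C))`, and a high-sand correction
#' `1 - 0.7 SN1 / (SN1 + exp(22.9 SN1 - 5.51))` with `SN1 = 1 - SAN/100`.
#' Cells where `CLA + SIL = 0` are nodata (the second factor is undefined).
#'
#' @param san,sil,cla `eco_grid`s of sand, silt, clay content (\%, \[0, 100\]).
#' @param oc `eco_grid` of organic-carbon content (\%, >= 0).
#' @param sand_coef Coefficient on SAN in the first factor; 0.0256 (the
#'   original EPIC value, SAN in percent).
#' @return An `eco_grid` of erodibility K (t h MJ^-1 mm^-1).
#' @export
soil_erodibility <- function(san, sil, cla, oc, sand_coef = 0.0256) {
  stopifnot(is_grid(san), is_grid(sil), is_grid(cla), is_grid(oc))
  assert_aligned(list(san = san, sil = sil, cla = cla, oc = oc))
  SAN <- san$values; SIL <- sil$values; CLA <- cla$values; C <- oc$values
  rng <- function(x, lo, hi) any(x[!is.na(x)] < lo | x[!is.na(x)] > hi)
  if (rng(SAN, 0, 100) || rng(SIL, 0, 100) || rng(CLA, 0, 100))
    stop("texture fractions must lie in [0, 100] %", call. = FALSE)
  if (any(C[!is.na(C)] < 0)) stop("organic carbon must be >= 0", call. = FALSE)
  SN1 <- 1 - SAN / 100
  f1 <- 0.2 + 0.3 * exp(-sand_coef * SAN * (1 - SIL / 100))
  f2 <- (SIL / (CLA + SIL))^0.3
  f3 <- 1 - 0.25 * C / (C + exp(3.72 - 2.95 * C))
  f4 <- 1 - 0.7 * SN1 / (SN1 + exp(22.9 * SN1 - 5.51))
  K <- f1 * f2 * f3 * f4
  K[!is.na(CLA + SIL) & (CLA + SIL) == 0] <- NA_real_
  grid_like(san, K)
}

# Horn 3x3 slope (radians) with edge replication; row 1 is the north edge.
horn_slope <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  pad <- z[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  sh <- function(dr, dc) pad[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc]
  cs <- dem$cell_size
  dzdx <- ((sh(-1L, 1L) + 2 * sh(0L, 1L) + sh(1L, 1L)) -
             (sh(-1L, -1L) + 2 * sh(0L, -1L) + sh(1L, -1L))) / (8 * cs)
  dzdy <- ((sh(1L, -1L) + 2 * sh(1L, 0L) + sh(1L, 1L)) -
             (sh(-1L, -1L) + 2 * sh(-1L, 0L) + sh(-1L, 1L))) / (8 * cs)
  atan(sqrt(dzdx^2 + dzdy^2))
}

# D8 flow accumulation in cells (each cell counts itself). Flow goes to the
# steepest strictly-lower 8-neighbour; cells are processed from high to low
# so every donor is settled before its receiver.
d8_accumulation <- function(dem) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  drs <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dcs <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dist <- sqrt(drs^2 + dcs^2)
  recv <- integer(n)  # 0 = pit / edge outlet
  best <- matrix(-Inf, nr, nc)
  idx <- matrix(seq_len(n), nr, nc)
  for (k in 1:8) {
    r_ok <- which(seq_len(nr) + drs[k] >= 1L & seq_len(nr) + drs[k] <= nr)
    c_ok <- which(seq_len(nc) + dcs[k] >= 1L & seq_len(nc) + dcs[k] <= nc)
    if (!length(r_ok) || !length(c_ok)) next
    grad <- (z[r_ok, c_ok, drop = FALSE] -
               z[r_ok + drs[k], c_ok + dcs[k], drop = FALSE]) /
      (dist[k] * dem$cell_size)
    better <- !is.na(grad) & grad > 0 &
      grad > best[r_ok, c_ok, drop = FALSE]
    if (!any(better)) next
    bsub <- best[r_ok, c_ok, drop = FALSE]
    bsub[better] <- grad[better]
    best[r_ok, c_ok] <- bsub
    src_idx <- idx[r_ok, c_ok, drop = FALSE]
    rec_idx <- idx[r_ok + drs[k], c_ok + dcs[k], drop = FALSE]
    recv[src_idx[better]] <- rec_idx[better]
  }
  acc <- rep(1, n)
  for (i in order(z, decreasing = TRUE, na.last = TRUE)) {
    r <- recv[i]
    if (r > 0L) acc[r] <- acc[r] + acc[i]
  }
  matrix(acc, nr, nc)
}

#' Topographic slope-length and steepness factor
#'
#' LS from the DEM: slope from Horn 3x3 finite differences, upslope
#' contributing area from D8 flow accumulation (in cells, each cell counting
#' itself), slope length `lambda = min(A * cell_size, 333 m)`, and
#' `LS = (lambda / 22.13)^0.4 * (sin(theta) / 0.0896)^1.3`. The reference
#' constants 22.13 m and 0.0896 are the unit-plot length and slope of the
#' USLE, so a single-cell flow path of 22.13 m at the reference gradient has
#' LS exactly 1. A flat DEM yields LS = 0 everywhere (with a warning).
#'
#' @param dem Elevation `eco_grid` (m); must have no nodata holes inside the
#'   analysis window.
#' @param max_slope_length Slope-length cap in metres (default 333).
#' @return An `eco_grid` of LS (>= 0).
#' @export
ls_factor <- function(dem, max_slope_length = 333) {
  stopifnot(is_grid(dem))
  if (any(is.na(dem$values)))
    stop("DEM has nodata holes inside the analysis window", call. = FALSE)
  theta <- horn_slope(dem)
  if (all(theta == 0))
    warning("constant DEM: slope is zero everywhere, LS = 0", call. = FALSE)
  acc <- d8_accumulation(dem)
  lambda <- pmin(acc * dem$cell_size, max_slope_length)
  ls <- (lambda / 22.13)^0.4 * (sin(theta) / 0.0896)^1.3
  grid_like(dem, ls)
}

#' USLE erosion stack: actual loss, potential loss, retention
#'
#' Combines erosivity R, erodibility K, topography LS, and the per-class
#' cover-management C and support-practice P factors into the actual loss
#' `USLE = R K LS C P`, the bare-soil potential loss `RKLS = R K LS`, and the
#' soil retention `SD = RKLS - USLE = RKLS (1 - C P)`, which is non-negative
#' because `C P` lies in \[0, 1\].
#'
#' @param r Erosivity `eco_grid`, from [rainfall_erosivity()].
#' @param k Erodibility `eco_grid`, from [soil_erodibility()].
#' @param ls LS `eco_grid`, from [ls_factor()].
#' @param landuse An `eco_landuse`.
#' @param cp C/P factor table, as from [cp_table()].
#' @return A list of `eco_grid`s: `usle`, `rkls`, `sd` (loss-rate units,
#'   t ha^-1 yr^-1 when R is SI and K is t h MJ^-1 mm^-1).
#' @export
usle_stack <- function(r, k, ls, landuse, cp = cp_table()) {
  stopifnot(is_grid(r), is_grid(k), is_grid(ls), is_landuse(landuse))
  assert_aligned(list(r = r, k = k, ls = ls, landuse = landuse$grid))
  cf <- class_param_grid(landuse, cp, "c_factor", level = "primary")
  pf <- class_param_grid(landuse, cp, "p_factor", level = "primary")
  rkls <- r$values * k$values * ls$values
  usle <- rkls * cf * pf
  list(usle = grid_like(r, usle),
       rkls = grid_like(r, rkls),
       sd = grid_like(r, rkls - usle))
}

#' Full soil stage: erosivity, erodibility, LS, USLE stack
#'
#' @param landuse An `eco_landuse`.
#' @param monthly List of 12 monthly rainfall `eco_grid`s (mm).
#' @param dem Elevation `eco_grid` (m).
#' @param san,sil,cla,oc Soil texture / organic-carbon `eco_grid`s (\%).
#' @param cp C/P factor table.
#' @param si_convert Apply the 17.02 SI conversion to erosivity.
#' @return A list of `eco_grid`s: `r`, `k`, `ls`, `usle`, `rkls`, `sd`.
#' @export
soil_stage <- function(landuse, monthly, dem, san, sil, cla, oc,
                       cp = cp_table(), si_convert = TRUE) {
  stopifnot(is_landuse(landuse))
  assert_aligned(c(list(landuse = landuse$grid, dem = dem, san = san,
                        sil = sil, cla = cla, oc = oc), monthly))
  r <- rainfall_erosivity(monthly, si_convert = si_convert)
  kk <- soil_erodibility(san, sil, cla, oc)
  ls <- ls_factor(dem)
  c(list(r = r, k = kk, ls = ls), usle_stack(r, kk, ls, landuse, cp))
}
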