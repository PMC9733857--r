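#' Potential evapotranspiration per cell
#'
#' Scales reference evapotranspiration by each cell's land-cover
#' evapotranspiration coefficient Kc: `PET = Kc * ET0`.
#'
#' @param et0 Reference evapotranspiration `eco_grid` (mm/yr).
#' @param landuse An `eco_landuse`.
#' @param table Biophysical table, as from [biophysical_table()].
#' @return An `eco_grid` of PET (mm/yr).
#' @export
pet_grid <- function(et0, landuse, table = biophysical_table()) {
  stopifnot(is_grid(et0), is_landuse(landuse))
  assert_aligned(list(et0 = et0, landuse = landuse$grid))
  kc <- class_param_grid(landuse, table, "kc", level = "primary")
  grid_like(et0, kc * et0$values)
}

#' Budyko shape parameter from seasonal storage
#'
#' `omega = Z * AWC / P + 1.25`: the dimensionless curve-shape parameter
#' grows with plant-available water relative to annual rainfall, scaled by
#' the seasonality constant Z (dimensionless, in \[1, 30\]). Cells with zero
#' rainfall are set to nodata (the ratio is undefined there) and counted in
#' a warning.
#'
#' @param p Annual precipitation `eco_grid` (mm/yr, >= 0).
#' @param awc Plant-available water capacity `eco_grid` (mm, >= 0).
#' @param z_coeff Seasonality constant Z in \[1, 30\].
#' @return An `eco_grid` of omega values (>= 1.25).
#' @export
omega_grid <- function(p, awc, z_coeff) {
  stopifnot(is_grid(p), is_grid(awc))
  if (!is.numeric(z_coeff) || length(z_coeff) != 1L ||
      z_coeff < 1 || z_coeff > 30)
    stop("z_coeff must be a single value in [1, 30]", call. = FALSE)
  assert_aligned(list(p = p, awc = awc))
  pv <- p$values
  if (any(pv[!is.na(pv)] < 0)) stop("precipitation must be >= 0", call. = FALSE)
  if (any(awc$values[!is.na(awc$values)] < 0))
    stop("AWC must be >= 0", call. = FALSE)
  zero_p <- !is.na(pv) & pv == 0
  om <- z_coeff * awc$values / pv + 1.25
  if (any(zero_p)) {
    om[zero_p] <- NA_real_
    warning(sum(zero_p), " cell(s) with zero annual rainfall set to nodata",
            call. = FALSE)
  }
  grid_like(p, om)
}

#' Budyko-curve evapotranspiration fraction (vegetated cells)
#'
#' The fraction of rainfall lost to evapotranspiration on vegetated land:
#' `AET/P = 1 + PET/P - (1 + (PET/P)^omega)^(1/omega)`, which lies in
#' \[0, 1\] for any dryness ratio `PET/P >= 0` when `omega >= 1`, and tends
#' to `min(PET/P, 1)` as `omega` grows. Evaluated in a scale-stable form so
#' large dryness ratios and omegas do not overflow.
#'
#' @param pet PET `eco_grid` (mm/yr).
#' @param p Annual precipitation `eco_grid` (mm/yr, > 0 where evaluated).
#' @param omega Omega `eco_grid` from [omega_grid()] (values >= 1).
#' @return An `eco_grid` of AET/P fractions in \[0, 1\].
#' @export
aet_fraction_vegetated <- function(pet, p, omega) {
  stopifnot(is_grid(pet), is_grid(p), is_grid(omega))
  assert_aligned(list(pet = pet, p = p, omega = omega))
  om <- omega$values
  if (any(om[!is.na(om)] < 1))
    stop("omega must be >= 1 (the curve leaves [0, 1] otherwise)",
         call. = FALSE)
  ratio <- pet$values / p$values
  # (1 + x^w)^(1/w) computed as m * (m^-w + (x/m)^w)^(1/w), m = max(x, 1),
  # so the inner powers never exceed 1
  m <- pmax(ratio, 1)
  term <- m * (m^(-om) + (ratio / m)^om)^(1 / om)
  frac <- 1 + ratio - term
  frac <- pmin(pmax(frac, 0), 1)  # clamp roundoff at the boundaries
  grid_like(p, frac)
}

#' Capped actual evapotranspiration (non-vegetated cells)
#'
#' On land without a vegetated water balance (waters, construction, bare
#' land), actual evapotranspiration is the Kc-scaled reference demand capped
#' by the rainfall supply: `AET = min(Kc * ET0, P)`.
#'
#' @param et0 Reference evapotranspiration `eco_grid` (mm/yr).
#' @param p Annual precipitation `eco_grid` (mm/yr).
#' @param landuse An `eco_landuse`.
#' @param table Biophysical table.
#' @return An `eco_grid` of AET (mm/yr).
#' @export
aet_unvegetated <- function(et0, p, landuse, table = biophysical_table()) {
  stopifnot(is_grid(et0), is_grid(p), is_landuse(landuse))
  assert_aligned(list(et0 = et0, p = p, landuse = landuse$grid))
  kc <- class_param_grid(landuse, table, "kc", level = "primary")
  grid_like(p, pmin(kc * et0$values, p$values))
}

#' Annual water yield
#'
#' The water balance residual `Y = P - AET`, reported as water conservation
#' throughout the assessment: rainfall not returned to the atmosphere. Requires
#' `AET <= P`, which the vegetated/non-vegetated dispatch guarantees.
#'
#' @param p Annual precipitation `eco_grid` (mm/yr).
#' @param aet Actual evapotranspiration `eco_grid` (mm/yr).
#' @param tol Tolerance on the `AET <= P` contract (default 1e-9).
#' @return An `eco_grid` of yield (mm/yr) in \[0, P\].
#' @export
water_yield <- function(p, aet, tol = 1e-9) {
  stopifnot(is_grid(p), is_grid(aet))
  assert_aligned(list(p = p, aet = aet))
  diff <- aet$values - p$values
  if (any(diff[!is.na(diff)] > tol))
    stop("AET exceeds P on some cells: upstream dispatch violated its contract",
         call. = FALSE)
  grid_like(p, pmax(p$values - aet$values, 0))
}

#' Full water stage: PET, AET dispatch, yield
#'
#' Applies the Budyko curve on vegetated classes and the rainfall-capped
#' demand rule elsewhere, then takes the yield `Y = P - AET`.
#'
#' @param landuse An `eco_landuse`.
#' @param p Annual precipitation `eco_grid` (mm/yr).
#' @param et0 Reference evapotranspiration `eco_grid` (mm/yr).
#' @param awc Plant-available water capacity `eco_grid` (mm).
#' @param table Biophysical table.
#' @param z_coeff Seasonality constant Z in \[1, 30\].
#' @return A list of `eco_grid`s: `pet`, `aet`, `yield`.
#' @export
water_stage <- function(landuse, p, et0, awc, table = biophysical_table(),
                        z_coeff = 10) {
  stopifnot(is_landuse(landuse))
  assert_aligned(list(landuse = landuse$grid, p = p, et0 = et0, awc = awc))
  pet <- pet_grid(et0, landuse, table)
  veg <- class_param_grid(landuse, table, "vegetated", level = "primary") == 1
  om <- omega_grid(p, awc, z_coeff)
  frac <- aet_fraction_vegetated(pet, p, om)
  aet_v <- frac$values * p$values
  aet_u <- aet_unvegetated(et0, p, landuse, table)$values
  aet <- ifelse(veg, aet_v, aet_u)
  aet[is.na(veg)] <- NA_real_
  aet <- grid_like(p, aet)
  list(pet = pet, aet = aet, yield = water_yield(p, aet))
}
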