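#' Per-cell carbon storage
#'
#' Sums the four carbon pools (aboveground biomass, belowground biomass,
#' soil, dead organic matter) for each cell's secondary land-use class and
#' multiplies by the cell area, giving tonnes of carbon per cell. Densities
#' are t/ha; a cell of side `cell_size` metres covers `cell_size^2 / 1e4` ha.
#'
#' @param landuse An `eco_landuse`.
#' @param table Carbon density table, as from [carbon_density_table()]:
#'   one row per secondary class, columns `c_above`, `c_below`, `c_soil`,
#'   `c_dead` in t/ha.
#' @return An `eco_grid` of carbon stock in t per cell.
#' @export
carbon_per_cell <- function(landuse, table = carbon_density_table()) {
  stopifnot(is_landuse(landuse))
  dens <- class_param_grid(landuse, table, "c_above", level = "secondary") +
    class_param_grid(landuse, table, "c_below", level = "secondary") +
    class_param_grid(landuse, table, "c_soil", level = "secondary") +
    class_param_grid(landuse, table, "c_dead", level = "secondary")
  cell_area_ha <- landuse$grid$cell_size^2 / 1e4
  grid_like(landuse$grid, dens * cell_area_ha)
}

#' Total carbon stock of a map
#'
#' @param carbon An `eco_grid` of t-per-cell stocks, from [carbon_per_cell()].
#' @return Total stock in tonnes (0 for an all-nodata grid).
#' @export
total_carbon <- function(carbon) {
  stopifnot(is_grid(carbon))
  sum(carbon$values, na.rm = TRUE)
}
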