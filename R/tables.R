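#' Packaged parameter tables
#'
#' The package ships the full parameterisation used for mountainous,
#' woodland-dominated landscapes in central China as plain CSVs under
#' `inst/extdata`: the threat-source roster (maximum influence distance,
#' weight, decay kind, source definition), per-class habitat suitability and
#' threat sensitivities, four-pool carbon densities by secondary land-use
#' class, the biophysical table (evapotranspiration coefficient, root depth,
#' vegetated flag), and USLE cover-management / support-practice factors.
#' Each loader returns the packaged table, or parses a user-supplied CSV with
#' the same columns.
#'
#' @param path Optional path to a CSV overriding the packaged table.
#' @return A tibble.
#' @name param_tables
NULL

read_param_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

pkg_extdata <- function(file) {
  system.file("extdata", file, package = "ecozoner", mustWork = TRUE)
}

#' @rdname param_tables
#' @export
landuse_code_table <- function(path = NULL) {
  read_param_csv(path %||% pkg_extdata("landuse_codes.csv"))
}

#' @rdname param_tables
#' @export
threat_table <- function(path = NULL) {
  tab <- read_param_csv(path %||% pkg_extdata("threats.csv"))
  need <- c("name", "max_dist_km", "weight", "decay", "source")
  stopifnot(all(need %in% names(tab)))
  if (any(tab$max_dist_km <= 0)) stop("threat max_dist_km must be > 0")
  if (any(tab$weight <= 0 | tab$weight > 1))
    stop("threat weights must lie in (0, 1]")
  if (!all(tab$decay %in% c("linear", "exponential")))
    stop("threat decay must be 'linear' or 'exponential'")
  tab
}

#' @rdname param_tables
#' @export
sensitivity_table <- function(path = NULL) {
  tab <- read_param_csv(path %||% pkg_extdata("sensitivity.csv"))
  stopifnot("class" %in% names(tab), "habitat" %in% names(tab))
  num <- tab[setdiff(names(tab), "class")]
  if (any(num < 0 | num > 1))
    stop("habitat suitability and sensitivities must lie in [0, 1]")
  tab
}

#' @rdname param_tables
#' @export
carbon_density_table <- function(path = NULL) {
  tab <- read_param_csv(path %||% pkg_extdata("carbon_density.csv"))
  need <- c("class", "c_above", "c_below", "c_soil", "c_dead")
  stopifnot(all(need %in% names(tab)))
  if (any(tab[, need[-1L]] < 0)) stop("carbon densities must be >= 0")
  tab
}

#' @rdname param_tables
#' @export
biophysical_table <- function(path = NULL) {
  tab <- read_param_csv(path %||% pkg_extdata("biophysical.csv"))
  need <- c("class", "kc", "root_depth_mm", "vegetated")
  stopifnot(all(need %in% names(tab)))
  if (any(tab$kc < 0)) stop("kc must be >= 0")
  if (!all(tab$vegetated %in% c(0L, 1L))) stop("vegetated flag must be 0/1")
  tab
}

#' @rdname param_tables
#' @export
cp_table <- function(path = NULL) {
  tab <- read_param_csv(path %||% pkg_extdata("cp_factors.csv"))
  need <- c("class", "c_factor", "p_factor")
  stopifnot(all(need %in% names(tab)))
  if (any(tab$c_factor < 0 | tab$c_factor > 1 |
          tab$p_factor < 0 | tab$p_factor > 1))
    stop("C and P factors must lie in [0, 1]")
  tab
}
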