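#' Land-use grid with a two-level class legend
#'
#' Couples an integer raster of secondary land-use codes with a code table
#' mapping each code to a secondary class name and one of the six primary
#' classes (`arable`, `woodland`, `grassland`, `waters`, `construction`,
#' `unused`). Habitat sensitivity, biophysical and cover/practice parameters
#' are keyed by primary class; carbon densities by secondary class.
#'
#' @param codes Integer matrix of secondary codes (`NA` = nodata), or an
#'   `eco_grid` holding them.
#' @param code_table Data frame with columns `code`, `name`, `primary`;
#'   defaults to the packaged legend ([landuse_code_table()]).
#' @param cell_size,xll,yll Geometry, used when `codes` is a bare matrix.
#' @return An object of class `eco_landuse`.
#' @export
eco_landuse <- function(codes, code_table = landuse_code_table(),
                        cell_size = NULL, xll = 0, yll = 0) {
  if (is_grid(codes)) {
    g <- codes
  } else {
    stopifnot(!is.null(cell_size))
    g <- eco_grid(codes, cell_size, xll, yll)
  }
  code_table <- tibble::as_tibble(code_table)
  stopifnot(all(c("code", "name", "primary") %in% names(code_table)))
  bad <- setdiff(unique(code_table$primary), primary_classes())
  if (length(bad))
    stop("unknown primary class in code table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  present <- unique(g$values[!is.na(g$values)])
  missing <- setdiff(present, code_table$code)
  if (length(missing))
    stop("land-use codes absent from code table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(grid = g, code_table = code_table), class = "eco_landuse")
}

is_landuse <- function(x) inherits(x, "eco_landuse")

#' The six primary land-use classes
#' @return Character vector in canonical order.
#' @export
primary_classes <- function() {
  c("arable", "woodland", "grassland", "waters", "construction", "unused")
}

#' @export
print.eco_landuse <- function(x, ...) {
  cat("<eco_landuse>\n")
  print(x$grid)
  tab <- table(landuse_primary(x))
  cat("  primary classes: ",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Per-cell primary class of a land-use grid
#'
#' @param landuse An `eco_landuse`.
#' @return Character matrix of primary class names (`NA` on nodata).
#' @export
landuse_primary <- function(landuse) {
  stopifnot(is_landuse(landuse))
  v <- landuse$grid$values
  idx <- match(v, landuse$code_table$code)
  out <- landuse$code_table$primary[idx]
  matrix(out, nrow(v), ncol(v))
}

#' Per-cell secondary class name of a land-use grid
#'
#' @param landuse An `eco_landuse`.
#' @return Character matrix of secondary class names (`NA` on nodata).
#' @export
landuse_secondary <- function(landuse) {
  stopifnot(is_landuse(landuse))
  v <- landuse$grid$values
  idx <- match(v, landuse$code_table$code)
  matrix(landuse$code_table$name[idx], nrow(v), ncol(v))
}

#' Look up a per-class parameter on the grid
#'
#' Scatter a parameter keyed by class onto every cell of the map.
#'
#' @param landuse An `eco_landuse`.
#' @param table Data frame with the key column and the parameter column.
#' @param value Name of the parameter column in `table`.
#' @param key Name of the class key column in `table` (default `"class"`).
#' @param level `"primary"` or `"secondary"` keying.
#' @return Numeric matrix of per-cell parameter values.
#' @export
class_param_grid <- function(landuse, table, value, key = "class",
                             level = c("primary", "secondary")) {
  level <- match.arg(level)
  cls <- if (level == "primary") landuse_primary(landuse)
         else landuse_secondary(landuse)
  present <- unique(cls[!is.na(cls)])
  missing <- setdiff(present, table[[key]])
  if (length(missing))
    stop(sprintf("no '%s' row for class(es): %s", value,
                 paste(missing, collapse = ", ")), call. = FALSE)
  idx <- match(cls, table[[key]])
  matrix(as.numeric(table[[value]][idx]), nrow(cls), ncol(cls))
}
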