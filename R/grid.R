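#' Raster grid object
#'
#' A minimal single-band raster: a numeric matrix (row 1 = northernmost row,
#' `NA` = nodata), a square cell size in metres, and the coordinates of the
#' lower-left corner. All layers entering the pipeline must share the same
#' geometry; see [assert_aligned()].
#'
#' @param values Numeric matrix; `NA` marks nodata cells.
#' @param cell_size Cell edge length in metres (> 0; cells are square).
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @return An object of class `eco_grid`.
#' @examples
#' g <- eco_grid(matrix(runif(25), 5, 5), cell_size = 30)
#' g
#' @export
eco_grid <- function(values, cell_size, xll = 0, yll = 0) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll)),
    class = "eco_grid"
  )
}

#' @export
print.eco_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<eco_grid> %d x %d cells, %g m resolution\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  origin (lower-left): (%g, %g)\n", x$xll, x$yll))
  ok <- !is.na(v)
  if (any(ok)) {
    cat(sprintf("  values: [%g, %g], nodata cells: %d\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  } else {
    cat("  values: all nodata\n")
  }
  invisible(x)
}

#' @export
dim.eco_grid <- function(x) dim(x$values)

is_grid <- function(x) inherits(x, "eco_grid")

#' Build a grid with the same geometry as a template
#'
#' @param template An `eco_grid` supplying geometry.
#' @param values Matrix (or scalar, recycled) of new cell values.
#' @return An `eco_grid`.
#' @export
grid_like <- function(template, values) {
  stopifnot(is_grid(template))
  if (length(values) == 1L)
    values <- matrix(values, nrow(template$values), ncol(template$values))
  stopifnot(identical(dim(values), dim(template$values)))
  eco_grid(values, template$cell_size, template$xll, template$yll)
}

#' Nodata mask of a grid
#'
#' @param x An `eco_grid`.
#' @return Logical matrix, `TRUE` where the cell is nodata.
#' @export
nodata_mask <- function(x) {
  stopifnot(is_grid(x))
  is.na(x$values)
}

#' Read a single-band raster
#'
#' Reads an ESRI ASCII grid (`ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value` header followed by row-major values, northernmost row first).
#' Nodata cells become `NA`. Non-square cells (separate `dx`/`dy` headers) are
#' rejected. GeoTIFF is not supported by this build and is rejected with a
#' clear message; ASCII grid is the interchange format (every common GIS
#' imports and exports it losslessly for single-band data).
#'
#' @param path Path to the raster file.
#' @param format `"esri_ascii"` (default) or `"geotiff"` (rejected).
#' @return An `eco_grid`.
#' @export
read_grid <- function(path, format = c("esri_ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff") {
    stop("GeoTIFF input is not supported; convert to ESRI ASCII grid ",
         "(e.g. `gdal_translate -of AAIGrid`) and use format = \"esri_ascii\".",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) < 2L) stop("malformed ASCII grid header line: ", lines[i],
                                 call. = FALSE)
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header incomplete; need ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(c("dx", "dy") %in% names(hdr)))
    stop("non-square cells (dx/dy header) are not supported", call. = FALSE)
  if (is.null(hdr$cellsize)) stop("ASCII grid header lacks cellsize", call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid body has %d values, expected %d x %d = %d",
                 length(vals), nr, nc, nr * nc), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  eco_grid(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner)
}

#' Write a grid as an ESRI ASCII raster
#'
#' The inverse of [read_grid()]: `read_grid(write_grid(g, f))` restores
#' values, mask and geometry exactly (values are written with full precision).
#' Output is byte-deterministic for identical input.
#'
#' @param x An `eco_grid`.
#' @param path Output file path.
#' @param nodata Sentinel written for `NA` cells.
#' @param digits Significant digits written (default 17, which round-trips
#'   IEEE doubles exactly).
#' @return `path`, invisibly.
#' @export
write_grid <- function(x, path, nodata = -9999, digits = 17) {
  stopifnot(is_grid(x))
  v <- x$values
  if (any(v[!is.na(v)] == nodata))
    stop("grid contains the nodata sentinel ", nodata, " as a real value",
         call. = FALSE)
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", x$xll),
    sprintf("yllcorner %.10g", x$yll),
    sprintf("cellsize %.10g", x$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(v, 1L, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Check that raster layers share one geometry
#'
#' All stages of the pipeline require pre-aligned inputs (same shape, cell
#' size and origin); this package validates alignment but never resamples.
#'
#' @param grids A named (or unnamed) list of `eco_grid` objects.
#' @param tol Numeric tolerance on cell size and origin (default 1e-6).
#' @return `TRUE`, invisibly, if aligned; otherwise an error naming the first
#'   offending layer.
#' @export
assert_aligned <- function(grids, tol = 1e-6) {
  stopifnot(is.list(grids), length(grids) >= 1L)
  nm <- names(grids)
  if (is.null(nm)) nm <- paste0("layer", seq_along(grids))
  nm[nm == ""] <- paste0("layer", which(nm == ""))
  ref <- grids[[1L]]
  stopifnot(is_grid(ref))
  for (k in seq_along(grids)[-1L]) {
    g <- grids[[k]]
    stopifnot(is_grid(g))
    if (!identical(dim(g$values), dim(ref$values)))
      stop(sprintf("layer '%s' shape (%d,%d) does not match '%s' (%d,%d)",
                   nm[k], nrow(g$values), ncol(g$values),
                   nm[1L], nrow(ref$values), ncol(ref$values)), call. = FALSE)
    if (abs(g$cell_size - ref$cell_size) > tol)
      stop(sprintf("layer '%s' cell size %g does not match '%s' cell size %g",
                   nm[k], g$cell_size, nm[1L], ref$cell_size), call. = FALSE)
    if (abs(g$xll - ref$xll) > tol || abs(g$yll - ref$yll) > tol)
      stop(sprintf("layer '%s' origin (%g,%g) does not match '%s' (%g,%g)",
                   nm[k], g$xll, g$yll, nm[1L], ref$xll, ref$yll),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Euclidean distance to the nearest source cell
#'
#' Exact centre-to-centre Euclidean distance from every cell to the nearest
#' `TRUE` cell of `source_mask`, in metres; 0 on source cells themselves.
#' Backed by the exact Euclidean distance transform in \pkg{EBImage}.
#'
#' @param source_mask Logical matrix (or 0/1 `eco_grid`) marking source cells.
#' @param cell_size Cell size in metres; taken from the grid when
#'   `source_mask` is an `eco_grid`.
#' @return An `eco_grid` of distances in metres.
#' @export
distance_field <- function(source_mask, cell_size = NULL) {
  g <- NULL
  if (is_grid(source_mask)) {
    g <- source_mask
    if (is.null(cell_size)) cell_size <- g$cell_size
    source_mask <- !is.na(g$values) & g$values != 0
  }
  stopifnot(is.matrix(source_mask), is.logical(source_mask) ||
              all(source_mask %in% c(0, 1)))
  src <- source_mask != 0
  if (!any(src)) stop("distance_field: source mask has no source cells",
                      call. = FALSE)
  # distmap() measures each positive pixel's distance to the nearest zero
  # pixel, so feed it the complement of the source set
  d_cells <- EBImage::distmap(matrix(as.numeric(!src), nrow(src), ncol(src)),
                              metric = "euclidean")
  d <- d_cells * cell_size
  if (!is.null(g)) grid_like(g, d) else eco_grid(d, cell_size)
}

#' Zonal summary of a value layer over land-use classes
#'
#' One row per land-use class present, with one column per requested
#' statistic, the layout used for per-class service reporting (mean habitat
#' index, summed carbon and soil retention, mean water yield). Nodata cells in
#' either layer are excluded; `sum` is in value-units x cells (multiply by the
#' per-cell area to convert to mass or volume totals).
#'
#' @param value An `eco_grid` of cell values.
#' @param landuse An [eco_landuse] aligned with `value`.
#' @param stat Character vector from `c("mean", "sum")`.
#' @param level Summarise by `"primary"` class (default) or `"secondary"` code.
#' @return A tibble keyed by class with one column per statistic.
#' @export
zonal_summary <- function(value, landuse, stat = "mean",
                          level = c("primary", "secondary")) {
  stopifnot(is_grid(value), is_landuse(landuse))
  stat <- match.arg(stat, c("mean", "sum"), several.ok = TRUE)
  level <- match.arg(level)
  assert_aligned(list(value = value, landuse = landuse$grid))
  key <- if (level == "primary") landuse_primary(landuse) else landuse$grid$values
  ok <- !is.na(value$values) & !is.na(key)
  if (!any(ok))
    stop("zonal_summary: no cells where value and land use are both valid",
         call. = FALSE)
  df <- tibble::tibble(class = as.vector(key[ok]),
                       value = as.vector(value$values[ok]))
  out <- dplyr::group_by(df, .data$class)
  fns <- list(mean = ~ mean(.x), sum = ~ sum(.x))[stat]
  out <- dplyr::summarise(
    out, dplyr::across("value", fns, .names = "{.fn}"), n_cells = dplyr::n(),
    .groups = "drop")
  dplyr::arrange(out, .data$class)
}

#' Raster heat-map of a grid
#'
#' @param object An `eco_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eco_grid <- function(object, ...) {
  v <- object$values
  df <- tidyr::expand_grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  df$x <- object$xll + (df$col - 0.5) * object$cell_size
  df$y <- object$yll + (nrow(v) - df$row + 0.5) * object$cell_size
  df$value <- v[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
}
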