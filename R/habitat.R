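#' Habitat-quality model parameters
#'
#' @param k Half-saturation constant of the degradation response (> 0): the
#'   degradation level at which habitat quality falls to half its potential.
#'   Default 0.5, the conventional value for degradation indices on \[0, 1\].
#' @param z_exponent Sharpness exponent of the saturation curve; fixed at 2.5
#'   by convention for this model family.
#' @param accessibility Optional `eco_grid` in \[0, 1\] scaling threat
#'   exposure per cell (1 = fully accessible). Default: 1 everywhere.
#' @return A list of class `habitat_params`.
#' @export
habitat_params <- function(k = 0.5, z_exponent = 2.5, accessibility = NULL) {
  stopifnot(is.numeric(k), length(k) == 1L, k > 0,
            is.numeric(z_exponent), length(z_exponent) == 1L)
  if (!is.null(accessibility)) {
    stopifnot(is_grid(accessibility))
    a <- accessibility$values
    if (any(a[!is.na(a)] < 0 | a[!is.na(a)] > 1))
      stop("accessibility must lie in [0, 1]", call. = FALSE)
  }
  structure(list(k = k, z_exponent = z_exponent,
                 accessibility = accessibility),
            class = "habitat_params")
}

#' Binary source layer for one threat
#'
#' Resolves a threat's `source` definition against the land-use map (source
#' string `"codes:11|12"`: cells carrying those secondary codes) or an
#' external raster (`"raster:<name>"`, looked up in `extra_rasters`, e.g. a
#' rasterised road network). The returned indicator is 1 on stressor cells.
#'
#' @param landuse An `eco_landuse`.
#' @param threat One row of [threat_table()] (data frame or list).
#' @param extra_rasters Named list of `eco_grid`s for `raster:` sources.
#' @return An `eco_grid` of 0/1 values.
#' @export
threat_sources <- function(landuse, threat, extra_rasters = list()) {
  stopifnot(is_landuse(landuse))
  src <- threat$source
  v <- landuse$grid$values
  if (grepl("^codes:", src)) {
    codes <- as.numeric(strsplit(sub("^codes:", "", src), "\\|")[[1]])
    unknown <- setdiff(codes, landuse$code_table$code)
    if (length(unknown))
      stop(sprintf("threat '%s': source code(s) %s not in code table",
                   threat$name, paste(unknown, collapse = ", ")),
           call. = FALSE)
    ind <- matrix(as.numeric(v %in% codes), nrow(v), ncol(v))
  } else if (grepl("^raster:", src)) {
    key <- sub("^raster:", "", src)
    r <- extra_rasters[[key]]
    if (is.null(r))
      stop(sprintf("threat '%s' needs external raster '%s'", threat$name, key),
           call. = FALSE)
    stopifnot(is_grid(r))
    assert_aligned(list(landuse = landuse$grid, source = r))
    ind <- matrix(as.numeric(!is.na(r$values) & r$values != 0),
                  nrow(v), ncol(v))
  } else {
    stop(sprintf("threat '%s': unrecognised source '%s'", threat$name, src),
         call. = FALSE)
  }
  grid_like(landuse$grid, ind)
}

#' Distance-decay of threat influence
#'
#' Influence of a stressor at distance `d` from its nearest source, on
#' \[0, 1\]: `linear` is `max(0, 1 - d/d_max)`; `exponential` is
#' `exp(-(2.99/d_max) * d)` truncated to 0 beyond `d_max`, so influence has
#' fallen to about 5\% at the maximum impact distance.
#'
#' @param d Distance(s) in metres, >= 0.
#' @param d_max Maximum impact distance in metres (> 0).
#' @param decay `"linear"` or `"exponential"`.
#' @return Influence value(s) in \[0, 1\].
#' @export
decay_factor <- function(d, d_max, decay = c("linear", "exponential")) {
  decay <- match.arg(decay)
  if (!is.numeric(d_max) || length(d_max) != 1L || d_max <= 0)
    stop("d_max must be a single value > 0", call. = FALSE)
  if (any(d[!is.na(d)] < 0)) stop("distances must be >= 0", call. = FALSE)
  if (decay == "linear") {
    pmax(0, 1 - d / d_max)
  } else {
    ifelse(d <= d_max, exp(-(2.99 / d_max) * d), 0)
  }
}

#' Habitat degradation index
#'
#' Per-cell degradation from all threats: each threat contributes its
#' normalised weight times the distance-decayed influence of the nearest
#' source cell, scaled by the cell's accessibility and the sensitivity of the
#' cell's land-use class to that threat. Threats with no source cells on the
#' map contribute zero but still take part in weight normalisation, so
#' rescaling all weights by a common factor leaves the index unchanged.
#'
#' @param landuse An `eco_landuse`.
#' @param threats Threat roster, as from [threat_table()].
#' @param sens Sensitivity table, as from [sensitivity_table()]; must hold one
#'   column per threat name.
#' @param params A [habitat_params()] object.
#' @param extra_rasters Named list of external source rasters (see
#'   [threat_sources()]).
#' @return An `eco_grid` of degradation values (>= 0).
#' @export
degradation <- function(landuse, threats = threat_table(),
                        sens = sensitivity_table(),
                        params = habitat_params(),
                        extra_rasters = list()) {
  stopifnot(is_landuse(landuse), inherits(params, "habitat_params"))
  threats <- tibble::as_tibble(threats)
  miss <- setdiff(threats$name, names(sens))
  if (length(miss))
    stop("sensitivity table lacks column(s) for threat(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  g <- landuse$grid
  w_sum <- sum(threats$weight)
  beta <- if (is.null(params$accessibility)) 1 else {
    assert_aligned(list(landuse = g, accessibility = params$accessibility))
    params$accessibility$values
  }
  D <- matrix(0, nrow(g$values), ncol(g$values))
  for (i in seq_len(nrow(threats))) {
    th <- threats[i, ]
    src <- threat_sources(landuse, th, extra_rasters)
    if (!any(src$values != 0, na.rm = TRUE)) next  # vacuous threat
    d <- distance_field(src)$values
    infl <- decay_factor(d, th$max_dist_km * 1000, th$decay)
    s_grid <- class_param_grid(landuse, sens, th$name, level = "primary")
    D <- D + (th$weight / w_sum) * infl * beta * s_grid
  }
  D[is.na(landuse_primary(landuse))] <- NA_real_
  grid_like(g, D)
}

#' Habitat quality from degradation
#'
#' Converts the degradation index into habitat quality by scaling each
#' class's habitat suitability with a half-saturation response:
#' `Q = H * (1 - D^z / (D^z + k^z))`. Quality equals the suitability `H`
#' where degradation is zero, and half of it where `D` equals `k`.
#'
#' @param degradation An `eco_grid` of degradation values (>= 0), from
#'   [degradation()].
#' @param landuse An `eco_landuse`.
#' @param sens Sensitivity table carrying the `habitat` suitability column.
#' @param params A [habitat_params()] object.
#' @return An `eco_grid` of habitat quality in \[0, 1\].
#' @export
habitat_quality <- function(degradation, landuse, sens = sensitivity_table(),
                            params = habitat_params()) {
  stopifnot(is_grid(degradation), is_landuse(landuse),
            inherits(params, "habitat_params"))
  assert_aligned(list(degradation = degradation, landuse = landuse$grid))
  D <- degradation$values
  if (any(D[!is.na(D)] < 0)) stop("degradation must be >= 0", call. = FALSE)
  H <- class_param_grid(landuse, sens, "habitat", level = "primary")
  z <- params$z_exponent
  Dz <- D^z
  Q <- H * (1 - Dz / (Dz + params$k^z))
  grid_like(degradation, Q)
}

#' Full habitat stage: degradation + quality
#'
#' @inheritParams degradation
#' @return A list with `eco_grid`s `degradation` and `quality`.
#' @export
habitat_stage <- function(landuse, threats = threat_table(),
                          sens = sensitivity_table(),
                          params = habitat_params(),
                          extra_rasters = list()) {
  D <- degradation(landuse, threats, sens, params, extra_rasters)
  list(degradation = D,
       quality = habitat_quality(D, landuse, sens, params))
}
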