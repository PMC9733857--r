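#' Per-cell indicator matrix from service layers
#'
#' Stacks the four service rasters into a cells-by-indicators matrix over the
#' cells where every layer is valid, remembering the cell positions so any
#' column can be scattered back onto the map. Column order is as supplied and
#' recorded in the object.
#'
#' @param services Named list of aligned `eco_grid`s, one per indicator, in
#'   the declared order (conventionally habitat quality, carbon, water yield,
#'   soil retention).
#' @return An object of class `eco_indicators`: fields `values` (numeric
#'   matrix), `indicators` (column names), `cells` (linear cell indices),
#'   `template` (an `eco_grid` supplying geometry), `normalized` (logical).
#' @export
build_matrix <- function(services) {
  stopifnot(is.list(services), length(services) >= 1L,
            !is.null(names(services)), all(nzchar(names(services))),
            all(vapply(services, is_grid, logical(1))))
  assert_aligned(services)
  masks <- vapply(services, function(g) !is.na(g$values),
                  matrix(TRUE, nrow(services[[1L]]$values),
                         ncol(services[[1L]]$values)))
  dim(masks) <- c(length(services[[1L]]$values), length(services))
  valid <- rowSums(masks) == length(services)
  if (!any(valid))
    stop("no cells are valid in all service layers", call. = FALSE)
  cells <- which(valid)
  vals <- vapply(services, function(g) g$values[cells],
                 numeric(length(cells)))
  vals <- matrix(vals, ncol = length(services),
                 dimnames = list(NULL, names(services)))
  structure(list(values = vals, indicators = names(services), cells = cells,
                 template = grid_like(services[[1L]], NA_real_),
                 normalized = FALSE),
            class = "eco_indicators")
}

#' @export
print.eco_indicators <- function(x, ...) {
  cat(sprintf("<eco_indicators> %d cells x %d indicators (%s)%s\n",
              nrow(x$values), ncol(x$values),
              paste(x$indicators, collapse = ", "),
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' @export
as_tibble.eco_indicators <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$values))
}

#' Scatter one indicator column back onto the map
#'
#' @param x An `eco_indicators` object.
#' @param column Column name or index.
#' @return An `eco_grid` with the column's values at their cells, `NA`
#'   elsewhere.
#' @export
matrix_to_grid <- function(x, column) {
  stopifnot(inherits(x, "eco_indicators"))
  g <- x$template
  g$values[x$cells] <- x$values[, column]
  g
}

#' Min-max normalisation of the indicator matrix
#'
#' Rescales each column to \[0, 1\] by its extremes: benefit columns as
#' `(x - min) / (max - min)`, cost columns reflected as
#' `(max - x) / (max - min)`. A constant column carries no ranking
#' information; it is set to 0.5 everywhere and flagged with a warning (its
#' entropy weight then collapses toward zero).
#'
#' @param x An `eco_indicators` object with raw values.
#' @param orientation `"benefit"` or `"cost"`, recycled across columns. All
#'   four services are benefits in the importance framing.
#' @return The `eco_indicators` object with normalised values.
#' @export
normalize_indicators <- function(x, orientation = "benefit") {
  stopifnot(inherits(x, "eco_indicators"))
  m <- ncol(x$values)
  orientation <- rep_len(match.arg(orientation, c("benefit", "cost"),
                                   several.ok = TRUE), m)
  out <- x$values
  const <- logical(m)
  for (i in seq_len(m)) {
    col <- x$values[, i]
    rng <- range(col)
    if (rng[1] == rng[2]) {
      out[, i] <- 0.5
      const[i] <- TRUE
    } else if (orientation[i] == "benefit") {
      out[, i] <- (col - rng[1]) / (rng[2] - rng[1])
    } else {
      out[, i] <- (rng[2] - col) / (rng[2] - rng[1])
    }
  }
  if (any(const))
    warning("constant indicator column(s) set to 0.5: ",
            paste(x$indicators[const], collapse = ", "), call. = FALSE)
  x$values <- out
  x$normalized <- TRUE
  x$constant <- x$indicators[const]
  x
}

#' Entropy weights of the indicators
#'
#' Objective weighting by information entropy at the grid-cell scale: with
#' normalised values `p_ij` (cells j, indicators i), the cell shares are
#' `f_ij = p_ij / sum_j p_ij`, the entropy of indicator i is
#' `H_i = -(1/ln n) * sum_j f_ij ln f_ij` (with `0 ln 0 = 0`), and the weight
#' is `W_i = (1 - H_i) / (m - sum_i H_i)`. Indicators whose normalised
#' distribution is more dispersed (less uniform across cells) carry more
#' information and receive larger weights; weights are non-negative and sum
#' to one.
#'
#' @param x An `eco_indicators` object with normalised values (see
#'   [normalize_indicators()]).
#' @return An object of class `eco_weights`: a tibble with columns
#'   `indicator`, `entropy`, `weight`, plus attributes `n_cells`.
#' @export
entropy_weights <- function(x) {
  stopifnot(inherits(x, "eco_indicators"))
  if (!isTRUE(x$normalized))
    stop("entropy_weights() expects a normalised matrix; ",
         "call normalize_indicators() first", call. = FALSE)
  p <- x$values
  n <- nrow(p); m <- ncol(p)
  if (n < 2L) stop("need at least 2 cells to compute entropy", call. = FALSE)
  csum <- colSums(p)
  if (all(csum == 0))
    stop("all indicator columns are zero; weights are undefined",
         call. = FALSE)
  H <- vapply(seq_len(m), function(i) {
    if (csum[i] == 0) return(1)  # no information: maximal entropy
    f <- p[, i] / csum[i]
    f <- f[f > 0]               # 0 * ln 0 := 0
    -sum(f * log(f)) / log(n)
  }, numeric(1))
  if (sum(1 - H) <= 0)
    stop("all indicators are uninformative (entropy 1); weights undefined",
         call. = FALSE)
  W <- (1 - H) / (m - sum(H))
  out <- tibble::tibble(indicator = x$indicators, entropy = H, weight = W)
  structure(out, class = c("eco_weights", class(out)), n_cells = n)
}

#' @export
tidy.eco_weights <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("indicator", "entropy", "weight")])
}

#' @export
glance.eco_weights <- function(x, ...) {
  tibble::tibble(n_cells = attr(x, "n_cells"),
                 n_indicators = nrow(x),
                 entropy_total = sum(x$entropy))
}

#' Weighted importance score
#'
#' The weighted sum `R = sum_i W_i S_i` of the normalised service values,
#' scattered back onto the map. Lies in \[0, 1\] because the weights sum to
#' one and each `S_i` is in \[0, 1\].
#'
#' @param x An `eco_indicators` object with normalised values.
#' @param weights An `eco_weights` object (or a data frame with `indicator`
#'   and `weight` columns matching the matrix).
#' @return An `eco_grid` of importance scores.
#' @export
importance_score <- function(x, weights) {
  stopifnot(inherits(x, "eco_indicators"))
  if (!isTRUE(x$normalized))
    stop("importance_score() expects normalised indicator values",
         call. = FALSE)
  w <- weights$weight[match(x$indicators, weights$indicator)]
  if (anyNA(w))
    stop("weights missing for indicator(s): ",
         paste(x$indicators[is.na(w)], collapse = ", "), call. = FALSE)
  if (abs(sum(w) - 1) > 1e-6)
    stop("weights must sum to 1", call. = FALSE)
  score <- as.vector(x$values %*% w)
  g <- x$template
  g$values[x$cells] <- score
  g
}

#' Jenks natural-breaks classification
#'
#' Exact Fisher-Jenks optimal partition of a numeric vector into `n_classes`
#' contiguous classes minimising the total within-class sum of squared
#' deviations, by dynamic programming. For vectors longer than `sample_cap`
#' the breaks are fitted on a deterministic quantile-thinned subsample of
#' that size (evenly spaced order statistics — the standard practice for
#' map-scale natural breaks) and then applied to all values; below the cap
#' the optimum is exact.
#'
#' @param x Numeric vector (NAs dropped for fitting).
#' @param n_classes Number of classes (default 4).
#' @param sample_cap Above this length the DP runs on evenly spaced order
#'   statistics (default 6000). Set to `Inf` to force the exact solution.
#' @return A list: `breaks` (the `n_classes - 1` upper class bounds,
#'   ascending), `classes` (integer vector, 1 = lowest tier, `NA` where `x`
#'   is `NA`), `n_classes`.
#' @export
jenks_classify <- function(x, n_classes = 4, sample_cap = 6000) {
  stopifnot(is.numeric(x), n_classes >= 1)
  xv <- x[!is.na(x)]
  if (length(unique(xv)) < n_classes)
    stop(sprintf("need at least %d distinct values for %d classes",
                 n_classes, n_classes), call. = FALSE)
  if (n_classes == 1L) {
    cls <- ifelse(is.na(x), NA_integer_, 1L)
    return(list(breaks = numeric(0), classes = cls, n_classes = 1L))
  }
  s <- sort(xv)
  if (length(s) > sample_cap) {
    take <- unique(round(seq(1L, length(s), length.out = sample_cap)))
    s <- s[take]
  }
  idx <- jenks_breaks_idx(s, as.integer(n_classes))
  breaks <- s[idx]
  cls <- findInterval(x, breaks, left.open = TRUE) + 1L
  cls[is.na(x)] <- NA_integer_
  list(breaks = breaks, classes = cls, n_classes = as.integer(n_classes))
}

#' Per-tier area accounting
#'
#' @param tier An `eco_grid` of integer tier labels (1 = lowest).
#' @param labels Optional character labels, lowest tier first.
#' @return A tibble: `tier`, `label`, `n_cells`, `area_km2`, `percent`
#'   (percent of the valid area; the column sums to 100).
#' @export
tier_areas <- function(tier, labels = NULL) {
  stopifnot(is_grid(tier))
  v <- tier$values[!is.na(tier$values)]
  tab <- table(factor(v, levels = sort(unique(v))))
  cell_km2 <- tier$cell_size^2 / 1e6
  out <- tibble::tibble(
    tier = as.integer(names(tab)),
    n_cells = as.integer(tab),
    area_km2 = as.integer(tab) * cell_km2,
    percent = 100 * as.integer(tab) / length(v)
  )
  if (!is.null(labels)) out <- tibble::add_column(
    out, label = labels[out$tier], .after = "tier")
  out
}

#' Default tier labels, lowest importance first
#' @return Character vector of length 4.
#' @export
importance_labels <- function() c("general", "moderate", "high", "extreme")

#' Importance assessment and zoning of four service layers
#'
#' The full multi-criteria stage: stack the service rasters cellwise,
#' min-max normalise, weight by information entropy, score by weighted sum,
#' cut the score into tiers by Jenks natural breaks, and account per-tier
#' areas.
#'
#' @param services Named list of four aligned service `eco_grid`s
#'   (habitat quality, carbon, water yield, soil retention).
#' @param n_classes Number of tiers (default 4).
#' @param sample_cap Passed to [jenks_classify()].
#' @return An object of class `eco_importance`: fields `score` and `tier`
#'   (`eco_grid`s), `breaks`, `weights` (an `eco_weights` tibble), `areas`
#'   (tibble), `indicators`.
#' @export
assess_importance <- function(services, n_classes = 4, sample_cap = 6000) {
  mat <- normalize_indicators(build_matrix(services))
  w <- entropy_weights(mat)
  score <- importance_score(mat, w)
  jc <- jenks_classify(score$values[mat$cells], n_classes = n_classes,
                       sample_cap = sample_cap)
  tier <- mat$template
  tier$values[mat$cells] <- jc$classes[seq_along(mat$cells)]
  labels <- if (n_classes == 4) importance_labels() else
    paste0("tier", seq_len(n_classes))
  structure(list(score = score, tier = tier, breaks = jc$breaks,
                 weights = w, areas = tier_areas(tier, labels),
                 indicators = mat$indicators),
            class = "eco_importance")
}

#' @export
print.eco_importance <- function(x, ...) {
  cat("<eco_importance>\n")
  cat("  weights: ",
      paste(sprintf("%s %.3f", x$weights$indicator, x$weights$weight),
            collapse = ", "), "\n")
  cat("  breaks:  ", paste(signif(x$breaks, 4), collapse = ", "), "\n")
  print(x$areas)
  invisible(x)
}

#' @export
tidy.eco_importance <- function(x, ...) x$areas

#' @export
glance.eco_importance <- function(x, ...) {
  tibble::tibble(n_tiers = nrow(x$areas),
                 total_area_km2 = sum(x$areas$area_km2),
                 score_min = min(x$score$values, na.rm = TRUE),
                 score_max = max(x$score$values, na.rm = TRUE))
}

#' Tier map of an importance result
#'
#' @param object An `eco_importance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eco_importance <- function(object, ...) {
  g <- object$tier
  v <- g$values
  df <- tidyr::expand_grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  df$x <- g$xll + (df$col - 0.5) * g$cell_size
  df$y <- g$yll + (nrow(v) - df$row + 0.5) * g$cell_size
  lab <- if ("label" %in% names(object$areas))
    object$areas$label else as.character(object$areas$tier)
  df$tier <- factor(v[cbind(df$row, df$col)],
                    levels = object$areas$tier, labels = lab)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$tier)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_d(na.value = "grey85", direction = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)", fill = "importance")
}
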