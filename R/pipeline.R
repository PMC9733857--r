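#' Pipeline run configuration
#'
#' Assembles and validates everything one run needs: where inputs come from
#' (a bundle directory, or generator settings for a synthetic landscape),
#' model parameters, parameter-table overrides, and the output directory.
#' Accepts a YAML file with the same field names.
#'
#' @param input_dir Directory holding a raster bundle (see [write_bundle()]);
#'   mutually exclusive with `generate`.
#' @param generate Named list of [landscape_spec()] arguments for a synthetic
#'   run (the `seed` field of the config is injected).
#' @param output_dir Directory for stage outputs and the run manifest.
#' @param seed Integer seed for synthetic generation.
#' @param params Named list overriding model parameters: `k` (> 0),
#'   `z_exponent`, `z_coeff` (\[1, 30\]), `si_convert`, `n_classes`,
#'   `sample_cap`.
#' @param tables Named list of CSV paths overriding packaged parameter
#'   tables: `threats`, `sensitivity`, `carbon_density`, `biophysical`,
#'   `cp`, `codes`.
#' @return A validated list of class `eco_config`.
#' @export
eco_config <- function(input_dir = NULL, generate = NULL,
                       output_dir = tempfile("ecozoner_run_"),
                       seed = 1L, params = list(), tables = list()) {
  if (is.null(input_dir) && is.null(generate))
    stop("config needs either input_dir or generate settings", call. = FALSE)
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  defaults <- list(k = 0.5, z_exponent = 2.5, z_coeff = 10,
                   si_convert = TRUE, n_classes = 4L, sample_cap = 6000L)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- utils::modifyList(defaults, params)
  if (params$k <= 0) stop("k must be > 0", call. = FALSE)
  if (params$z_coeff < 1 || params$z_coeff > 30)
    stop("z_coeff must lie in [1, 30]", call. = FALSE)
  known_tabs <- c("threats", "sensitivity", "carbon_density", "biophysical",
                  "cp", "codes")
  unknown <- setdiff(names(tables), known_tabs)
  if (length(unknown))
    stop("unknown table override(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (p in unlist(tables)) if (!file.exists(p))
    stop("table override not found: ", p, call. = FALSE)
  structure(list(input_dir = input_dir, generate = generate,
                 output_dir = output_dir, seed = as.integer(seed),
                 params = params, tables = tables),
            class = "eco_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [eco_config()].
#' @return An `eco_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(eco_config, raw[intersect(names(raw), names(formals(eco_config)))])
}

config_tables <- function(config) {
  tb <- config$tables
  list(threats = threat_table(tb$threats),
       sensitivity = sensitivity_table(tb$sensitivity),
       carbon_density = carbon_density_table(tb$carbon_density),
       biophysical = biophysical_table(tb$biophysical),
       cp = cp_table(tb$cp),
       codes = landuse_code_table(tb$codes))
}

config_bundle <- function(config, tabs) {
  if (!is.null(config$input_dir)) {
    read_bundle(config$input_dir, code_table = tabs$codes)
  } else {
    args <- config$generate %||% list()
    args$seed <- config$seed
    generate_landscape(do.call(landscape_spec, args))
  }
}

write_table_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the assessment pipeline
#'
#' Orchestrates the stages over one configuration. `"all"` computes the four
#' services and the importance zoning in one pass; the individual service
#' stages write their rasters only; `"importance"` alone re-reads previously
#' written service rasters from `output_dir` and fails with an actionable
#' message when they are missing; `"generate"` writes the synthetic input
#' bundle itself. Every invocation writes a `manifest_<stage>.json` recording
#' the configuration hash, seed, package version and files written; the same
#' config and seed give byte-identical outputs. On error, files written by
#' the failed invocation are removed.
#'
#' @param config An [eco_config()] (or path to a YAML config).
#' @param stage One of `"all"`, `"generate"`, `"habitat"`, `"carbon"`,
#'   `"water"`, `"soil"`, `"importance"`.
#' @return Invisibly, a named list of artifact paths; for `"all"` and
#'   `"importance"` also the in-memory `eco_importance` result under
#'   `$importance`.
#' @export
run_pipeline <- function(config,
                         stage = c("all", "generate", "habitat", "carbon",
                                   "water", "soil", "importance")) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "eco_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written, recursive = TRUE))
  emit <- function(x, name) {
    p <- file.path(out, name)
    if (is_grid(x)) write_grid(x, p) else write_table_csv(x, p)
    written <<- c(written, p)
    p
  }

  tabs <- config_tables(config)
  pars <- config$params
  artifacts <- list()
  result <- NULL

  if (stage == "generate") {
    bundle <- config_bundle(config, tabs)
    bdir <- file.path(out, "inputs")
    write_bundle(bundle, bdir)
    written <- c(written, bdir)
    artifacts$inputs <- bdir
  } else if (stage == "importance") {
    need <- c("habitat_quality", "carbon_t_per_cell", "water_conservation_mm",
              "soil_retention")
    paths <- file.path(out, paste0(need, ".asc"))
    missing <- need[!file.exists(paths)]
    if (length(missing))
      stop("importance stage needs service rasters in ", out, "; missing: ",
           paste(missing, collapse = ", "),
           ". Run stage 'all' (or the habitat/carbon/water/soil stages) first.",
           call. = FALSE)
    services <- stats::setNames(lapply(paths, read_grid), need)
    result <- assess_importance(services, n_classes = pars$n_classes,
                                sample_cap = pars$sample_cap)
    artifacts <- emit_importance(result, emit)
  } else {
    bundle <- config_bundle(config, tabs)
    hpar <- habitat_params(k = pars$k, z_exponent = pars$z_exponent)
    services <- list()
    if (stage %in% c("all", "habitat")) {
      hab <- habitat_stage(bundle$landuse, tabs$threats, tabs$sensitivity,
                           hpar, extra_rasters = list(road = bundle$road))
      artifacts$habitat_quality <- emit(hab$quality, "habitat_quality.asc")
      artifacts$habitat_degradation <-
        emit(hab$degradation, "habitat_degradation.asc")
      services$habitat_quality <- hab$quality
    }
    if (stage %in% c("all", "carbon")) {
      carbon <- carbon_per_cell(bundle$landuse, tabs$carbon_density)
      artifacts$carbon <- emit(carbon, "carbon_t_per_cell.asc")
      services$carbon_t_per_cell <- carbon
    }
    if (stage %in% c("all", "water")) {
      wat <- water_stage(bundle$landuse, bundle$precip_annual, bundle$et0,
                         bundle$awc, tabs$biophysical, pars$z_coeff)
      artifacts$water <- emit(wat$yield, "water_conservation_mm.asc")
      artifacts$aet <- emit(wat$aet, "aet_mm.asc")
      services$water_conservation_mm <- wat$yield
    }
    if (stage %in% c("all", "soil")) {
      soil <- soil_stage(bundle$landuse, bundle$precip_monthly, bundle$dem,
                         bundle$san, bundle$sil, bundle$cla, bundle$oc,
                         tabs$cp, pars$si_convert)
      artifacts$soil_retention <- emit(soil$sd, "soil_retention.asc")
      artifacts$usle <- emit(soil$usle, "usle.asc")
      artifacts$rkls <- emit(soil$rkls, "rkls.asc")
      services$soil_retention <- soil$sd
    }
    if (stage == "all") {
      result <- assess_importance(services, n_classes = pars$n_classes,
                                  sample_cap = pars$sample_cap)
      artifacts <- c(artifacts, emit_importance(result, emit))
      artifacts$zonal <- emit(
        service_zonal_table(services, bundle$landuse),
        "services_by_landuse.csv")
    }
  }

  manifest <- list(
    stage = stage,
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)[c("generate", "seed", "params",
                                                "tables", "input_dir")]),
    package_version = as.character(utils::packageVersion("ecozoner")),
    params = config$params,
    files = vapply(unlist(artifacts), basename, character(1),
                   USE.NAMES = FALSE))
  mpath <- file.path(out, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, mpath)
  artifacts$manifest <- mpath
  ok <- TRUE
  invisible(c(artifacts, list(importance = result)))
}

emit_importance <- function(result, emit) {
  list(
    score = emit(result$score, "importance_score.asc"),
    tier = emit(result$tier, "importance_tier.asc"),
    weights = emit(tidy(result$weights), "entropy_weights.csv"),
    areas = emit(result$areas, "tier_areas.csv"),
    breaks = emit(tibble::tibble(break_upper = result$breaks), "breaks.csv"))
}

#' Per-class service summary table
#'
#' The per-land-use reporting layout of the assessment: mean habitat quality
#' index, total carbon (t), mean water yield (mm), and total soil retention
#' (summed over cells) per primary class.
#'
#' @param services Named list with the four service `eco_grid`s (names as
#'   produced by [run_pipeline()]).
#' @param landuse An `eco_landuse`.
#' @return A tibble with one row per primary class.
#' @export
service_zonal_table <- function(services, landuse) {
  hab <- zonal_summary(services$habitat_quality, landuse, "mean")
  car <- zonal_summary(services$carbon_t_per_cell, landuse, "sum")
  wat <- zonal_summary(services$water_conservation_mm, landuse, "mean")
  soi <- zonal_summary(services$soil_retention, landuse, "sum")
  out <- tibble::tibble(class = hab$class,
                        habitat_quality_mean = hab$mean,
                        carbon_t = car$sum,
                        water_conservation_mm = wat$mean,
                        soil_retention_sum = soi$sum,
                        n_cells = hab$n_cells)
  out[order(match(out$class, primary_classes())), ]
}
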