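#' Pipeline configuration
#'
#' Validates and normalises the full set of knobs the analysis uses. All
#' defaults are the analysis' canonical values: 3 x 3 window, growing season
#' May-September, significance level 0.05, sparse-vegetation threshold 0.2,
#' per-stratum sample cap 10000. Either `scene` (a synthetic-scene recipe)
#' or `inputs` (paths to on-disk stacks) must be supplied.
#'
#' @param scene Optional list with elements `specs` (list of
#'   [scenario_spec()]s), `n_rows`, `n_cols`, `years`, and optional
#'   `noise_sd`, `water_fraction`, `response_link`.
#' @param inputs Optional list of paths: `ndvi_manifest`, `drivers_manifest`,
#'   `grassland`, `landcover`, `lines`.
#' @param months Growing-season months (default 5:9).
#' @param window Focal window size, odd (default 3).
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @param ndvi_threshold Sparse-vegetation mean-NDVI threshold (default 0.2).
#' @param min_valid_months Minimum valid months per pixel-year (default 3).
#' @param min_valid_years Minimum valid years per pixel (default 15).
#' @param buffer_distance Line buffer distance(s), map units (default 250).
#' @param excluded_classes Landcover classes masked out.
#' @param epsilon Driver slope dead-band (default 0).
#' @param sample_cap Per-stratum sample cap (default 10000).
#' @param tree_grid Candidate tree counts.
#' @param cv_folds Cross-validation folds (default 5).
#' @param seed Master integer seed.
#' @param out_dir Output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = NULL, inputs = NULL, months = 5:9,
                            window = 3, alpha = 0.05, ndvi_threshold = 0.2,
                            min_valid_months = 3, min_valid_years = 15,
                            buffer_distance = 250,
                            excluded_classes = c("impervious", "water", "wetland", "glacier"),
                            epsilon = 0, sample_cap = 10000,
                            tree_grid = c(100, 200, 300, 500, 800),
                            cv_folds = 5, seed = 1, out_dir = tempfile("vegcv_run_")) {
  if (is.null(scene) && is.null(inputs)) {
    stop("config needs either a synthetic scene recipe or input paths",
         call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3", call. = FALSE)
  if (sample_cap < 1) stop("sample_cap must be >= 1", call. = FALSE)
  if (seed != as.integer(seed)) stop("seed must be an integer", call. = FALSE)
  if (any(epsilon < 0)) stop("epsilon must be >= 0", call. = FALSE)
  structure(list(scene = scene, inputs = inputs, months = months,
                 window = window, alpha = alpha,
                 ndvi_threshold = ndvi_threshold,
                 min_valid_months = min_valid_months,
                 min_valid_years = min_valid_years,
                 buffer_distance = buffer_distance,
                 excluded_classes = excluded_classes, epsilon = epsilon,
                 sample_cap = sample_cap, tree_grid = tree_grid,
                 cv_folds = cv_folds, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scene scenario specs are given as lists of the [scenario_spec()] fields
#' (with `block = [row1, row2, col1, col2]`), or as `demo: true` for the
#' bundled six-block demonstration scene.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scene)) {
    if (isTRUE(y$scene$demo)) {
      y$scene <- within_scene_demo(y$scene)
    } else if (!is.null(y$scene$specs)) {
      y$scene$specs <- lapply(y$scene$specs, function(s) {
        scenario_spec(s$class_label, unlist(s$block), s$baseline_ndvi,
                      s$ndvi_slope, s$divergence_base, s$divergence_slope,
                      s$noise_sd %||% 0, s$grassland %||% "steppe")
      })
    }
  }
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  if (!is.null(args$months)) args$months <- as.integer(unlist(args$months))
  if (!is.null(args$tree_grid)) args$tree_grid <- as.integer(unlist(args$tree_grid))
  if (!is.null(args$excluded_classes)) args$excluded_classes <- unlist(args$excluded_classes)
  do.call(pipeline_config, args)
}

within_scene_demo <- function(sc) {
  noise <- sc$noise_sd %||% 0.02
  list(specs = demo_scenario_specs(noise), n_rows = 120, n_cols = 120,
       years = 2000:2022, noise_sd = noise,
       water_fraction = sc$water_fraction %||% 0.02,
       response_link = sc$response_link)
}

#' Demonstration pipeline configuration
#'
#' The bundled 120 x 120 six-block scene over 23 years with monthly noise
#' 0.02, analysed end-to-end. The attribution stage is scaled to desk size
#' (per-stratum cap 2000, tree grid up to 300) so a full run stays within a
#' few minutes on one CPU.
#'
#' @param out_dir Output directory.
#' @param seed Master seed (default 42).
#' @param noise_sd Scene noise (default 0.02).
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(out_dir = tempfile("vegcv_demo_"), seed = 42,
                                 noise_sd = 0.02) {
  pipeline_config(
    scene = list(specs = demo_scenario_specs(noise_sd), n_rows = 120,
                 n_cols = 120, years = 2000:2022, noise_sd = noise_sd,
                 water_fraction = 0.02),
    sample_cap = 2000, tree_grid = c(100, 200, 300), cv_folds = 5,
    seed = seed, out_dir = out_dir)
}

#' Run the full vegetation-change analysis
#'
#' Executes every stage in order: scene simulation (or input reading), mask
#' construction, growing-season median composites, the multi-year mean NDVI
#' surface, focal-CV heterogeneity, NDVI and CV trend surfaces with
#' single-variable significance summaries, the six-class change raster with
#' proportion tables, driver trend summaries, the Pearson correlation
#' summary, stratified sample extraction and random-forest importance with
#' climate/human aggregate shares. All tables are written as CSV, rasters as
#' ASCII-grid stacks, and a run manifest (config echo, seed, package
#' version) as JSON under `config$out_dir`. Identical configurations produce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with every intermediate and final result.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("stage %-14s %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  scene <- NULL
  if (!is.null(config$scene)) {
    sc <- config$scene
    scene <- stage("simulate", {
      grid <- raster_grid(sc$n_rows, sc$n_cols)
      build_scene(sc$specs, grid, as.integer(unlist(sc$years)),
                  seed = config$seed,
                  water_fraction = sc$water_fraction %||% 0.02,
                  response_link = unlist(sc$response_link))
    })
    monthly <- scene$monthly_ndvi
    drivers <- scene$drivers
    grassland <- scene$grassland_type
    landcover <- scene$landcover
    lines <- scene$lines
    write_scene(scene, file.path(out, "scene"))
  } else {
    ins <- config$inputs
    monthly <- stage("read", read_stack(ins$ndvi_manifest))
    drivers <- read_stack(ins$drivers_manifest, expected_grid = monthly$grid)
    grid <- monthly$grid
    gl <- read_ascii_grid(ins$grassland, crs_id = grid$crs_id)
    gl_names <- c("other", "steppe", "meadow")
    grassland <- matrix(gl_names[gl$values + 1], grid$n_rows, grid$n_cols)
    lc <- read_ascii_grid(ins$landcover, crs_id = grid$crs_id)
    landcover <- matrix(landcover_legend()[lc$values + 1], grid$n_rows, grid$n_cols)
    lines <- if (!is.null(ins$lines)) read_lines_geojson(ins$lines) else NULL
  }
  grid <- monthly$grid

  masks <- stage("mask", build_mask_set(
    landcover, excluded_classes = config$excluded_classes, lines = lines,
    distance = config$buffer_distance, grid = grid))
  say("  masked pixels: landcover %d, buffer %d, combined %d",
      sum(masks$landcover_mask), sum(masks$buffer_mask), sum(masks$combined))

  composite <- stage("composite", growing_season_median(
    monthly, months = config$months,
    min_valid_months = config$min_valid_months))
  write_stack(composite, file.path(out, "composite"), prefix = "ndvi")

  mean_ndvi <- stage("period_mean", period_mean(
    composite, min_valid_years = config$min_valid_years))
  write_ascii_grid(mean_ndvi$values, grid, file.path(out, "mean_ndvi.asc"))

  cv <- stage("heterogeneity", focal_cv(composite, window = config$window,
                                        mask = masks))
  write_stack(cv, file.path(out, "cv"), prefix = "cv")

  ndvi_trend <- stage("trend_ndvi", fit_linear_trend(
    composite, min_valid_years = config$min_valid_years, variable = "NDVI"))
  cv_trend <- stage("trend_cv", fit_linear_trend(
    cv, min_valid_years = config$min_valid_years, variable = "CV"))
  for (tr in list(ndvi_trend, cv_trend)) {
    write_ascii_grid(tr$slope, grid,
                     file.path(out, sprintf("%s_slope.asc", tolower(tr$variable))))
    write_ascii_grid(tr$p_value, grid,
                     file.path(out, sprintf("%s_pvalue.asc", tolower(tr$variable))))
  }
  single_sig <- purrr::map_dfr(list(ndvi_trend, cv_trend), function(tr) {
    s <- as.vector(tr$slope); p <- as.vector(tr$p_value)
    ok <- !is.na(s) & !is.na(p)
    tibble::tibble(
      variable = tr$variable, n_valid = sum(ok),
      significant_increase = 100 * sum(ok & s > 0 & p < config$alpha) / sum(ok),
      significant_decrease = 100 * sum(ok & s < 0 & p < config$alpha) / sum(ok),
      not_significant = 100 * sum(ok & p >= config$alpha) / sum(ok))
  })
  utils::write.csv(single_sig, file.path(out, "single_significance.csv"),
                   row.names = FALSE)

  classes <- stage("classify", classify_change(
    ndvi_trend, cv_trend, mean_ndvi, alpha = config$alpha,
    ndvi_threshold = config$ndvi_threshold))
  cc <- change_class_codes()
  write_ascii_grid(matrix(cc[classes$labels], grid$n_rows), grid,
                   file.path(out, "change_classes.asc"))
  proportions <- summarize_proportions(classes, grassland)
  utils::write.csv(proportions, file.path(out, "class_proportions.csv"),
                   row.names = FALSE)
  say("  dual-significant pixels: %d of %d valid",
      sum(!is.na(classes$labels) & classes$labels != "not_significant"),
      sum(!is.na(classes$labels)))

  driver_trends <- stage("trend_drivers", lapply(
    stats::setNames(names(drivers$variables), names(drivers$variables)),
    function(v) fit_linear_trend(
      annual_stack(grid, drivers$years, drivers$variables[[v]]),
      min_valid_years = config$min_valid_years, variable = v)))
  drv_summary <- driver_trend_summary(driver_trends, epsilon = config$epsilon,
                                      alpha = config$alpha)
  utils::write.csv(drv_summary, file.path(out, "driver_trends.csv"),
                   row.names = FALSE)

  correlations <- stage("correlations", summarize_correlations(
    list(NDVI = composite, CV = cv), drivers, alpha = config$alpha))
  utils::write.csv(correlations, file.path(out, "correlation_summary.csv"),
                   row.names = FALSE)

  samples <- stage("samples", extract_strata_samples(
    classes, grassland, list(NDVI = composite, CV = cv), drivers,
    sample_cap = config$sample_cap, seed = config$seed + 1L))
  utils::write.csv(samples, file.path(out, "strata_samples.csv"),
                   row.names = FALSE)

  importance <- stage("importance", dplyr::bind_rows(
    fit_importance(samples, "ndvi", tree_grid = config$tree_grid,
                   cv_folds = config$cv_folds, seed = config$seed + 2L),
    fit_importance(samples, "cv", tree_grid = config$tree_grid,
                   cv_folds = config$cv_folds, seed = config$seed + 3L)))
  utils::write.csv(importance, file.path(out, "importance.csv"),
                   row.names = FALSE)
  shares <- aggregate_contributions(importance)
  utils::write.csv(shares, file.path(out, "aggregate_shares.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("vegcv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config)[setdiff(names(unclass(config)), "scene")],
    scene_seed = if (!is.null(scene)) scene$seed else NULL)
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  invisible(list(scene = scene, masks = masks, composite = composite,
                 mean_ndvi = mean_ndvi, cv = cv, ndvi_trend = ndvi_trend,
                 cv_trend = cv_trend, single_significance = single_sig,
                 classes = classes, proportions = proportions,
                 driver_trends = driver_trends, driver_summary = drv_summary,
                 correlations = correlations, samples = samples,
                 importance = importance, shares = shares, out_dir = out))
}
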