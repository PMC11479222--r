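#' Scenario specification for one synthetic scene block
#'
#' Describes a rectangular block of pixels whose NDVI series follows
#' `v(t) = (baseline + slope * t) * (1 + offset * (div_base + div_slope * t)) + noise`,
#' where `t` is years since the scene start and `offset` is the pixel's
#' position in a fixed zero-mean 3 x 3 divergence pattern. The mean term
#' controls the NDVI trend; the multiplicative divergence term controls the
#' within-window spread and hence the focal-CV trend, so the two change
#' signals can be set independently and every change class can be produced
#' on demand.
#'
#' @param class_label One of [change_class_levels()] (except
#'   `not_significant`), `"no_change"`, or `"custom"`. Parameter signs must
#'   be consistent with the label (e.g. `regrowing` needs
#'   `baseline_ndvi < 0.2`, `ndvi_slope > 0`, `divergence_slope > 0`);
#'   `"custom"` blocks carry no sign constraint (and no truth label beyond
#'   `not_significant`), for free experimentation with the generative model.
#' @param block Integer vector `c(row1, row2, col1, col2)` (inclusive), or
#'   `NULL` for a background spec.
#' @param baseline_ndvi Start-of-period NDVI in `[0, 1]`.
#' @param ndvi_slope NDVI change per year.
#' @param divergence_base Initial relative within-window spread, `>= 0`.
#' @param divergence_slope Spread change per year; its sign is the CV trend.
#' @param noise_sd Monthly observation noise standard deviation, `>= 0`.
#' @param grassland `"steppe"`, `"meadow"` or `"other"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(class_label, block = NULL, baseline_ndvi,
                          ndvi_slope, divergence_base, divergence_slope,
                          noise_sd = 0, grassland = "steppe") {
  ok_labels <- c(setdiff(change_class_levels(), "not_significant"),
                 "no_change", "custom")
  if (!class_label %in% ok_labels) {
    stop("unknown class_label: ", class_label, call. = FALSE)
  }
  stopifnot(baseline_ndvi >= 0, baseline_ndvi <= 1,
            divergence_base >= 0, noise_sd >= 0,
            grassland %in% c("steppe", "meadow", "other"))
  if (!is.null(block)) {
    stopifnot(length(block) == 4, block[1] <= block[2], block[3] <= block[4])
    block <- as.integer(block)
  }
  need <- switch(class_label,
    improving          = ndvi_slope > 0 && divergence_slope < 0,
    regrowing          = baseline_ndvi < 0.2 && ndvi_slope > 0 && divergence_slope > 0,
    slight_degradation = baseline_ndvi >= 0.2 && ndvi_slope > 0 && divergence_slope > 0,
    medium_degradation = ndvi_slope < 0 && divergence_slope > 0,
    severe_degradation = baseline_ndvi >= 0.2 && ndvi_slope < 0 && divergence_slope < 0,
    desertification    = baseline_ndvi < 0.2 && ndvi_slope < 0 && divergence_slope < 0,
    no_change          = ndvi_slope == 0 && divergence_slope == 0,
    custom             = TRUE)
  if (!need) {
    stop(sprintf("parameters inconsistent with class_label '%s'", class_label),
         call. = FALSE)
  }
  structure(list(class_label = class_label, block = block,
                 baseline_ndvi = baseline_ndvi, ndvi_slope = ndvi_slope,
                 divergence_base = divergence_base,
                 divergence_slope = divergence_slope,
                 noise_sd = noise_sd, grassland = grassland),
            class = "scenario_spec")
}

#' Canonical zero-mean 3 x 3 divergence offset pattern
#'
#' The nine offsets `{-1, -0.75, -0.5, -0.25, 0, 0.25, 0.5, 0.75, 1}` in a
#' fixed scrambled arrangement. Tiled periodically over a block, every 3 x 3
#' window contains each offset exactly once, so the focal CV of a noiseless
#' block is exactly `divergence(t) * sd(offsets)` at every interior pixel.
#'
#' @return A 3 x 3 numeric matrix with mean zero.
#' @export
canonical_offsets <- function() {
  matrix(c(-1, 0.25, 0.5, 0.75, -0.25, -0.5, 0, 1, -0.75), nrow = 3)
}

noiseless_annual <- function(spec, pattern_offset, t) {
  (spec$baseline_ndvi + spec$ndvi_slope * t) *
    (1 + pattern_offset * (spec$divergence_base + spec$divergence_slope * t))
}

#' Simulate one pixel's monthly NDVI series
#'
#' Reference scalar implementation of the scene generative model: the
#' noiseless annual value is replicated over the growing-season months with
#' per-month Gaussian noise (`noise_sd`) plus a fixed per-month seasonal
#' jitter (sd `noise_sd / 2`, drawn once and shared across years). Values
#' are clipped to `[-1, 1]`; a noiseless trajectory leaving `[0, 1]` is
#' rejected.
#'
#' @param spec A [scenario_spec()].
#' @param pattern_offset Divergence offset for this pixel, in `[-1, 1]`.
#' @param years Integer vector of calendar years.
#' @param months_per_year Growing-season months simulated (default 5,
#'   May-September).
#' @param seed Integer RNG seed.
#' @return A tibble with columns `year`, `month`, `ndvi`.
#' @export
simulate_pixel_series <- function(spec, pattern_offset, years,
                                  months_per_year = 5, seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"),
            pattern_offset >= -1, pattern_offset <= 1,
            months_per_year >= 1)
  t <- seq_along(years) - 1
  annual <- noiseless_annual(spec, pattern_offset, t)
  if (any(annual < 0 | annual > 1)) {
    stop("noiseless trajectory exits [0, 1]; adjust the scenario parameters",
         call. = FALSE)
  }
  months <- 4 + seq_len(months_per_year)
  withr::with_seed(seed, {
    jitter <- stats::rnorm(months_per_year, 0, spec$noise_sd / 2)
    eps <- stats::rnorm(length(years) * months_per_year, 0, spec$noise_sd)
  })
  v <- rep(annual, each = months_per_year) + rep(jitter, times = length(years)) + eps
  tibble::tibble(year = rep(years, each = months_per_year),
                 month = rep(months, times = length(years)),
                 ndvi = pmin(pmax(v, -1), 1))
}

#' Default generative settings for the six annual drivers
#'
#' Per-variable `{mean, slope, sd}` of the coarse-grid annual series
#' `mean + slope * t + Normal(0, sd)`, in the variable's own units, chosen
#' to emulate a warming/wetting alpine climate with slowly shifting human
#' pressure. `Pop` is integer-valued with a literally zero slope, which is
#' what produces large "unchanged" fractions under the exact-zero rule.
#'
#' @return Named list of per-variable links.
#' @export
default_driver_links <- function() {
  list(Pre  = list(mean = 450, slope = 1.5,  sd = 25,  integer = FALSE),
       Temp = list(mean = -2,  slope = 0.04, sd = 0.3, integer = FALSE),
       RH   = list(mean = 55,  slope = -0.06, sd = 1.5, integer = FALSE),
       SPEI = list(mean = 0,   slope = 0.01, sd = 0.4, integer = FALSE),
       Graz = list(mean = 50,  slope = 0.25, sd = 6,   integer = FALSE),
       Pop  = list(mean = 3,   slope = 0,    sd = 0,   integer = TRUE))
}

#' Simulate annual driver rasters on a coarser grid and align them
#'
#' Drivers are generated per coarse cell and year as
#' `mean + slope * t + Normal(0, sd)`, then resampled to the analysis grid
#' (bilinear for continuous variables, nearest for integer-valued ones), the
#' same path real driver products take. An optional `response_link` returns
#' an NDVI perturbation stack `sum(beta_v * standardized driver_v)` that the
#' scene builder adds to the NDVI annual signal, making driver-attribution
#' recovery testable against a known cause.
#'
#' @param grid Analysis [raster_grid()].
#' @param years Integer vector.
#' @param links Per-variable settings as in [default_driver_links()].
#' @param coarse_factor Coarse-grid pixel size multiplier (default 4).
#' @param response_link Optional named numeric vector of per-sd NDVI effects,
#'   e.g. `c(Temp = 0.02)`.
#' @param seed Integer RNG seed.
#' @return A [driver_stack()]; when `response_link` is given, the NDVI
#'   perturbation [annual_stack()] is attached as attribute
#'   `"perturbation"`.
#' @export
simulate_drivers <- function(grid, years, links = default_driver_links(),
                             coarse_factor = 4, response_link = NULL,
                             seed = 1) {
  bad <- setdiff(names(links), driver_names())
  if (length(bad) > 0) stop("unknown variable name(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  if (any(vapply(links, function(l) l$sd < 0, logical(1)))) {
    stop("negative sd in driver links", call. = FALSE)
  }
  cg <- raster_grid(ceiling(grid$n_rows / coarse_factor),
                    ceiling(grid$n_cols / coarse_factor),
                    origin_x = grid$origin_x, origin_y = grid$origin_y,
                    pixel_size = grid$pixel_size * coarse_factor,
                    crs_id = grid$crs_id, nodata = grid$nodata)
  t <- seq_along(years) - 1
  ny <- length(years)
  variables <- withr::with_seed(seed, {
    lapply(links, function(l) {
      coarse <- array(stats::rnorm(cg$n_rows * cg$n_cols * ny, 0, l$sd),
                      dim = c(cg$n_rows, cg$n_cols, ny))
      coarse <- sweep(coarse, 3, l$mean + l$slope * t, `+`)
      if (isTRUE(l$integer)) coarse <- pmax(round(coarse), 0)
      fine <- array(NA_real_, dim = c(grid$n_rows, grid$n_cols, ny))
      method <- if (isTRUE(l$integer)) "nearest" else "bilinear"
      for (k in seq_len(ny)) {
        fine[, , k] <- align_to_grid(coarse[, , k], cg, grid, method = method)
      }
      fine
    })
  })
  out <- driver_stack(grid, years, variables)
  if (!is.null(response_link)) {
    bad <- setdiff(names(response_link), names(variables))
    if (length(bad) > 0) stop("response_link names unknown: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    pert <- array(0, dim = c(grid$n_rows, grid$n_cols, ny))
    for (v in names(response_link)) {
      z <- variables[[v]]
      s <- stats::sd(z)
      z <- if (s > 0) (z - mean(z)) / s else z * 0
      pert <- pert + response_link[[v]] * z
    }
    attr(out, "perturbation") <- annual_stack(grid, years, pert)
  }
  out
}

#' Build a fully labelled synthetic scene
#'
#' Assembles every input the analysis consumes: a monthly NDVI stack, six
#' annual driver rasters on a coarser grid brought up to the analysis grid,
#' a grassland-type raster, a landcover raster with a configurable fraction
#' of water/impervious pixels, road and river polylines that cross at least
#' one block, and a ground-truth change-class raster. Each block gets the
#' canonical zero-mean 3 x 3 divergence pattern tiled across it, so every
#' interior window realises the block's CV trajectory exactly. Identical
#' arguments produce bit-identical scenes.
#'
#' @param specs List of [scenario_spec()]s with disjoint blocks inside the
#'   grid.
#' @param grid Analysis [raster_grid()].
#' @param years Integer vector, length `>= 3`.
#' @param seed Integer RNG seed.
#' @param background [scenario_spec()] applied to pixels outside all blocks
#'   (default: stable mid-NDVI grassland with the first spec's noise).
#' @param months_per_year Growing-season months simulated (default 5).
#' @param water_fraction Fraction of background pixels marked as water or
#'   impervious in the landcover raster (default 0.02); NDVI is nodata
#'   there.
#' @param driver_links,coarse_factor,response_link Passed to
#'   [simulate_drivers()].
#' @return An object of class `synthetic_scene`: list with `monthly_ndvi`,
#'   `drivers`, `grassland_type`, `landcover`, `lines`, `truth`, `seed`,
#'   `specs`, and the NDVI `perturbation` stack when a `response_link` was
#'   given.
#' @export
build_scene <- function(specs, grid, years, seed = 1, background = NULL,
                        months_per_year = 5, water_fraction = 0.02,
                        driver_links = default_driver_links(),
                        coarse_factor = 4, response_link = NULL) {
  if (length(years) < 3) stop("years list shorter than 3", call. = FALSE)
  nr <- grid$n_rows; nc <- grid$n_cols
  occupied <- matrix(FALSE, nr, nc)
  for (sp in specs) {
    stopifnot(inherits(sp, "scenario_spec"))
    b <- sp$block
    if (is.null(b)) stop("every block spec needs a block extent", call. = FALSE)
    if (b[1] < 1 || b[2] > nr || b[3] < 1 || b[4] > nc) {
      stop("block extends beyond the grid", call. = FALSE)
    }
    if (any(occupied[b[1]:b[2], b[3]:b[4]])) {
      stop("overlapping blocks in scenario specs", call. = FALSE)
    }
    occupied[b[1]:b[2], b[3]:b[4]] <- TRUE
  }
  if (is.null(background)) {
    bg_noise <- if (length(specs) > 0) specs[[1]]$noise_sd else 0.02
    background <- scenario_spec("no_change", NULL, baseline_ndvi = 0.3,
                                ndvi_slope = 0, divergence_base = 0.05,
                                divergence_slope = 0, noise_sd = bg_noise,
                                grassland = "other")
  }
  t <- seq_along(years) - 1
  n_last <- max(t)
  # parameter rasters
  B <- matrix(background$baseline_ndvi, nr, nc)
  S <- matrix(background$ndvi_slope, nr, nc)
  D0 <- matrix(background$divergence_base, nr, nc)
  D1 <- matrix(background$divergence_slope, nr, nc)
  NS <- matrix(background$noise_sd, nr, nc)
  grassland <- matrix(background$grassland, nr, nc)
  truth <- matrix("not_significant", nr, nc)
  pat <- canonical_offsets()
  O <- pat[(matrix(seq_len(nr) - 1, nr, nc) %% 3) + 1 +
             3 * (matrix(rep(seq_len(nc) - 1, each = nr), nr, nc) %% 3)]
  O <- matrix(O, nr, nc)
  for (sp in specs) {
    b <- sp$block
    rows <- b[1]:b[2]; cols <- b[3]:b[4]
    # validate the noiseless envelope at the extreme offsets and end years
    for (off in c(-1, 1)) {
      env <- noiseless_annual(sp, off, c(0, n_last))
      if (any(env < 0 | env > 1)) {
        stop(sprintf("block '%s': noiseless trajectory exits [0, 1]",
                     sp$class_label), call. = FALSE)
      }
    }
    B[rows, cols] <- sp$baseline_ndvi
    S[rows, cols] <- sp$ndvi_slope
    D0[rows, cols] <- sp$divergence_base
    D1[rows, cols] <- sp$divergence_slope
    NS[rows, cols] <- sp$noise_sd
    grassland[rows, cols] <- sp$grassland
    truth[rows, cols] <- if (sp$class_label %in% c("no_change", "custom"))
      "not_significant" else sp$class_label
    # re-tile the pattern relative to the block corner so interior windows
    # always hold all nine offsets
    O[rows, cols] <- pat[((rows - b[1]) %% 3) + 1 +
                           3 * rep((cols - b[3]) %% 3, each = length(rows))]
  }
  months <- 4 + seq_len(months_per_year)
  ny <- length(years)
  index <- tibble::tibble(year = rep(years, each = months_per_year),
                          month = rep(months, times = ny))
  drivers <- simulate_drivers(grid, years, links = driver_links,
                              coarse_factor = coarse_factor,
                              response_link = response_link,
                              seed = seed + 1L)
  pert <- attr(drivers, "perturbation")
  vals <- array(NA_real_, dim = c(nr, nc, nrow(index)))
  landcover <- matrix("grassland", nr, nc)
  withr::with_seed(seed, {
    jitter <- array(stats::rnorm(nr * nc * months_per_year), dim = c(nr, nc, months_per_year))
    for (k in seq_len(nrow(index))) {
      yi <- match(index$year[k], years)
      mi <- ((k - 1) %% months_per_year) + 1
      annual <- (B + S * t[yi]) * (1 + O * (D0 + D1 * t[yi]))
      if (!is.null(pert)) annual <- annual + pert$values[, , yi]
      eps <- matrix(stats::rnorm(nr * nc, 0, 1), nr, nc) * NS
      vals[, , k] <- pmin(pmax(annual + eps + jitter[, , mi] * NS / 2, -1), 1)
    }
    # landcover: scatter water/impervious pixels over the background
    bg_idx <- which(!occupied)
    n_water <- round(water_fraction * length(bg_idx))
    if (n_water > 0) {
      wi <- sample(bg_idx, n_water)
      landcover[wi[seq_len(ceiling(n_water / 2))]] <- "water"
      if (n_water > 1) {
        landcover[wi[(ceiling(n_water / 2) + 1):n_water]] <- "impervious"
      }
    }
  })
  bad_lc <- landcover %in% c("water", "impervious")
  for (k in seq_len(dim(vals)[3])) {
    slab <- vals[, , k]
    slab[bad_lc] <- NA_real_
    vals[, , k] <- slab
  }
  truth[bad_lc] <- NA_character_
  lines <- scene_lines(grid, specs)
  structure(list(
    monthly_ndvi = monthly_stack(grid, index, vals),
    drivers = drivers, grassland_type = grassland, landcover = landcover,
    lines = lines, truth = structure(list(grid = grid, labels = truth),
                                     class = "change_class_raster"),
    perturbation = pert, seed = seed, specs = specs, background = background),
    class = "synthetic_scene")
}

# One road crossing the first block horizontally and one river crossing the
# scene vertically; deterministic in the grid and blocks.
scene_lines <- function(grid, specs) {
  ctr <- pixel_centers(grid)
  coords <- list(); layer <- character()
  if (length(specs) > 0) {
    b <- specs[[1]]$block
    y <- ctr$y[round((b[1] + b[2]) / 2)]
    coords[[1]] <- cbind(c(min(ctr$x) - grid$pixel_size,
                           max(ctr$x) + grid$pixel_size), c(y, y))
    layer <- "road"
    x <- ctr$x[min(grid$n_cols, b[4] + round(grid$n_cols / 8))]
    coords[[2]] <- cbind(c(x, x), c(max(ctr$y) + grid$pixel_size,
                                    min(ctr$y) - grid$pixel_size))
    layer <- c(layer, "river")
  }
  line_set(coords, layer)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d block(s), %d x %d pixels, %d years, seed %d\n",
              length(x$specs), x$monthly_ndvi$grid$n_rows,
              x$monthly_ndvi$grid$n_cols,
              length(unique(x$monthly_ndvi$index$year)), x$seed))
  invisible(x)
}

#' Demonstration six-block scenario set
#'
#' One block per change class on a 120 x 120 grid, parameterised so each
#' block's NDVI and CV trends are strong enough to be detected at
#' `alpha = 0.05` over 23 years under the default observation noise
#' (per-pixel trend |t|-statistics of roughly 4 and above).
#'
#' @param noise_sd Monthly NDVI noise (default 0.02).
#' @return List of six [scenario_spec()]s.
#' @export
demo_scenario_specs <- function(noise_sd = 0.02) {
  list(
    scenario_spec("improving", c(9, 40, 9, 40), 0.50, 0.004, 0.10, -0.003,
                  noise_sd, "steppe"),
    scenario_spec("regrowing", c(9, 40, 45, 76), 0.10, 0.004, 0.05, 0.012,
                  noise_sd, "meadow"),
    scenario_spec("slight_degradation", c(9, 40, 81, 112), 0.45, 0.004, 0.08,
                  0.004, noise_sd, "steppe"),
    scenario_spec("medium_degradation", c(73, 104, 9, 40), 0.50, -0.004, 0.08,
                  0.004, noise_sd, "meadow"),
    scenario_spec("severe_degradation", c(73, 104, 45, 76), 0.50, -0.004, 0.15,
                  -0.004, noise_sd, "steppe"),
    scenario_spec("desertification", c(73, 104, 81, 112), 0.16, -0.004, 0.60,
                  -0.009, noise_sd, "meadow"))
}

#' Interior pixels of the scene blocks
#'
#' Logical raster marking pixels at least `erode` pixels inside a block, the
#' pixels whose focal windows lie entirely within the block and therefore
#' carry the block's exact CV trajectory.
#'
#' @param scene A [build_scene()] result.
#' @param erode Margin width in pixels (default 1, matching a 3 x 3 window).
#' @return Logical matrix.
#' @export
scene_interior <- function(scene, erode = 1) {
  grid <- scene$monthly_ndvi$grid
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (sp in scene$specs) {
    b <- sp$block
    if (b[2] - b[1] >= 2 * erode && b[4] - b[3] >= 2 * erode) {
      m[(b[1] + erode):(b[2] - erode), (b[3] + erode):(b[4] - erode)] <- TRUE
    }
  }
  m
}

#' Ground-truth recovery rate of a classification
#'
#' Share of interior block pixels whose classified label equals the scene's
#' truth label, among interior pixels that received a classification (pixels
#' under the river/road buffer or masked landcover are nodata by design and
#' are excluded from the denominator).
#'
#' @param classes A [classify_change()] raster.
#' @param scene The [build_scene()] scene it was computed from.
#' @param erode Interior margin (default 1).
#' @return A list with `rate` (percent), `n_assessed` and `n_matched`.
#' @export
recovery_rate <- function(classes, scene, erode = 1) {
  stopifnot(inherits(classes, "change_class_raster"))
  interior <- scene_interior(scene, erode)
  sel <- interior & !is.na(classes$labels) & !is.na(scene$truth$labels)
  n <- sum(sel)
  hit <- sum(classes$labels[sel] == scene$truth$labels[sel])
  list(rate = if (n > 0) 100 * hit / n else NA_real_,
       n_assessed = n, n_matched = hit)
}

#' Write a synthetic scene to a directory
#'
#' NDVI and drivers as ASCII-grid stacks with JSON manifests, lines as
#' GeoJSON, categorical rasters (grassland type, landcover, truth) as coded
#' ASCII grids, plus a `scene_manifest.json` recording the seed and all
#' scenario parameters.
#'
#' @param scene A [build_scene()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- scene$monthly_ndvi$grid
  write_stack(scene$monthly_ndvi, file.path(dir, "ndvi"), prefix = "ndvi")
  write_stack(scene$drivers, file.path(dir, "drivers"), prefix = "driver")
  write_lines_geojson(scene$lines, file.path(dir, "lines.geojson"))
  gl_codes <- c(steppe = 1, meadow = 2, other = 0)
  write_ascii_grid(matrix(gl_codes[scene$grassland_type], grid$n_rows),
                   grid, file.path(dir, "grassland_type.asc"))
  lc_codes <- stats::setNames(seq_along(landcover_legend()) - 1, landcover_legend())
  write_ascii_grid(matrix(lc_codes[scene$landcover], grid$n_rows),
                   grid, file.path(dir, "landcover.asc"))
  cc <- change_class_codes()
  tr <- matrix(cc[scene$truth$labels], grid$n_rows)
  write_ascii_grid(tr, grid, file.path(dir, "truth.asc"))
  manifest <- list(
    seed = scene$seed,
    grid = unclass(grid),
    grassland_codes = as.list(gl_codes),
    landcover_codes = as.list(lc_codes),
    class_codes = as.list(cc),
    background = unclass(scene$background),
    specs = lapply(scene$specs, unclass))
  jsonlite::write_json(manifest, file.path(dir, "scene_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
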