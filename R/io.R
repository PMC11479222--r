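#' Write a single raster layer as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by every desktop GIS. `NA` pixels
#' are written as the grid's nodata sentinel. Values are written at full
#' double precision so write/read round-trips are exact.
#'
#' @param values Numeric matrix conforming to `grid`.
#' @param grid A [raster_grid()].
#' @param path Output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path) {
  check_raster_conforms(values, grid)
  v <- values
  v[is.na(v)] <- grid$nodata
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y - grid$n_rows * grid$pixel_size),
    sprintf("cellsize %.10g", grid$pixel_size),
    sprintf("NODATA_value %.10g", grid$nodata))
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Values equal to the file's `NODATA_value` become `NA`. The CRS identifier
#' is not part of the format; supply it (it usually comes from a stack
#' manifest).
#'
#' @param path File to read.
#' @param crs_id CRS identifier to stamp on the grid.
#' @param extra_nodata Optional numeric vector of additional sentinel values
#'   (e.g. `-3000`, the MODIS fill convention) also mapped to `NA`.
#' @return A list with elements `values` (matrix, `NA` for nodata) and `grid`.
#' @export
read_ascii_grid <- function(path, crs_id = "local", extra_nodata = numeric()) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  n_rows <- as.integer(hdr$nrows); n_cols <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != n_rows * n_cols) {
    stop("ASCII grid body does not match header dimensions", call. = FALSE)
  }
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m %in% c(hdr$nodata_value, extra_nodata)] <- NA
  grid <- raster_grid(n_rows, n_cols, origin_x = hdr$xllcorner,
                      origin_y = hdr$yllcorner + n_rows * hdr$cellsize,
                      pixel_size = hdr$cellsize, crs_id = crs_id,
                      nodata = hdr$nodata_value)
  list(values = m, grid = grid)
}

#' Write a raster stack to a directory with a JSON manifest
#'
#' One ASCII-grid file per layer plus `manifest.json` recording the grid,
#' CRS and the `(year, month, variable)` of every layer, so stacks re-read
#' byte-identically with [read_stack()].
#'
#' @param stack A `monthly_stack`, `annual_stack` or `driver_stack`.
#' @param dir Output directory (created if missing).
#' @param prefix Layer file-name prefix.
#' @return Path to the manifest, invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "layer") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layers <- list()
  add_layer <- function(values, year, month, variable, tag) {
    fn <- paste0(prefix, "_", tag, ".asc")
    write_ascii_grid(values, stack$grid, file.path(dir, fn))
    layers[[length(layers) + 1]] <<- list(path = fn, year = year,
                                          month = month, variable = variable)
  }
  if (inherits(stack, "monthly_stack")) {
    for (k in seq_len(nrow(stack$index))) {
      add_layer(stack$values[, , k], stack$index$year[k], stack$index$month[k],
                "ndvi", sprintf("%d_%02d", stack$index$year[k], stack$index$month[k]))
    }
  } else if (inherits(stack, "annual_stack")) {
    for (k in seq_along(stack$years)) {
      add_layer(stack$values[, , k], stack$years[k], NULL, prefix,
                sprintf("%d", stack$years[k]))
    }
  } else if (inherits(stack, "driver_stack")) {
    for (v in names(stack$variables)) {
      for (k in seq_along(stack$years)) {
        add_layer(stack$variables[[v]][, , k], stack$years[k], NULL, v,
                  sprintf("%s_%d", v, stack$years[k]))
      }
    }
  } else stop("unsupported stack class", call. = FALSE)
  manifest <- list(kind = class(stack)[1], crs_id = stack$grid$crs_id,
                   nodata = stack$grid$nodata, layers = layers)
  path <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a raster stack from a manifest
#'
#' All layers must share one grid; a mismatch is an error. Layers are sorted
#' into calendar order regardless of manifest order.
#'
#' @param manifest_path Path to a manifest written by [write_stack()], or a
#'   manifest-shaped list.
#' @param expected_grid Optional [raster_grid()] the stack must match.
#' @param extra_nodata Passed to [read_ascii_grid()].
#' @return A `monthly_stack`, `annual_stack` or `driver_stack`.
#' @export
read_stack <- function(manifest_path, expected_grid = NULL,
                       extra_nodata = numeric()) {
  if (is.character(manifest_path)) {
    manifest <- jsonlite::read_json(manifest_path)
    base <- dirname(manifest_path)
  } else {
    manifest <- manifest_path
    base <- "."
  }
  if (length(manifest$layers) == 0) stop("empty stack manifest", call. = FALSE)
  crs <- manifest$crs_id %||% "local"
  reads <- lapply(manifest$layers, function(ly) {
    g <- read_ascii_grid(file.path(base, ly$path), crs_id = crs,
                         extra_nodata = extra_nodata)
    scalar_or_na <- function(x, na) {
      if (is.null(x) || length(x) == 0) na else x
    }
    list(values = g$values, grid = g$grid,
         year = as.integer(scalar_or_na(ly$year, NA)),
         month = as.integer(scalar_or_na(ly$month, NA)),
         variable = as.character(scalar_or_na(ly$variable, NA)))
  })
  grid <- reads[[1]]$grid
  for (r in reads) stop_if_grid_mismatch(grid, r$grid, "stack layers")
  if (!is.null(expected_grid)) stop_if_grid_mismatch(expected_grid, grid, "stack")
  years <- vapply(reads, `[[`, integer(1), "year")
  months <- vapply(reads, `[[`, integer(1), "month")
  if (any(is.na(years))) stop("unparseable layer dates in manifest", call. = FALSE)
  kind <- manifest$kind %||% if (all(!is.na(months))) "monthly_stack" else "annual_stack"
  if (kind == "monthly_stack") {
    ord <- order(years * 12 + months)
    vals <- array(NA_real_, dim = c(grid$n_rows, grid$n_cols, length(ord)))
    for (i in seq_along(ord)) vals[, , i] <- reads[[ord[i]]]$values
    monthly_stack(grid, tibble::tibble(year = years[ord], month = months[ord]), vals)
  } else if (kind == "driver_stack") {
    vars <- vapply(reads, `[[`, character(1), "variable")
    yrs <- sort(unique(years))
    variables <- lapply(split(seq_along(reads), vars), function(idx) {
      idx <- idx[order(years[idx])]
      vals <- array(NA_real_, dim = c(grid$n_rows, grid$n_cols, length(idx)))
      for (i in seq_along(idx)) vals[, , i] <- reads[[idx[i]]]$values
      vals
    })
    driver_stack(grid, yrs, variables[intersect(driver_names(), names(variables))])
  } else {
    ord <- order(years)
    vals <- array(NA_real_, dim = c(grid$n_rows, grid$n_cols, length(ord)))
    for (i in seq_along(ord)) vals[, , i] <- reads[[ord[i]]]$values
    annual_stack(grid, years[ord], vals)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a set of polylines in map coordinates
#'
#' @param coords List of numeric matrices, each `n x 2` with columns x, y and
#'   `n >= 2`, one matrix per polyline.
#' @param layer Character vector (recycled) labelling each line, e.g.
#'   `"road"` or `"river"`.
#' @return An object of class `line_set`.
#' @export
line_set <- function(coords = list(), layer = character()) {
  stopifnot(is.list(coords))
  for (m in coords) {
    stopifnot(is.matrix(m), ncol(m) == 2, nrow(m) >= 2)
  }
  if (length(coords) > 0 && length(layer) == 0) layer <- "line"
  layer <- rep_len(as.character(layer), length(coords))
  structure(list(coords = coords, layer = layer), class = "line_set")
}

#' @export
print.line_set <- function(x, ...) {
  cat(sprintf("<line_set> %d polyline(s)\n", length(x$coords)))
  invisible(x)
}

#' Write polylines as GeoJSON
#'
#' @param lines A [line_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lines_geojson <- function(lines, path) {
  features <- purrr::map2(lines$coords, lines$layer, function(m, lyr) {
    list(type = "Feature",
         properties = list(layer = lyr),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(m)),
                                              function(i) as.numeric(m[i, ]))))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polylines from GeoJSON
#'
#' Supports LineString and MultiLineString features; other geometry types are
#' skipped with a warning.
#'
#' @param path GeoJSON file.
#' @return A [line_set()].
#' @export
read_lines_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  coords <- list(); layer <- character()
  for (f in fc$features) {
    lyr <- f$properties$layer %||% "line"
    g <- f$geometry
    parts <- switch(g$type,
                    LineString = list(g$coordinates),
                    MultiLineString = g$coordinates,
                    { warning("skipping non-line geometry: ", g$type); NULL })
    for (p in parts) {
      m <- do.call(rbind, lapply(p, function(xy) as.numeric(unlist(xy)[1:2])))
      coords[[length(coords) + 1]] <- m
      layer <- c(layer, lyr)
    }
  }
  line_set(coords, layer)
}
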