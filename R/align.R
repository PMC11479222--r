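#' Resample a raster onto a target grid
#'
#' Continuous fields (drivers, NDVI) use bilinear interpolation between the
#' four nearest source pixel centers; categorical rasters must use nearest
#' neighbour. Under bilinear, any contributing nodata pixel makes the target
#' pixel nodata. Target centers outside the hull of source centers are
#' clamped to the edge (constant extrapolation), which matters when annual
#' drivers simulated on a coarser grid are brought up to the analysis grid.
#'
#' @param values Source matrix conforming to `source_grid`.
#' @param source_grid,target Source and target [raster_grid()]s; their map
#'   extents must overlap.
#' @param method `"bilinear"` or `"nearest"`.
#' @return A matrix conforming to `target`.
#' @export
align_to_grid <- function(values, source_grid, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  check_raster_conforms(values, source_grid)
  sx <- c(source_grid$origin_x,
          source_grid$origin_x + source_grid$n_cols * source_grid$pixel_size)
  sy <- c(source_grid$origin_y - source_grid$n_rows * source_grid$pixel_size,
          source_grid$origin_y)
  tx <- c(target$origin_x, target$origin_x + target$n_cols * target$pixel_size)
  ty <- c(target$origin_y - target$n_rows * target$pixel_size, target$origin_y)
  if (tx[1] >= sx[2] || tx[2] <= sx[1] || ty[1] >= sy[2] || ty[2] <= sy[1]) {
    stop("disjoint extents: source and target grids do not overlap", call. = FALSE)
  }
  ctr <- pixel_centers(target)
  # fractional (1-based) source indices of each target center
  fc <- (ctr$x - source_grid$origin_x) / source_grid$pixel_size + 0.5
  fr <- (source_grid$origin_y - ctr$y) / source_grid$pixel_size + 0.5
  nr <- source_grid$n_rows; nc <- source_grid$n_cols
  if (method == "nearest") {
    ic <- pmin(pmax(round(fc), 1), nc)
    ir <- pmin(pmax(round(fr), 1), nr)
    return(values[cbind(rep(ir, times = target$n_cols),
                        rep(ic, each = target$n_rows))] |>
             matrix(nrow = target$n_rows))
  }
  c0 <- pmin(pmax(floor(fc), 1), nc); c1 <- pmin(c0 + 1, nc)
  r0 <- pmin(pmax(floor(fr), 1), nr); r1 <- pmin(r0 + 1, nr)
  wc <- pmin(pmax(fc - c0, 0), 1)    # weight of the right column
  wr <- pmin(pmax(fr - r0, 0), 1)    # weight of the lower row
  R0 <- rep(r0, times = target$n_cols); R1 <- rep(r1, times = target$n_cols)
  C0 <- rep(c0, each = target$n_rows); C1 <- rep(c1, each = target$n_rows)
  WC <- rep(wc, each = target$n_rows); WR <- rep(wr, times = target$n_cols)
  v00 <- values[cbind(R0, C0)]; v01 <- values[cbind(R0, C1)]
  v10 <- values[cbind(R1, C0)]; v11 <- values[cbind(R1, C1)]
  out <- (1 - WR) * ((1 - WC) * v00 + WC * v01) + WR * ((1 - WC) * v10 + WC * v11)
  matrix(out, nrow = target$n_rows)
}

#' Rasterize a buffer around polylines
#'
#' A pixel is inside the buffer iff its center lies within `distance` map
#' units of any polyline segment (center-in-buffer rule, deterministic and
#' resolution independent). Used to cull the spuriously high heterogeneity
#' that rivers and roads induce in the focal CV.
#'
#' @param lines A [line_set()] (possibly empty).
#' @param distance Buffer distance in map units, `>= 0`.
#' @param grid Target [raster_grid()].
#' @param layers Optional character vector: only rasterize lines whose layer
#'   label is in this set.
#' @return Logical matrix, `TRUE` = inside the buffer.
#' @export
rasterize_buffer <- function(lines, distance, grid, layers = NULL) {
  if (distance < 0) stop("buffer distance must be >= 0", call. = FALSE)
  ctr <- pixel_centers(grid)
  X <- matrix(rep(ctr$x, each = grid$n_rows), nrow = grid$n_rows)
  Y <- matrix(rep(ctr$y, times = grid$n_cols), nrow = grid$n_rows)
  out <- matrix(FALSE, grid$n_rows, grid$n_cols)
  keep <- if (is.null(layers)) seq_along(lines$coords)
          else which(lines$layer %in% layers)
  d2max <- distance^2
  for (k in keep) {
    m <- lines$coords[[k]]
    for (s in seq_len(nrow(m) - 1)) {
      ax <- m[s, 1]; ay <- m[s, 2]
      bx <- m[s + 1, 1]; by <- m[s + 1, 2]
      dx <- bx - ax; dy <- by - ay
      len2 <- dx^2 + dy^2
      if (len2 == 0) {
        d2 <- (X - ax)^2 + (Y - ay)^2
      } else {
        t <- pmin(pmax(((X - ax) * dx + (Y - ay) * dy) / len2, 0), 1)
        d2 <- (X - (ax + t * dx))^2 + (Y - (ay + t * dy))^2
      }
      out <- out | (d2 <= d2max)
    }
  }
  out
}

#' Landcover classes recognised by the pipeline
#' @return Character vector of the legend.
#' @export
landcover_legend <- function() {
  c("grassland", "other", "impervious", "water", "wetland", "glacier")
}

#' Build the validity mask set
#'
#' Combines the landcover exclusion mask (impervious surfaces, open water,
#' wetlands, glaciers by default) with the river/road buffer mask into one
#' `combined` mask; `TRUE` everywhere means excluded.
#'
#' @param landcover Character matrix of landcover classes conforming to `grid`.
#' @param excluded_classes Classes to mask out.
#' @param lines A [line_set()] or `NULL`.
#' @param distance Buffer distance in map units; either a scalar applied to
#'   all lines or a named vector keyed by line layer (e.g.
#'   `c(road = 250, river = 500)`).
#' @param grid The analysis [raster_grid()].
#' @param legend Known landcover classes; an excluded class outside the
#'   legend is an error.
#' @return An object of class `mask_set` with logical matrices
#'   `landcover_mask`, `buffer_mask` and `combined`.
#' @export
build_mask_set <- function(landcover, excluded_classes = c("impervious", "water", "wetland", "glacier"),
                           lines = NULL, distance = 250, grid,
                           legend = landcover_legend()) {
  check_raster_conforms(landcover, grid, "landcover")
  unknown <- setdiff(excluded_classes, legend)
  if (length(unknown) > 0) {
    stop("unknown landcover class code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  lc_mask <- matrix(landcover %in% excluded_classes, grid$n_rows, grid$n_cols)
  if (is.null(lines) || length(lines$coords) == 0) {
    buf <- matrix(FALSE, grid$n_rows, grid$n_cols)
  } else if (is.null(names(distance))) {
    buf <- rasterize_buffer(lines, distance[1], grid)
  } else {
    buf <- matrix(FALSE, grid$n_rows, grid$n_cols)
    for (lyr in unique(lines$layer)) {
      d <- if (lyr %in% names(distance)) distance[[lyr]] else max(distance)
      buf <- buf | rasterize_buffer(lines, d, grid, layers = lyr)
    }
  }
  structure(list(landcover_mask = lc_mask, buffer_mask = buf,
                 combined = lc_mask | buf),
            class = "mask_set")
}
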