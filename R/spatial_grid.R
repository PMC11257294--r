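#' Analysis grid specification
#'
#' A regular lon/lat grid with half-open cell membership
#' `[x0, x0 + size) x [y0, y0 + size)`, so every finite coordinate maps to
#' exactly one cell. The origin must sit on integer multiples of the cell
#' size, which makes cell indices comparable across datasets.
#'
#' @param cell_size Cell edge in degrees (default 0.25, the analysis
#'   resolution).
#' @param origin `(lon, lat)` grid origin.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(cell_size = 0.25, origin = c(0, 0)) {
  stopifnot(cell_size > 0)
  if (any(abs(origin %% cell_size) > 1e-12 &
            abs(origin %% cell_size - cell_size) > 1e-12)) {
    stop("grid origin must be at integer multiples of the cell size")
  }
  structure(list(cell_size = cell_size, origin = as.numeric(origin)),
            class = "grid_spec")
}

#' Map coordinates to grid cells
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Coordinate vectors (finite).
#' @return A data.frame with integer cell indices `ix`, `iy` and a combined
#'   `cell` label.
#' @export
cell_index <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"))
  ix <- floor((lon - grid$origin[1]) / grid$cell_size + 1e-12)
  iy <- floor((lat - grid$origin[2]) / grid$cell_size + 1e-12)
  data.frame(ix = as.integer(ix), iy = as.integer(iy),
             cell = paste(ix, iy, sep = ":"), stringsAsFactors = FALSE)
}

#' Grid-cell centroids
#'
#' @param grid A [grid_spec()].
#' @param ix,iy Integer cell indices.
#' @return A data.frame with centroid `lon`, `lat`.
#' @export
cell_centroid <- function(grid, ix, iy) {
  data.frame(lon = grid$origin[1] + (ix + 0.5) * grid$cell_size,
             lat = grid$origin[2] + (iy + 0.5) * grid$cell_size)
}

# All cells whose centroid lies inside the study area.
study_area_cells <- function(grid, study_area) {
  bb <- polygon_bbox(study_area)
  ix <- seq(floor((bb["xmin"] - grid$origin[1]) / grid$cell_size),
            ceiling((bb["xmax"] - grid$origin[1]) / grid$cell_size))
  iy <- seq(floor((bb["ymin"] - grid$origin[2]) / grid$cell_size),
            ceiling((bb["ymax"] - grid$origin[2]) / grid$cell_size))
  g <- expand.grid(ix = as.integer(ix), iy = as.integer(iy))
  ctr <- cell_centroid(grid, g$ix, g$iy)
  g <- g[point_in_polygons(ctr$lon, ctr$lat, study_area), , drop = FALSE]
  g$cell <- paste(g$ix, g$iy, sep = ":")
  rownames(g) <- NULL
  g
}

#' Per-cell occurrence counts
#'
#' Bins records with coordinates into grid cells. When a study area is
#' supplied, every cell whose centroid falls inside it is listed, including
#' zero-count cells, so coverage gaps are visible. The total of the counts
#' equals the number of records binned.
#'
#' @param records Canonical occurrence data.frame (spatial tier).
#' @param grid A [grid_spec()].
#' @param study_area Optional polygon layer for zero-cell enumeration.
#' @return A data.frame with `cell`, `ix`, `iy`, centroid `lon`/`lat`, and
#'   `count`.
#' @export
grid_counts <- function(records, grid = grid_spec(), study_area = NULL) {
  ok <- !is.na(records$latitude) & !is.na(records$longitude)
  idx <- cell_index(grid, records$longitude[ok], records$latitude[ok])
  tab <- table(idx$cell)
  if (is.null(study_area)) {
    cells <- unique(idx[, c("ix", "iy", "cell")])
  } else {
    cells <- study_area_cells(grid, study_area)
    extra <- !(idx$cell %in% cells$cell)
    if (any(extra)) {
      cells <- rbind(cells, unique(idx[extra, c("ix", "iy", "cell")]))
    }
  }
  ctr <- cell_centroid(grid, cells$ix, cells$iy)
  out <- data.frame(cell = cells$cell, ix = cells$ix, iy = cells$iy,
                    lon = ctr$lon, lat = ctr$lat,
                    count = as.integer(tab[cells$cell]),
                    stringsAsFactors = FALSE)
  out$count[is.na(out$count)] <- 0L
  out[order(out$ix, out$iy), ]
}
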