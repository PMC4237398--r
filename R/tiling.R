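# Partition a landscape into large square cells (3 km x 3 km at the study's
# 30 m resolution, i.e. 100 x 100 pixels), filter cells by land coverage,
# and assemble the per-cell table of fragmentation indices, covariate
# summaries, and land-cover pixel-count increments that feeds the spatial
# regressions.

#' Tile a grid into non-overlapping square cells
#'
#' Windows of `cell_pixels` x `cell_pixels` anchored at the grid origin;
#' partial windows at the right/bottom edges are retained and flagged.
#'
#' @param grid An `fs_grid`.
#' @param cell_pixels Window edge length in pixels (default 100, the 3-km
#'   cell at 30 m resolution).
#' @return Tibble of footprints: `cell_id`, `row0`, `row1`, `col0`, `col1`
#'   (1-based inclusive pixel ranges), `partial`, `centroid_x`, `centroid_y`
#'   (projected meters, center of the actual window).
#' @export
tile_grid <- function(grid, cell_pixels = 100) {
  stopifnot(cell_pixels >= 1)
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  row_starts <- seq(1, nr, by = cell_pixels)
  col_starts <- seq(1, nc, by = cell_pixels)
  fp <- expand.grid(row0 = row_starts, col0 = col_starts)
  fp$row1 <- pmin(fp$row0 + cell_pixels - 1, nr)
  fp$col1 <- pmin(fp$col0 + cell_pixels - 1, nc)
  fp$partial <- (fp$row1 - fp$row0 + 1 < cell_pixels) |
    (fp$col1 - fp$col0 + 1 < cell_pixels)
  fp$centroid_x <- grid$origin[1] + (fp$col0 + fp$col1) / 2 * grid$cell_size -
    grid$cell_size / 2
  fp$centroid_y <- grid$origin[2] - ((fp$row0 + fp$row1) / 2 * grid$cell_size -
    grid$cell_size / 2)
  fp$cell_id <- seq_len(nrow(fp))
  as_tibble(fp[, c("cell_id", "row0", "row1", "col0", "col1", "partial",
                   "centroid_x", "centroid_y")])
}

cell_window <- function(grid, cell) {
  grid$values[cell$row0:cell$row1, cell$col0:cell$col1, drop = FALSE]
}

subgrid <- function(grid, cell) {
  vals <- cell_window(grid, cell)
  origin <- c(grid$origin[1] + (cell$col0 - 1) * grid$cell_size,
              grid$origin[2] - (cell$row0 - 1) * grid$cell_size)
  if (grid$kind == "categorical") {
    lc_grid(vals, cell_size = grid$cell_size, origin = origin,
            nodata = grid$nodata, vocabulary = grid$vocabulary)
  } else {
    covariate_grid(vals, cell_size = grid$cell_size, origin = origin,
                   nodata = grid$nodata)
  }
}

#' Count land pixels per cell footprint
#'
#' @param grid An `fs_grid`.
#' @param cells Footprints from [tile_grid()].
#' @return Integer vector, one count per cell.
#' @export
cell_land_counts <- function(grid, cells) {
  land <- land_mask(grid)
  vapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    sum(land[cl$row0:cl$row1, cl$col0:cl$col1])
  }, integer(1))
}

#' Filter cells by minimum land coverage
#'
#' Cells with fewer than `min_land_pixels` land pixels are discarded (the
#' study's rule: < 2,500 of 10,000, i.e. under 25% land).
#'
#' @param cells Footprints from [tile_grid()].
#' @param land_counts Land-pixel counts per cell, as from
#'   [cell_land_counts()].
#' @param min_land_pixels Retention threshold (default 2500).
#' @return The retained subset of `cells`, with a `land_pixel_count` column.
#' @export
filter_cells <- function(cells, land_counts, min_land_pixels = 2500) {
  stopifnot(length(land_counts) == nrow(cells))
  cells$land_pixel_count <- land_counts
  cells[land_counts >= min_land_pixels, ]
}

#' Exact Euclidean distance-to-urban surface
#'
#' Distance in meters from every pixel center to the nearest urban pixel
#' center of a reference grid (0 on urban pixels). Urban includes the
#' high-density subclass.
#'
#' @param urban_reference Categorical `fs_grid` with at least one urban
#'   pixel.
#' @return A continuous `fs_grid` of distances (m).
#' @export
distance_to_urban_surface <- function(urban_reference) {
  urb <- class_mask(urban_reference, LC_CLASSES[["URBAN"]])
  if (!any(urb)) stop("reference grid has no urban pixels", call. = FALSE)
  d <- sqrt(edt_sq_cpp(urb)) * urban_reference$cell_size
  covariate_grid(d, cell_size = urban_reference$cell_size,
                 origin = urban_reference$origin, nodata = -9999)
}

#' Horn slope surface from elevation
#'
#' 8-neighbour Horn gradient, in degrees. Border pixels use replicated
#' edges.
#'
#' @param elevation Continuous `fs_grid`, meters.
#' @return Continuous `fs_grid` of slopes in degrees.
#' @export
horn_slope <- function(elevation) {
  z <- elevation$values
  nr <- nrow(z)
  nc <- ncol(z)
  pad <- z[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  sh <- function(dr, dc) pad[(1:nr) + 1 + dr, (1:nc) + 1 + dc]
  cs <- elevation$cell_size
  dzdx <- ((sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
           (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))) / (8 * cs)
  dzdy <- ((sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
           (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  covariate_grid(slope, cell_size = cs, origin = elevation$origin,
                 nodata = elevation$nodata)
}

#' Assemble the per-cell analysis table
#'
#' For every retained cell, computes the fragmentation indices per class
#' and year treating the cell as its own landscape (A_T = the cell's land
#' area), covariate means and standard deviations over land pixels, and
#' signed pixel-count increments per increment class between the first and
#' last year.
#'
#' Metric columns are named `<index>_<class name>_<year>` (e.g.
#' `ED_FOREST_2000`), increments `dN_<class name>`, covariates
#' `<name>_mean` / `<name>_sd`. Undefined metrics (no focal patches in the
#' cell) are `NA`.
#'
#' @param cells Retained footprints from [filter_cells()].
#' @param year_grids Named list of aligned categorical `fs_grid`s, names =
#'   years, in chronological order.
#' @param covariates Named list of aligned continuous `fs_grid`s (e.g.
#'   `dist_urban` in meters, `slope` deg, `elevation` m, `pop_density`).
#' @param classes Metric classes (default urban, forest, wetland).
#' @param increment_classes Classes whose pixel-count increments are
#'   tabulated (default urban, high-density urban, forest, pasture,
#'   wetland, agriculture). `URBAN` here counts the urban superclass
#'   (including high-density); `HIGH_DENSITY_URBAN` counts the subclass
#'   alone.
#' @param connectivity,boundary_policy,edge_area_unit Passed to the patch
#'   metrics.
#' @return Tibble, one row per cell. Distance-to-urban means are reported
#'   in km (`dist_urban_mean`), matching the scale on which the regression
#'   coefficients are interpreted; all other covariates keep their units.
#' @export
summarize_cells <- function(cells, year_grids, covariates = list(),
                            classes = LC_CLASSES[c("URBAN", "FOREST", "WETLAND")],
                            increment_classes = LC_CLASSES[c("URBAN",
                              "HIGH_DENSITY_URBAN", "FOREST", "PASTURE",
                              "WETLAND", "AGRICULTURE")],
                            connectivity = 8, boundary_policy = "exclude",
                            edge_area_unit = "ha") {
  stopifnot(length(year_grids) >= 1, !is.null(names(year_grids)))
  if (length(year_grids) >= 2) {
    do.call(require_aligned, c(unname(year_grids), list(what = "cell summary")))
  }
  years <- names(year_grids)
  first <- year_grids[[1]]
  last <- year_grids[[length(year_grids)]]
  class_names <- names(LC_CLASSES)[match(classes, LC_CLASSES)]
  inc_names <- names(LC_CLASSES)[match(increment_classes, LC_CLASSES)]

  count_class <- function(vals, code, nodata) {
    if (code == LC_CLASSES[["URBAN"]]) {
      sum(vals %in% c(LC_CLASSES[["URBAN"]], LC_CLASSES[["HIGH_DENSITY_URBAN"]]) &
            vals != nodata)
    } else {
      sum(vals == code & vals != nodata)
    }
  }

  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    row <- list(cell_id = cl$cell_id, centroid_x = cl$centroid_x,
                centroid_y = cl$centroid_y, partial = cl$partial)
    if ("land_pixel_count" %in% names(cells)) {
      row$land_pixel_count <- cl$land_pixel_count
    }
    for (y in years) {
      sg <- subgrid(year_grids[[y]], cl)
      mets <- all_class_metrics(sg, classes, connectivity, boundary_policy,
                                edge_area_unit)
      for (j in seq_along(classes)) {
        m <- mets[mets$class == classes[j], ]
        for (idx in c("AREA_MN", "LPI", "ED", "EDGE_AREA")) {
          row[[paste(idx, class_names[j], y, sep = "_")]] <- m[[idx]]
        }
      }
    }
    for (nm in names(covariates)) {
      w <- cell_window(covariates[[nm]], cl)
      land <- w != covariates[[nm]]$nodata & !is.na(w)
      v <- w[land]
      scale <- if (nm == "dist_urban") 1 / 1000 else 1  # report D in km
      row[[paste0(nm, "_mean")]] <- if (length(v)) mean(v) * scale else NA_real_
      row[[paste0(nm, "_sd")]] <- if (length(v) > 1) sd(v) * scale else NA_real_
    }
    if (length(year_grids) >= 2) {
      w1 <- cell_window(first, cl)
      w2 <- cell_window(last, cl)
      for (j in seq_along(increment_classes)) {
        row[[paste0("dN_", inc_names[j])]] <-
          count_class(w2, increment_classes[j], last$nodata) -
          count_class(w1, increment_classes[j], first$nodata)
      }
    }
    as_tibble(row)
  })
  do.call(rbind, rows)
}
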