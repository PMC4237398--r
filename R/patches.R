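# Patch delineation and the four class-level fragmentation indices:
# AREA_MN (mean patch area, ha), LPI (largest patch index, % of landscape),
# ED (edge density, m per ha of landscape), EDGE_AREA (edge per focal area).
#
# Patches are maximal connected components of the focal class, 8-neighbour
# by default (the FRAGSTATS convention). Edge is always counted on
# 4-neighbour pixel faces of length cell_size: a diagonal adjacency has no
# physical boundary face.

#' Delineate patches of a focal class
#'
#' @param grid Categorical `fs_grid`.
#' @param focal_class Class code; for `URBAN` the high-density subclass is
#'   included.
#' @param connectivity 8 (default, FRAGSTATS rule) or 4.
#' @param boundary_policy `"exclude"` (default): faces against nodata or the
#'   grid border are not edge; `"include"`: they are.
#' @return An `fs_patchset`: `labels` (integer matrix, 0 = not focal),
#'   `n`, `patch_area` (m^2), `patch_edge` (m), `focal_class`,
#'   `landscape_area` (m^2), `cell_size`, `connectivity`, `boundary_policy`.
#' @examples
#' g <- lc_grid(matrix(c(3, 3, 0, 3), 2, 2), cell_size = 30, vocabulary = c(0, 3))
#' label_patches(g, 3)$n
#' @export
label_patches <- function(grid, focal_class, connectivity = 8,
                          boundary_policy = c("exclude", "include")) {
  stopifnot(inherits(grid, "fs_grid"), grid$kind == "categorical")
  boundary_policy <- match.arg(boundary_policy)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  if (!focal_class %in% grid$vocabulary &&
      !(focal_class == LC_CLASSES[["URBAN"]] &&
        LC_CLASSES[["HIGH_DENSITY_URBAN"]] %in% grid$vocabulary)) {
    stop("focal class ", focal_class, " not in grid vocabulary", call. = FALSE)
  }
  focal <- class_mask(grid, focal_class)
  labels <- label_components_cpp(focal, as.integer(connectivity))
  n <- attr(labels, "n")
  area <- if (n > 0) tabulate(labels[labels > 0], nbins = n) * grid$cell_size^2 else numeric(0)
  ps <- structure(
    list(labels = labels, n = n, patch_area = area,
         patch_edge = numeric(n), focal_class = as.integer(focal_class),
         landscape_area = landscape_area(grid), cell_size = grid$cell_size,
         connectivity = connectivity, boundary_policy = boundary_policy,
         nodata_mask = !land_mask(grid)),
    class = "fs_patchset"
  )
  compute_edges(ps, boundary_policy)
}

#' Recompute per-patch edge lengths under a boundary policy
#'
#' Edge is the count of 4-adjacent pixel faces between a patch and non-focal
#' land pixels, times `cell_size`; under `"include"` faces against nodata and
#' the grid border are edge as well.
#'
#' @param patchset An `fs_patchset`.
#' @param boundary_policy `"exclude"` or `"include"`.
#' @return The patchset with `patch_edge` repopulated.
#' @export
compute_edges <- function(patchset, boundary_policy = c("exclude", "include")) {
  boundary_policy <- match.arg(boundary_policy)
  if (patchset$n > 0) {
    faces <- patch_edge_faces_cpp(patchset$labels, patchset$nodata_mask,
                                  patchset$n, boundary_policy == "include")
    patchset$patch_edge <- faces * patchset$cell_size
  } else {
    patchset$patch_edge <- numeric(0)
  }
  patchset$boundary_policy <- boundary_policy
  patchset
}

#' @export
print.fs_patchset <- function(x, ...) {
  cat(sprintf("<fs_patchset> class %d: %d patch(es), focal area %g ha, edge %g m\n",
              x$focal_class, x$n, sum(x$patch_area) / 1e4, sum(x$patch_edge)))
  invisible(x)
}

#' Class-level fragmentation indices from a patch set
#'
#' * `AREA_MN` = mean patch area, hectares.
#' * `LPI` = 100 * max(a_i) / A_T, percent of landscape in the largest patch.
#' * `ED` = 10^4 * sum(e_i) / A_T, meters of edge per hectare of landscape.
#' * `EDGE_AREA` = sum(e_i) per unit focal area; with the default
#'   `edge_area_unit = "ha"` this is meters of edge per hectare of focal
#'   class (the scale on which multi-hectare mean patches give values in the
#'   hundreds), with `"m2"` it is m per m^2.
#'
#' A class with zero patches yields `NA` indices and `undefined = TRUE` —
#' never zeros, which would corrupt downstream regressions.
#'
#' @param patchset An `fs_patchset`.
#' @param edge_area_unit `"ha"` (default) or `"m2"` focal-area unit for
#'   `EDGE_AREA`.
#' @return One-row tibble: `class`, `n_patches`, `A` (focal area m^2),
#'   `AREA_MN`, `LPI`, `ED`, `EDGE_AREA`, `edge_area_unit`, `undefined`.
#' @export
class_metrics <- function(patchset, edge_area_unit = c("ha", "m2")) {
  edge_area_unit <- match.arg(edge_area_unit)
  if (patchset$n == 0) {
    return(tibble(
      class = patchset$focal_class, n_patches = 0L, A = 0,
      AREA_MN = NA_real_, LPI = NA_real_, ED = NA_real_, EDGE_AREA = NA_real_,
      edge_area_unit = edge_area_unit, undefined = TRUE
    ))
  }
  A <- sum(patchset$patch_area)
  total_edge <- sum(patchset$patch_edge)
  A_focal_unit <- if (edge_area_unit == "ha") A / 1e4 else A
  tibble(
    class = patchset$focal_class,
    n_patches = patchset$n,
    A = A,
    AREA_MN = (A / patchset$n) / 1e4,
    LPI = 100 * max(patchset$patch_area) / patchset$landscape_area,
    ED = 1e4 * total_edge / patchset$landscape_area,
    EDGE_AREA = total_edge / A_focal_unit,
    edge_area_unit = edge_area_unit,
    undefined = FALSE
  )
}

#' Fragmentation indices for several classes of one landscape
#'
#' Applies [label_patches()] and [class_metrics()] per class against the
#' shared landscape area of `grid`.
#'
#' @inheritParams label_patches
#' @param classes Integer class codes (default: every code in the grid
#'   vocabulary, with the urban subclass folded into urban).
#' @param edge_area_unit Passed to [class_metrics()].
#' @return Tibble, one row per class.
#' @export
all_class_metrics <- function(grid, classes = NULL, connectivity = 8,
                              boundary_policy = "exclude",
                              edge_area_unit = "ha") {
  if (is.null(classes)) {
    classes <- setdiff(grid$vocabulary, LC_CLASSES[["HIGH_DENSITY_URBAN"]])
  }
  in_vocab <- function(cl) {
    cl %in% grid$vocabulary ||
      (cl == LC_CLASSES[["URBAN"]] &&
         LC_CLASSES[["HIGH_DENSITY_URBAN"]] %in% grid$vocabulary)
  }
  rows <- lapply(classes, function(cl) {
    if (!in_vocab(cl)) {
      # class absent from this map: undefined, never zero
      return(tibble(class = as.integer(cl), n_patches = 0L, A = 0,
                    AREA_MN = NA_real_, LPI = NA_real_, ED = NA_real_,
                    EDGE_AREA = NA_real_, edge_area_unit = edge_area_unit,
                    undefined = TRUE))
    }
    ps <- label_patches(grid, cl, connectivity, boundary_policy)
    class_metrics(ps, edge_area_unit)
  })
  do.call(rbind, rows)
}

#' Pivot a class-metrics table to tidy long form
#'
#' One row per (class, index, value) — the interchange CSV layout.
#'
#' @param metrics Output of [all_class_metrics()].
#' @param grid_id Optional identifier column value.
#' @return Tibble with `grid_id`, `class`, `index`, `value`.
#' @export
tidy_metrics <- function(metrics, grid_id = NA_character_) {
  idx <- c("AREA_MN", "LPI", "ED", "EDGE_AREA")
  out <- do.call(rbind, lapply(idx, function(i) {
    tibble(grid_id = grid_id, class = metrics$class, index = i,
           value = metrics[[i]])
  }))
  out[order(out$class), ]
}
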