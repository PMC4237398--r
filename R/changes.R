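# Forest change classification between two dates, counterfactual scenario
# landscapes (deforestation-only / reforestation-only / urban-masked), and
# change-site distance statistics.

#' Classify per-pixel forest change between two dates
#'
#' Partitions land pixels into unchanged forest (forest at both dates, F_F),
#' deforested (forest only at t1), reforested (forest only at t2), and
#' never-forest.
#'
#' @param grid_t1,grid_t2 Aligned categorical `fs_grid`s containing a
#'   `FOREST` class.
#' @return An `fs_changemap`: `categories` matrix over [CHANGE_CODES] with
#'   nodata preserved, plus geometry fields.
#' @export
classify_forest_change <- function(grid_t1, grid_t2) {
  require_aligned(grid_t1, grid_t2, what = "forest change classification")
  f1 <- class_mask(grid_t1, LC_CLASSES[["FOREST"]])
  f2 <- class_mask(grid_t2, LC_CLASSES[["FOREST"]])
  land <- land_mask(grid_t1) & land_mask(grid_t2)
  cat_m <- matrix(CHANGE_CODES[["NEVER_FOREST"]],
                  nrow(grid_t1$values), ncol(grid_t1$values))
  cat_m[f1 & f2] <- CHANGE_CODES[["UNCHANGED_FOREST"]]
  cat_m[f1 & !f2] <- CHANGE_CODES[["DEFORESTED"]]
  cat_m[!f1 & f2] <- CHANGE_CODES[["REFORESTED"]]
  cat_m[!land] <- grid_t1$nodata
  structure(
    list(categories = cat_m, cell_size = grid_t1$cell_size,
         origin = grid_t1$origin, nodata = grid_t1$nodata),
    class = "fs_changemap"
  )
}

#' @export
print.fs_changemap <- function(x, ...) {
  tab <- table(factor(x$categories[x$categories != x$nodata],
                      levels = CHANGE_CODES, labels = names(CHANGE_CODES)))
  cat("<fs_changemap>\n")
  print(tab)
  invisible(x)
}

#' Build a counterfactual scenario landscape from a change map
#'
#' Scenario forest masks:
#' * `TRUE_T1`: unchanged forest + deforested pixels (the t1 forest).
#' * `TRUE_T2`: unchanged forest + reforested pixels (the t2 forest).
#' * `DEFORESTATION_ONLY`: unchanged forest only — t2 forest with the
#'   reforested sites eliminated.
#' * `REFORESTATION_ONLY`: the union of t1 and t2 forest — no deforestation
#'   occurred.
#'
#' Non-forest land pixels carry the single background class `OTHER`;
#' focal-class metrics are invariant to background labels.
#'
#' @param change An `fs_changemap`.
#' @param which Scenario tag.
#' @return An `fs_grid` with a `scenario` attribute.
#' @export
build_scenario <- function(change,
                           which = c("TRUE_T1", "TRUE_T2",
                                     "DEFORESTATION_ONLY", "REFORESTATION_ONLY")) {
  which <- match.arg(which)
  cc <- change$categories
  forest <- switch(which,
    TRUE_T1 = cc == CHANGE_CODES[["UNCHANGED_FOREST"]] | cc == CHANGE_CODES[["DEFORESTED"]],
    TRUE_T2 = cc == CHANGE_CODES[["UNCHANGED_FOREST"]] | cc == CHANGE_CODES[["REFORESTED"]],
    DEFORESTATION_ONLY = cc == CHANGE_CODES[["UNCHANGED_FOREST"]],
    REFORESTATION_ONLY = cc %in% c(CHANGE_CODES[["UNCHANGED_FOREST"]],
                                   CHANGE_CODES[["DEFORESTED"]],
                                   CHANGE_CODES[["REFORESTED"]])
  )
  forest <- matrix(forest, nrow(cc))
  vals <- matrix(LC_CLASSES[["OTHER"]], nrow(cc), ncol(cc))
  vals[forest] <- LC_CLASSES[["FOREST"]]
  vals[cc == change$nodata] <- change$nodata
  g <- lc_grid(vals, cell_size = change$cell_size, origin = change$origin,
               nodata = change$nodata,
               vocabulary = c(LC_CLASSES[["FOREST"]], LC_CLASSES[["OTHER"]]))
  attr(g, "scenario") <- which
  g
}

#' Mask the urban-union footprint out of a landscape
#'
#' Pixels urban at either date are removed from the landscape (set to
#' nodata), so that A_T shrinks and forest metrics are computed "outside
#' urban areas". Setting `to_nodata = FALSE` instead converts them to the
#' background class `OTHER`, keeping A_T fixed.
#'
#' @param grid Categorical `fs_grid`.
#' @param urban_t1,urban_t2 Logical matrices (or categorical `fs_grid`s, from
#'   which the urban classes are taken) aligned with `grid`.
#' @param to_nodata Remove masked pixels from the landscape? Default `TRUE`.
#' @return A masked `fs_grid`.
#' @export
apply_urban_mask <- function(grid, urban_t1, urban_t2, to_nodata = TRUE) {
  as_mask <- function(u) {
    if (inherits(u, "fs_grid")) {
      require_aligned(grid, u, what = "urban masking")
      class_mask(u, LC_CLASSES[["URBAN"]])
    } else {
      stopifnot(identical(dim(u), dim(grid$values)))
      u
    }
  }
  mask <- as_mask(urban_t1) | as_mask(urban_t2)
  vals <- grid$values
  vals[mask] <- if (to_nodata) grid$nodata else LC_CLASSES[["OTHER"]]
  lc_grid(vals, cell_size = grid$cell_size, origin = grid$origin,
          nodata = grid$nodata,
          vocabulary = sort(unique(c(grid$vocabulary, LC_CLASSES[["OTHER"]]))))
}

#' Mean distance from change sites to the nearest unchanged forest
#'
#' For every pixel of the chosen category, the Euclidean center-to-center
#' distance to the nearest unchanged-forest pixel is found by an exact
#' distance transform; the mean is returned in meters. By construction a
#' category pixel is never itself unchanged forest, so distances are > 0.
#'
#' @param change An `fs_changemap`.
#' @param category `"DEFORESTED"` or `"REFORESTED"`.
#' @return Mean distance, meters.
#' @export
mean_distance_to_unchanged <- function(change,
                                       category = c("REFORESTED", "DEFORESTED")) {
  category <- match.arg(category)
  cc <- change$categories
  seeds <- cc == CHANGE_CODES[["UNCHANGED_FOREST"]]
  sites <- cc == CHANGE_CODES[[category]]
  if (!any(seeds)) stop("no unchanged-forest pixels", call. = FALSE)
  if (!any(sites)) stop("no ", category, " pixels", call. = FALSE)
  d2 <- edt_sq_cpp(seeds)
  mean(sqrt(d2[sites])) * change$cell_size
}

#' Relative change of an index against a reference value
#'
#' `100 * (value - reference) / reference`, sign preserved.
#'
#' @param reference Non-zero reference (e.g. the 1991 index).
#' @param value Comparison value.
#' @return Percent change.
#' @examples
#' relative_change(8.03, 6.07)  # about -24.4
#' @export
relative_change <- function(reference, value) {
  if (any(reference == 0)) stop("reference must be non-zero", call. = FALSE)
  100 * (value - reference) / reference
}
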