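# Orchestration of the two analyses: the island-wide index/scenario
# comparison and the gridded spatial-error regression study. These
# functions are the package's "command line": each returns plain tables
# ready to write as CSV.

#' Island-wide fragmentation, scenario and change-distance analysis
#'
#' Computes the four fragmentation indices per class for both years, the
#' forest indices with the urban-union footprint masked out of the
#' landscape, the deforestation-only and reforestation-only counterfactual
#' scenarios, the mean distances of reforested and deforested sites to
#' unchanged forest, and the relative changes of the forest indices under
#' each scenario against the first year.
#'
#' @param grid_t1,grid_t2 Aligned categorical `fs_grid`s (reclassified to
#'   the analysis vocabulary), earlier and later year.
#' @param years Length-2 labels for the two dates.
#' @param classes Classes for the per-year index table.
#' @param connectivity,boundary_policy,edge_area_unit Metric settings.
#' @return List of tibbles: `metrics` (scenario, class, year, indices),
#'   `distances`, `relative_changes`.
#' @export
run_island_wide <- function(grid_t1, grid_t2, years = c("t1", "t2"),
                            classes = LC_CLASSES[c("URBAN", "FOREST", "WETLAND")],
                            connectivity = 8, boundary_policy = "exclude",
                            edge_area_unit = "ha") {
  require_aligned(grid_t1, grid_t2, what = "island-wide analysis")
  grids <- list(grid_t1, grid_t2)
  met <- function(grid, scenario, year, cls = classes) {
    m <- all_class_metrics(grid, cls, connectivity, boundary_policy,
                           edge_area_unit)
    cbind(tibble(scenario = scenario,
                 class_name = names(LC_CLASSES)[match(m$class, LC_CLASSES)],
                 year = year), m)
  }
  rows <- list()
  for (i in 1:2) rows[[i]] <- met(grids[[i]], "true", years[i])

  masked <- lapply(grids, apply_urban_mask, urban_t1 = grid_t1,
                   urban_t2 = grid_t2)
  for (i in 1:2) {
    rows[[length(rows) + 1]] <- met(masked[[i]], "outside_urban", years[i],
                                    cls = LC_CLASSES[["FOREST"]])
  }

  change <- classify_forest_change(grid_t1, grid_t2)
  for (sc in c("DEFORESTATION_ONLY", "REFORESTATION_ONLY")) {
    g <- build_scenario(change, sc)
    rows[[length(rows) + 1]] <- met(g, tolower(sc), NA_character_,
                                    cls = LC_CLASSES[["FOREST"]])
  }
  metrics <- do.call(rbind, rows)

  has_unchanged <- any(change$categories == CHANGE_CODES[["UNCHANGED_FOREST"]])
  dist_of <- function(cat) {
    if (has_unchanged &&
        any(change$categories == CHANGE_CODES[[cat]])) {
      mean_distance_to_unchanged(change, cat)
    } else NA_real_
  }
  distances <- tibble(
    category = c("REFORESTED", "DEFORESTED"),
    mean_distance_m = c(dist_of("REFORESTED"), dist_of("DEFORESTED"))
  )

  f1 <- metrics[metrics$scenario == "true" & metrics$class_name == "FOREST" &
                  metrics$year == years[1], ]
  rel_rows <- list()
  for (sc in c("true", "outside_urban", "deforestation_only",
               "reforestation_only")) {
    cmp <- metrics[metrics$scenario == sc & metrics$class_name == "FOREST", ]
    cmp <- cmp[nrow(cmp), ]  # later year (or the single scenario row)
    if (identical(sc, "true") || identical(sc, "outside_urban")) {
      ref <- metrics[metrics$scenario == sc & metrics$class_name == "FOREST" &
                       metrics$year == years[1], ]
    } else {
      ref <- f1
    }
    for (idx in c("AREA_MN", "LPI", "ED", "EDGE_AREA")) {
      if (is.na(ref[[idx]]) || is.na(cmp[[idx]]) || ref[[idx]] == 0) next
      rel_rows[[length(rel_rows) + 1]] <- tibble(
        scenario = sc, index = idx, reference = ref[[idx]],
        value = cmp[[idx]],
        relative_change_pct = relative_change(ref[[idx]], cmp[[idx]]))
    }
  }
  list(metrics = as_tibble(metrics),
       distances = distances,
       relative_changes = do.call(rbind, rel_rows))
}

#' Gridded spatial-error regression analysis
#'
#' Tiles the landscape into large cells, filters them by land coverage,
#' assembles the cell table, and fits: (1) intercept-only spatial-error
#' models to the 1991-to-2000-style index increments per class; (2)
#' AIC-selected spatial-error models of the chosen indices on the
#' biophysical/socioeconomic drivers per year, with quadratic terms; (3)
#' the increment-on-area-change regressions; and (4) extracts
#' distance-to-urban peak locations and their shift rate between years.
#'
#' @param year_grids Named list (years, chronological) of aligned
#'   categorical `fs_grid`s.
#' @param covariates Named list of aligned continuous `fs_grid`s; must
#'   include `dist_urban`, `slope`; `elevation` and `pop_density` are used
#'   when present.
#' @param cell_pixels,min_land_pixels Tiling and retention settings
#'   (defaults 100 pixels and 2500 land pixels: the 3-km / 25% rule at
#'   30 m).
#' @param k Nearest neighbours for the spatial weights (default 8).
#' @param driver_responses Which (index, class) pairs to regress on the
#'   drivers; default urban EDGE_AREA and ED, forest ED and AREA_MN.
#' @param interval_years Number of years between the first and last
#'   land-cover dates, for the peak shift rate; default parsed from the
#'   year names when they are numeric.
#' @param classes Metric classes for the cell table.
#' @return List: `cells`, `intercept_report`, `driver_fits`,
#'   `driver_report`, `increment_fits`, `increment_report`, `peak_fits`
#'   (the per-year pure-quadratic distance fits), `peak_report`,
#'   `slope_extrema` (extrema of the AIC-selected driver fits in slope and
#'   slope-SD), `peak_shifts`.
#' @export
run_grid_analysis <- function(year_grids, covariates,
                              cell_pixels = 100, min_land_pixels = 2500,
                              k = 8,
                              driver_responses = list(
                                EDGE_AREA_URBAN = c("EDGE_AREA", "URBAN"),
                                ED_URBAN = c("ED", "URBAN"),
                                ED_FOREST = c("ED", "FOREST"),
                                AREA_MN_FOREST = c("AREA_MN", "FOREST")),
                              interval_years = NULL,
                              classes = LC_CLASSES[c("URBAN", "FOREST", "WETLAND")]) {
  stopifnot(length(year_grids) >= 2, !is.null(names(year_grids)))
  years <- names(year_grids)
  ref <- year_grids[[1]]
  cells <- tile_grid(ref, cell_pixels)
  counts <- cell_land_counts(ref, cells)
  cells <- filter_cells(cells, counts, min_land_pixels)
  if (nrow(cells) < k + 2) {
    stop("only ", nrow(cells), " cells retained; too few for k = ", k,
         " spatial weights", call. = FALSE)
  }
  tab <- summarize_cells(cells, year_grids, covariates, classes = classes)

  # (1) Table-3-style intercept-only fits of the index increments
  t1 <- years[1]
  t2 <- years[length(years)]
  class_names <- names(LC_CLASSES)[match(classes, LC_CLASSES)]
  int_rows <- list()
  for (cn in class_names) {
    for (idx in c("AREA_MN", "LPI", "EDGE_AREA", "ED")) {
      c1 <- paste(idx, cn, t1, sep = "_")
      c2 <- paste(idx, cn, t2, sep = "_")
      if (!all(c(c1, c2) %in% names(tab))) next
      dy <- tab[[c2]] - tab[[c1]]
      keep <- !is.na(dy)
      if (sum(keep) < k + 2) next
      w <- knn_weights(tab[keep, c("centroid_x", "centroid_y")], k = k)
      fit <- fit_intercept_only(dy[keep], w)
      est <- fit$coefficients$estimate[1]
      mean_level <- mean(c(tab[[c1]][keep], tab[[c2]][keep]), na.rm = TRUE)
      int_rows[[length(int_rows) + 1]] <- tibble(
        class_name = cn, index = idx, intercept = est,
        p = fit$coefficients$p[1], stars = fit$coefficients$stars[1],
        relative_change = if (mean_level != 0) est / mean_level else NA_real_,
        n = fit$n)
    }
  }
  intercept_report <- do.call(rbind, int_rows)

  # (2) driver regressions per response and year, AIC-selected
  drv <- tibble(
    D = tab$dist_urban_mean,
    D_sq = tab$dist_urban_mean^2,
    s = tab$slope_mean,
    s_sq = tab$slope_mean^2,
    sigma_s = tab$slope_sd,
    sigma_s_sq = tab$slope_sd^2
  )
  if ("pop_density_mean" %in% names(tab)) drv$d_p <- tab$pop_density_mean
  candidates <- names(drv)
  driver_fits <- list()
  for (resp in names(driver_responses)) {
    idx <- driver_responses[[resp]][1]
    cn <- driver_responses[[resp]][2]
    for (y in years) {
      col <- paste(idx, cn, y, sep = "_")
      if (!col %in% names(tab)) next
      yv <- tab[[col]]
      keep <- !is.na(yv) & complete.cases(drv)
      if (sum(keep) <= length(candidates) + 3) next
      w <- knn_weights(tab[keep, c("centroid_x", "centroid_y")], k = k)
      intercept_mode <- if (idx == "AREA_MN") "search" else TRUE
      fit <- aic_select(yv[keep], drv[keep, ], candidates, w,
                        intercept = intercept_mode)
      driver_fits[[paste(resp, y, sep = "_")]] <- fit
    }
  }

  # (3) increment-on-area-change regressions
  increment_fits <- fit_increment_models(tab, t1 = t1, t2 = t2, k = k)

  # (4) distance-to-urban peaks and their shift. Vertex locations are only
  # comparable between years when both years carry the same functional
  # form, so the peak fits are dedicated intercept + D + D^2 spatial-error
  # models per response and year (the published models retained both D
  # orders in every year for the responses tracked here).
  peak_fits <- list()
  for (resp in names(driver_responses)) {
    idx <- driver_responses[[resp]][1]
    cn <- driver_responses[[resp]][2]
    for (y in years) {
      col <- paste(idx, cn, y, sep = "_")
      if (!col %in% names(tab)) next
      yv <- tab[[col]]
      keep <- !is.na(yv) & !is.na(drv$D)
      if (sum(keep) <= 5 || sum(keep) <= k) next
      w <- knn_weights(tab[keep, c("centroid_x", "centroid_y")], k = k)
      X <- build_design(drv[keep, ], c("D", "D_sq"))
      fit <- tryCatch(fit_sem(yv[keep], X, w), error = function(e) NULL)
      if (!is.null(fit)) peak_fits[[paste(resp, y, sep = "_")]] <- fit
    }
  }
  peak_report <- slope_extrema_report(peak_fits, predictors = "D")
  slope_extrema <- slope_extrema_report(driver_fits,
                                        predictors = c("s", "sigma_s"))
  peak_shifts <- NULL
  if (is.null(interval_years)) {
    yr_num <- suppressWarnings(as.numeric(years))
    if (!anyNA(yr_num)) interval_years <- yr_num[length(yr_num)] - yr_num[1]
  }
  if (!is.null(interval_years) && nrow(peak_report) > 0) {
    sh_rows <- list()
    for (resp in names(driver_responses)) {
      m1 <- paste(resp, t1, sep = "_")
      m2 <- paste(resp, t2, sep = "_")
      p1 <- peak_report[peak_report$model == m1 & peak_report$predictor == "D", ]
      p2 <- peak_report[peak_report$model == m2 & peak_report$predictor == "D", ]
      if (nrow(p1) != 1 || nrow(p2) != 1) next
      if (!identical(p1$kind, p2$kind)) next
      if (round(p1$location, 1) == 0) next
      sh <- peak_shift(p1$location, p2$location, interval_years)
      sh_rows[[length(sh_rows) + 1]] <- tibble(
        response = resp, kind = p1$kind, earlier = sh$earlier,
        later = sh$later, years = interval_years,
        absolute_rate = sh$absolute_rate, relative_rate = sh$relative_rate)
    }
    peak_shifts <- if (length(sh_rows)) do.call(rbind, sh_rows) else NULL
  }

  list(cells = tab,
       intercept_report = intercept_report,
       driver_fits = driver_fits,
       driver_report = sem_report(driver_fits),
       increment_fits = increment_fits,
       increment_report = if (length(increment_fits)) sem_report(increment_fits) else NULL,
       peak_fits = peak_fits,
       peak_report = peak_report,
       slope_extrema = slope_extrema,
       peak_shifts = peak_shifts)
}
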