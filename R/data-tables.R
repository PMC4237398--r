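# Published reference tables shipped with the package. Both come from the
# Puerto Rico 1977/1991/2000 land-cover fragmentation study that this
# pipeline re-implements; the source maps themselves are not distributable,
# so these printed results serve as inputs for worked examples and for the
# peak-shift arithmetic.

#' Published spatial-error-model coefficients (Puerto Rico)
#'
#' Tidy table of the retained coefficients of the published spatial-error
#' regressions of urban and forest fragmentation indices (EDGE_AREA, ED,
#' AREA_MN) on distance to urban centers `D` (km), slope `s` and its
#' standard deviation `sigma_s` (degrees), and population density `d_p`
#' (persons per km^2), for 1977, 1991 and 2000. Squared terms carry the
#' `_sq` suffix; rows absent from the published models are absent here.
#'
#' @return Tibble with columns `index`, `class`, `year`, `term`,
#'   `estimate`.
#' @export
sem_coefficient_table <- function() {
  path <- system.file("extdata", "sem_coefficients_puerto_rico.csv",
                      package = "fragscape", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Published island-wide fragmentation indices (Puerto Rico)
#'
#' The island-wide AREA_MN (ha), LPI (%), ED (m/ha) and EDGE_AREA values
#' for urban, wetland and forest cover in 1991 and 2000, together with the
#' forest-outside-urban rows and the deforestation-only /
#' reforestation-only counterfactual scenarios.
#'
#' @return Tibble with columns `scenario`, `class`, `year`, `AREA_MN`,
#'   `LPI`, `ED`, `EDGE_AREA`.
#' @export
island_metrics_table <- function() {
  path <- system.file("extdata", "island_metrics_puerto_rico.csv",
                      package = "fragscape", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Extremum of a published quadratic response in distance-to-urban
#'
#' Convenience wrapper: pulls the first- and second-order terms of one
#' published model from [sem_coefficient_table()] and returns the vertex.
#' A missing first-order term (the pure-quadratic AREA_MN models) puts the
#' extremum at 0.
#'
#' @param index `"EDGE_AREA"`, `"ED"` or `"AREA_MN"`.
#' @param class `"urban"` or `"forest"`.
#' @param year 1977, 1991 or 2000.
#' @param predictor `"D"` (default), `"s"` or `"sigma_s"`.
#' @return An `fs_extremum`.
#' @export
published_extremum <- function(index, class, year, predictor = "D") {
  tab <- sem_coefficient_table()
  rows <- tab[tab$index == index & tab$class == class & tab$year == year, ]
  if (nrow(rows) == 0) stop("no published model for ", index, "_", class,
                            "_", year, call. = FALSE)
  b2 <- rows$estimate[rows$term == paste0(predictor, "_sq")]
  if (length(b2) == 0) {
    stop("published model retains no second-order ", predictor, " term",
         call. = FALSE)
  }
  b1 <- rows$estimate[rows$term == predictor]
  if (length(b1) == 0) b1 <- 0
  quadratic_extremum(b1, b2, predictor = predictor)
}
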