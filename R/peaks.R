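# Quadratic extrema of fitted responses and peak-shift rates.
#
# A response fitted as b1*x + b2*x^2 (plus terms in other covariates) has a
# stationary point at x* = -b1 / (2*b2): a maximum when b2 < 0, a minimum
# when b2 > 0. Tracking the extremum of a fragmentation index along the
# distance-to-urban axis across years measures how fast the sprawl front
# moves outward.

#' Extremum of a fitted quadratic term
#'
#' @param b1 First-order coefficient.
#' @param b2 Second-order coefficient (non-zero).
#' @param predictor Optional predictor name carried into the result.
#' @param intercept Constant added when evaluating the value at the
#'   extremum (default 0: the quadratic part alone).
#' @return An `fs_extremum` list: `location`, `kind` (`"maximum"` or
#'   `"minimum"`), `value`, `predictor`.
#' @examples
#' quadratic_extremum(56.9, -2.73)$location  # 10.42...
#' @export
quadratic_extremum <- function(b1, b2, predictor = NA_character_,
                               intercept = 0) {
  if (length(b2) != 1 || is.na(b2) || b2 == 0) {
    stop("no extremum: second-order coefficient is zero or missing",
         call. = FALSE)
  }
  loc <- -b1 / (2 * b2)
  structure(
    list(location = loc,
         kind = if (b2 < 0) "maximum" else "minimum",
         value = intercept + b1 * loc + b2 * loc^2,
         predictor = predictor),
    class = "fs_extremum"
  )
}

#' @export
print.fs_extremum <- function(x, ...) {
  cat(sprintf("<fs_extremum> %s at %s = %.4g (value %.4g)\n", x$kind,
              if (is.na(x$predictor)) "x" else x$predictor, x$location,
              x$value))
  invisible(x)
}

#' Annual shift rate between two extremum locations
#'
#' Absolute rate `(later - earlier) / years` (units of the predictor per
#' year) and relative rate `100 * absolute / earlier` (% per year). By
#' default locations are first rounded to one decimal — the reporting
#' precision at which peak locations are quoted — so that published rates
#' reproduce exactly; set `round_digits = NULL` for unrounded rates.
#'
#' @param earlier,later `fs_extremum` objects or bare locations.
#' @param years Length of the interval in years (> 0).
#' @param round_digits Decimal places for the input locations (default 1),
#'   or `NULL` to skip rounding.
#' @return List: `earlier`, `later`, `years`, `absolute_rate`,
#'   `relative_rate`.
#' @examples
#' peak_shift(7.3, 8.7, 14)$relative_rate  # about 1.37 %/yr
#' @export
peak_shift <- function(earlier, later, years, round_digits = 1) {
  loc <- function(x, other) {
    if (inherits(x, "fs_extremum")) {
      if (inherits(other, "fs_extremum")) {
        if (!identical(x$predictor, other$predictor)) {
          stop("extrema are on different predictors", call. = FALSE)
        }
        if (!identical(x$kind, other$kind)) {
          stop("cannot compare a maximum with a minimum", call. = FALSE)
        }
      }
      x$location
    } else {
      as.numeric(x)
    }
  }
  if (years <= 0) stop("years must be positive", call. = FALSE)
  l1 <- loc(earlier, later)
  l2 <- loc(later, earlier)
  if (!is.null(round_digits)) {
    l1 <- round(l1, round_digits)
    l2 <- round(l2, round_digits)
  }
  if (l1 == 0) stop("earlier location is zero; relative rate undefined",
                    call. = FALSE)
  abs_rate <- (l2 - l1) / years
  list(earlier = l1, later = l2, years = years,
       absolute_rate = abs_rate,
       relative_rate = 100 * abs_rate / l1)
}

#' Predicted response curve along one predictor
#'
#' Evaluates the trend part `X beta` of a spatial-error fit along a grid of
#' predictor values, holding every other term at its sample mean (stored in
#' the fit). A squared companion term named `<predictor>_sq` moves with the
#' predictor.
#'
#' @param fit An `fs_sem`.
#' @param predictor Name of the term to vary (must be in the fit).
#' @param values Numeric grid of predictor values.
#' @return Tibble with `value` (the predictor) and `response`.
#' @export
predicted_curve <- function(fit, predictor, values) {
  terms <- fit$terms
  if (!predictor %in% terms) {
    stop("predictor '", predictor, "' is not a term of the fit", call. = FALSE)
  }
  beta <- coef(fit)
  sq <- paste0(predictor, "_sq")
  X <- matrix(rep(fit$x_means, each = length(values)), nrow = length(values),
              dimnames = list(NULL, terms))
  X[, predictor] <- values
  if (sq %in% terms) X[, sq] <- values^2
  tibble(value = values, response = as.numeric(X %*% beta))
}

#' Extrema of the quadratic terms of a set of fits
#'
#' For each fit and each predictor with both a first- and second-order term
#' retained (`<p>` and `<p>_sq`), reports the extremum; predictors lacking
#' either order are skipped. A pure-quadratic response (no first-order
#' term) has its extremum at 0.
#'
#' @param fits Named list of `fs_sem` fits, or a single fit.
#' @param predictors Candidate predictor names (default `D`, `s`,
#'   `sigma_s`).
#' @param require_linear Skip predictors whose first-order term is absent?
#'   Default `FALSE` (the extremum is then at 0).
#' @return Tibble: `model`, `predictor`, `location`, `kind`, `value`.
#' @export
slope_extrema_report <- function(fits, predictors = c("D", "s", "sigma_s"),
                                 require_linear = FALSE) {
  if (inherits(fits, "fs_sem")) fits <- list(fit = fits)
  rows <- list()
  for (nm in names(fits)) {
    beta <- coef(fits[[nm]])
    for (p in predictors) {
      sq <- paste0(p, "_sq")
      if (!sq %in% names(beta)) next
      b1 <- if (p %in% names(beta)) beta[[p]] else {
        if (require_linear) next else 0
      }
      ex <- quadratic_extremum(b1, beta[[sq]], predictor = p)
      rows[[length(rows) + 1]] <- tibble(
        model = nm, predictor = p, location = ex$location, kind = ex$kind,
        value = ex$value)
    }
  }
  if (length(rows) == 0) {
    return(tibble(model = character(0), predictor = character(0),
                  location = numeric(0), kind = character(0),
                  value = numeric(0)))
  }
  do.call(rbind, rows)
}
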