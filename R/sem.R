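# Maximum-likelihood spatial error model (SEM):
#
#   y = X beta + eps,   eps = lambda W eps + xi,   xi ~ N(0, sigma2 I)
#
# estimated by profiling the likelihood in lambda. Writing
# A(lambda) = I - lambda W, the transformed model A y = A X beta + xi is
# homoskedastic, so for fixed lambda the GLS estimates are OLS on the
# transformed data and the concentrated log-likelihood is
#
#   l(lambda) = const - n/2 log(RSS(lambda)/n) + log|A(lambda)|
#
# with log|A| = sum_i log(1 - lambda w_i) over the eigenvalues w_i of W
# (complex pairs contribute their real-log sum). lambda is searched on the
# stationary interval (1/min Re(w), 1/max Re(w)).

#' k-nearest-neighbour spatial weights
#'
#' Each observation is linked to its `k` nearest neighbours by Euclidean
#' distance between centroids; ties are broken deterministically by lowest
#' index. Rows are standardized to sum to 1 by default, the usual
#' convention for kNN spatial-error fits.
#'
#' @param coords Two-column matrix (or data frame) of point coordinates.
#' @param k Number of neighbours (default 8).
#' @param standardize Row-standardize the weights? Default `TRUE`.
#' @return An `fs_weights` object: sparse `W` (dgCMatrix), `k`,
#'   `standardized`, and the eigenvalues of `W` (used by the likelihood).
#' @export
knn_weights <- function(coords, k = 8, standardize = TRUE) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n <= k) stop("need more than k = ", k, " observations", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  idx <- integer(0)
  jdx <- integer(0)
  for (i in seq_len(n)) {
    # order() is stable: equidistant neighbours resolve to the lowest index
    nb <- order(d[i, ])[seq_len(k)]
    idx <- c(idx, rep.int(i, k))
    jdx <- c(jdx, nb)
  }
  w <- if (standardize) rep(1 / k, length(idx)) else rep(1, length(idx))
  W <- Matrix::sparseMatrix(i = idx, j = jdx, x = w, dims = c(n, n))
  ev <- eigen(as.matrix(W), only.values = TRUE)$values
  structure(list(W = W, k = k, standardized = standardize, eigenvalues = ev,
                 n = n),
            class = "fs_weights")
}

#' @export
print.fs_weights <- function(x, ...) {
  cat(sprintf("<fs_weights> n = %d, k = %d, %s\n", x$n, x$k,
              if (x$standardized) "row-standardized" else "binary"))
  invisible(x)
}

lambda_interval <- function(weights, eps = 1e-4) {
  er <- Re(weights$eigenvalues)
  lo <- if (min(er) < 0) 1 / min(er) else -1 + eps
  hi <- if (max(er) > 0) 1 / max(er) else 1 - eps
  c(lo + eps, hi - eps)
}

stars_for <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Fit a spatial error model by maximum likelihood
#'
#' @param y Response vector, no missing values.
#' @param X Design matrix (include the intercept column explicitly, e.g.
#'   via [build_design()]); must be full column rank.
#' @param weights An `fs_weights` object with `n == length(y)`.
#' @param tol Optimizer tolerance on lambda (default 1e-8).
#' @return An `fs_sem` fit: `coefficients` tibble (term, estimate, se, z,
#'   p, stars), `lambda`, `lambda_se`, `sigma2`, `logLik`, `AIC` (free
#'   parameters = ncol(X) + 2 for lambda and sigma2), `n`, `converged`,
#'   plus the column means of `X` (used by [predicted_curve()]).
#' @export
fit_sem <- function(y, X, weights, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n, inherits(weights, "fs_weights"))
  if (weights$n != n) stop("weights built for n = ", weights$n,
                           ", data has n = ", n, call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  if (n <= ncol(X)) stop("need n > number of columns of X", call. = FALSE)

  W <- weights$W
  ev <- weights$eigenvalues
  Wy <- as.numeric(W %*% y)
  WX <- as.matrix(W %*% X)

  gls_at <- function(lambda) {
    ys <- y - lambda * Wy
    Xs <- X - lambda * WX
    fit <- stats::lm.fit(Xs, ys)
    rss <- sum(fit$residuals^2)
    list(beta = fit$coefficients, rss = rss, Xs = Xs)
  }
  logdet <- function(lambda) sum(Re(log(1 - lambda * ev)))
  profile_ll <- function(lambda) {
    g <- gls_at(lambda)
    -n / 2 * (log(2 * pi) + 1) - n / 2 * log(g$rss / n) + logdet(lambda)
  }

  # degenerate exact fit (e.g. constant response on an intercept)
  g0 <- gls_at(0)
  if (g0$rss < 1e-10 * max(1, sum(y^2))) {
    coefs <- tibble(term = colnames(X), estimate = unname(g0$beta),
                    se = NA_real_, z = NA_real_, p = NA_real_, stars = "")
    return(structure(list(coefficients = coefs, lambda = 0, lambda_se = NA_real_,
                          sigma2 = 0, logLik = Inf, AIC = -Inf, n = n,
                          converged = TRUE, degenerate = TRUE,
                          x_means = colMeans(X), terms = colnames(X)),
                     class = "fs_sem"))
  }

  interval <- lambda_interval(weights)
  opt <- stats::optimize(profile_ll, interval = interval, maximum = TRUE,
                         tol = tol)
  lambda <- opt$maximum
  ll <- opt$objective
  # non-convergence guard: the optimum must beat both interval endpoints
  near_edge <- min(lambda - interval[1], interval[2] - lambda) <
    1e-3 * diff(interval)
  g <- gls_at(lambda)
  sigma2 <- g$rss / n
  vcov_beta <- sigma2 * solve(crossprod(g$Xs))
  se <- sqrt(diag(vcov_beta))
  z <- g$beta / se
  p <- 2 * pnorm(-abs(z))

  # lambda SE from the curvature of the profile likelihood
  h <- 1e-4 * diff(interval)
  l2 <- (profile_ll(min(lambda + h, interval[2])) - 2 * ll +
           profile_ll(max(lambda - h, interval[1]))) / h^2
  lambda_se <- if (is.finite(l2) && l2 < 0) sqrt(-1 / l2) else NA_real_

  coefs <- tibble(term = colnames(X), estimate = unname(g$beta),
                  se = unname(se), z = unname(z), p = unname(p),
                  stars = stars_for(unname(p)))
  k_free <- ncol(X) + 2
  structure(list(coefficients = coefs, lambda = lambda, lambda_se = lambda_se,
                 sigma2 = sigma2, logLik = ll, AIC = 2 * k_free - 2 * ll,
                 n = n, converged = !near_edge, degenerate = FALSE,
                 x_means = colMeans(X), terms = colnames(X)),
            class = "fs_sem")
}

#' @export
print.fs_sem <- function(x, ...) {
  cat(sprintf("<fs_sem> n = %d, lambda = %.4f, logLik = %.3f, AIC = %.2f\n",
              x$n, x$lambda, x$logLik, x$AIC))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
logLik.fs_sem <- function(object, ...) {
  structure(object$logLik, df = length(object$terms) + 2, class = "logLik")
}

#' @export
coef.fs_sem <- function(object, ...) {
  structure(object$coefficients$estimate, names = object$coefficients$term)
}

#' Intercept-only spatial error fit of an increment
#'
#' Fits `dy = mu + eps` with spatially correlated error, testing whether an
#' index changed on average over the landscape. The sign of a significant
#' intercept is read as fragmentation or aggregation depending on the
#' index.
#'
#' @param dy Increment vector (later year minus earlier year, per cell).
#' @param weights An `fs_weights`.
#' @return An `fs_sem` with the single term `intercept`.
#' @export
fit_intercept_only <- function(dy, weights) {
  X <- matrix(1, length(dy), 1, dimnames = list(NULL, "intercept"))
  fit_sem(dy, X, weights)
}

#' Build a design matrix from a data frame of candidate terms
#'
#' @param data Data frame holding the candidate columns.
#' @param terms Character vector of column names (may be empty).
#' @param intercept Include an intercept column?
#' @return Numeric matrix with named columns.
#' @export
build_design <- function(data, terms, intercept = TRUE) {
  cols <- lapply(terms, function(t) {
    if (!t %in% names(data)) stop("no column '", t, "' in data", call. = FALSE)
    as.numeric(data[[t]])
  })
  X <- do.call(cbind, c(list(if (intercept) rep(1, nrow(data)) else NULL), cols))
  colnames(X) <- c(if (intercept) "intercept", terms)
  X
}

#' AIC-guided exhaustive term selection for a spatial error model
#'
#' Fits every subset of the candidate terms and returns the minimum-AIC
#' fit. With `intercept = "search"` the intercept itself is a searched
#' term (some responses are best fit with no intercept).
#'
#' @param y Response vector.
#' @param data Data frame with the candidate columns.
#' @param candidates Character vector of candidate term names (at most 12).
#' @param weights An `fs_weights`.
#' @param intercept `TRUE`, `FALSE`, or `"search"`.
#' @return The best `fs_sem`, with `chosen_terms` and `with_intercept`
#'   fields added.
#' @export
aic_select <- function(y, data, candidates, weights, intercept = TRUE) {
  if (length(candidates) > 12) stop("at most 12 candidate terms", call. = FALSE)
  int_options <- if (identical(intercept, "search")) c(TRUE, FALSE) else isTRUE(intercept)
  best <- NULL
  subsets <- unlist(lapply(0:length(candidates), function(m) {
    if (m == 0) list(character(0)) else
      apply(combn(candidates, m), 2, identity, simplify = FALSE)
  }), recursive = FALSE)
  for (use_int in int_options) {
    for (terms in subsets) {
      if (!use_int && length(terms) == 0) next
      X <- build_design(data, terms, intercept = use_int)
      fit <- tryCatch(fit_sem(y, X, weights), error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$AIC < best$AIC) {
        best <- fit
        best$chosen_terms <- terms
        best$with_intercept <- use_int
      }
    }
  }
  if (is.null(best)) stop("every candidate subset failed to fit", call. = FALSE)
  best
}

#' Spatial-error regressions of index increments on land-cover increments
#'
#' For each response increment (urban EDGE_AREA and ED, forest ED and
#' AREA_MN, wetland EDGE_AREA between the first and last summarized years),
#' regresses the per-cell index change on the pixel-count increments of the
#' land-cover classes (and mean distance to urban), with AIC term
#' selection. Cells with undefined indices in either year are dropped per
#' response, and the kNN weights are rebuilt on the retained centroids.
#'
#' @param cells Cell table from [summarize_cells()] (with `centroid_x`,
#'   `centroid_y`, `dN_*` columns and metric columns for two years).
#' @param t1,t2 Year labels (character) of the earlier/later metric columns;
#'   defaults to the first and last years found in the column names.
#' @param k Neighbours for the rebuilt weights (default 8).
#' @param responses Named list mapping response label to
#'   `c(index, class name)`; the default is the five studied increments.
#' @param candidates Candidate regressors (default the six class increments
#'   plus mean distance to urban where present).
#' @param intercept Passed to [aic_select()] (default `"search"`).
#' @return Named list of `fs_sem` fits (with `chosen_terms`), one per
#'   response that had enough complete cells; responses skipped for lack of
#'   data are reported with a message.
#' @export
fit_increment_models <- function(cells, t1 = NULL, t2 = NULL, k = 8,
                                 responses = list(
                                   dEDGE_AREA_URBAN = c("EDGE_AREA", "URBAN"),
                                   dED_URBAN = c("ED", "URBAN"),
                                   dED_FOREST = c("ED", "FOREST"),
                                   dAREA_MN_FOREST = c("AREA_MN", "FOREST"),
                                   dEDGE_AREA_WETLAND = c("EDGE_AREA", "WETLAND")),
                                 candidates = NULL, intercept = "search") {
  metric_cols <- grep("^(AREA_MN|LPI|ED|EDGE_AREA)_", names(cells), value = TRUE)
  years <- sort(unique(sub(".*_", "", metric_cols)))
  if (is.null(t1)) t1 <- years[1]
  if (is.null(t2)) t2 <- years[length(years)]
  if (identical(t1, t2)) stop("need two distinct years of metrics", call. = FALSE)
  if (is.null(candidates)) {
    candidates <- grep("^dN_", names(cells), value = TRUE)
    if ("dist_urban_mean" %in% names(cells)) {
      candidates <- c(candidates, "dist_urban_mean")
    }
  }
  fits <- list()
  for (resp in names(responses)) {
    idx <- responses[[resp]][1]
    cls <- responses[[resp]][2]
    c1 <- paste(idx, cls, t1, sep = "_")
    c2 <- paste(idx, cls, t2, sep = "_")
    if (!all(c(c1, c2) %in% names(cells))) next
    dy <- cells[[c2]] - cells[[c1]]
    keep <- !is.na(dy) & complete.cases(cells[, candidates, drop = FALSE])
    n_keep <- sum(keep)
    if (n_keep <= length(candidates) + 3 || n_keep <= k) {
      message("skipping ", resp, ": only ", n_keep, " complete cells")
      next
    }
    w <- knn_weights(cells[keep, c("centroid_x", "centroid_y")], k = k)
    fit <- aic_select(dy[keep], cells[keep, ], candidates, w,
                      intercept = intercept)
    fit$response <- resp
    fits[[resp]] <- fit
  }
  fits
}

#' Flat report table from a set of SEM fits
#'
#' @param fits Named list of `fs_sem` objects.
#' @return Tibble with `model`, `term`, `estimate`, `se`, `z`, `p`,
#'   `stars`, `lambda`, `AIC`, `n`.
#' @export
sem_report <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    cbind(tibble(model = nm), f$coefficients,
          tibble(lambda = f$lambda, AIC = f$AIC, n = f$n))
  }))
}
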