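# kNN spatial weights and the maximum-likelihood spatial error model.

test_that("kNN weights recover lattice neighbourhoods and standardize rows", {
  xy <- expand.grid(x = 1:5, y = 1:5)
  w <- knn_weights(xy, k = 8)
  W <- as.matrix(w$W)
  center <- which(xy$x == 3 & xy$y == 3)
  nbrs <- which(W[center, ] > 0)
  expect_setequal(nbrs, which(abs(xy$x - 3) <= 1 & abs(xy$y - 3) <= 1 &
                                seq_len(25) != center))
  expect_equal(Matrix::rowSums(w$W), rep(1, 25), ignore_attr = TRUE)
  expect_true(all(Matrix::diag(w$W) == 0))

  wb <- knn_weights(xy, k = 4, standardize = FALSE)
  expect_equal(Matrix::rowSums(wb$W), rep(4, 25), ignore_attr = TRUE)
})

test_that("kNN weights match a brute-force sorted-distance oracle", {
  set.seed(31)
  pts <- cbind(runif(40), runif(40))
  w <- knn_weights(pts, k = 3, standardize = FALSE)
  W <- as.matrix(w$W)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  for (i in 1:40) {
    expect_setequal(which(W[i, ] > 0), order(d[i, ])[1:3])
  }
})

test_that("equidistant neighbours break ties toward the lowest index", {
  # four corners equidistant from the centre point (index 5)
  pts <- rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2), c(1, 1))
  w <- knn_weights(pts, k = 2, standardize = FALSE)
  expect_equal(which(as.matrix(w$W)[5, ] > 0), c(1L, 2L))
})

test_that("with lambda = 0 data the SEM reduces to ordinary least squares", {
  d <- generate_sem_data(sem_recipe(n = 100, beta = c(1, 2), lambda = 0,
                                    sigma = 1, seed = 3))
  f <- fit_sem(d$y, d$X, d$weights)
  ols <- lm(d$y ~ d$X[, 2])
  expect_equal(unname(coef(f)), unname(coef(ols)), tolerance = 0.02)
  expect_lt(abs(f$lambda), 0.35)  # no true spatial signal at this n
})

test_that("profile log-likelihood at the optimum beats lambda = 0 and a grid scan", {
  d <- generate_sem_data(sem_recipe(n = 64, beta = c(0.5, 1.5), lambda = 0.4,
                                    sigma = 1, seed = 9))
  f <- fit_sem(d$y, d$X, d$weights)
  # independent concentrated-likelihood evaluation on a fine grid
  ev <- d$weights$eigenvalues
  W <- d$weights$W
  conc <- function(lam) {
    ys <- d$y - lam * as.numeric(W %*% d$y)
    Xs <- d$X - lam * as.matrix(W %*% d$X)
    rss <- sum(lm.fit(Xs, ys)$residuals^2)
    -length(d$y) / 2 * (log(2 * pi) + 1) -
      length(d$y) / 2 * log(rss / length(d$y)) +
      sum(Re(log(1 - lam * ev)))
  }
  grid <- seq(-0.95, 0.99, by = 0.001)
  vals <- vapply(grid, conc, numeric(1))
  expect_gte(f$logLik, conc(0))
  expect_equal(f$lambda, grid[which.max(vals)], tolerance = 2e-3)
  expect_equal(f$logLik, max(vals), tolerance = 1e-6)
})

test_that("parameters are recovered from data simulated at n = 400", {
  d <- generate_sem_data(sem_recipe(n = 400, beta = c(1, 2), lambda = 0.5,
                                    sigma = 1, seed = 11))
  f <- fit_sem(d$y, d$X, d$weights)
  est <- f$coefficients
  expect_lt(abs(est$estimate[1] - 1), 3 * est$se[1])
  expect_lt(abs(est$estimate[2] - 2), 3 * est$se[2])
  expect_lt(abs(f$lambda - 0.5), 0.1)
  expect_equal(f$AIC, 2 * (2 + 2) - 2 * f$logLik)
})

test_that("degenerate and invalid designs are handled explicitly", {
  xy <- cbind(runif(30), runif(30))
  set.seed(2)
  w <- knn_weights(xy, k = 4)
  # constant response on an intercept: exact fit, zero variance
  f <- fit_intercept_only(rep(3.5, 30), w)
  expect_equal(coef(f)[["intercept"]], 3.5)
  expect_equal(f$sigma2, 0)
  expect_true(f$degenerate)
  # rank-deficient design
  X <- cbind(intercept = rep(1, 30), a = 1:30, b = 2 * (1:30))
  expect_error(fit_sem(rnorm(30), X, w), "rank")
  # missing values
  y <- rnorm(30)
  y[4] <- NA
  expect_error(fit_sem(y, cbind(rep(1, 30)), w), "missing")
  # size mismatch
  expect_error(fit_sem(rnorm(29), cbind(rep(1, 29)), w), "n = ")
})

test_that("intercept-only fit recovers a known mean increment", {
  base <- generate_sem_data(sem_recipe(n = 225, beta = 0, lambda = 0.4,
                                       sigma = 1, seed = 21))
  dy <- 3.8 + base$y  # zero-beta SEM noise around 3.8
  f <- fit_intercept_only(dy, base$weights)
  expect_equal(coef(f)[["intercept"]], 3.8, tolerance = 0.5)
  expect_lt(f$coefficients$p[1], 0.01)
  expect_equal(f$coefficients$stars[1], "**")
})

test_that("AIC selection recovers a quadratic signal and drops noise terms", {
  n <- 225
  xy <- expand.grid(x = 1:15, y = 1:15)
  w <- knn_weights(xy, k = 8)
  kept_signal <- 0
  dropped_noise <- 0
  for (s in 1:5) {
    set.seed(550 + s)
    dat <- tibble::tibble(D = runif(n, 0, 10))
    dat$D_sq <- dat$D^2
    dat$noise1 <- rnorm(n)
    dat$noise2 <- rnorm(n)
    y <- 5 + 4 * dat$D - 0.4 * dat$D_sq + rnorm(n, sd = 0.8)
    best <- aic_select(y, dat, c("D", "D_sq", "noise1", "noise2"), w)
    kept_signal <- kept_signal +
      all(c("D", "D_sq") %in% best$chosen_terms)
    dropped_noise <- dropped_noise +
      !any(c("noise1", "noise2") %in% best$chosen_terms)
    expect_equal(best$AIC, 2 * (length(best$terms) + 2) - 2 * best$logLik)
  }
  expect_equal(kept_signal, 5)       # the true terms always survive
  expect_gte(dropped_noise, 3)       # pure noise excluded in most seeds

  # single candidate with a monotone signal: degenerate choice keeps it
  set.seed(555)
  dat <- tibble::tibble(D = runif(n, 0, 10))
  y2 <- 2 * dat$D + rnorm(n, sd = 0.5)
  one <- aic_select(y2, dat, "D", w)
  expect_equal(one$chosen_terms, "D")
  # intercept search reports its decision
  b2 <- aic_select(y2, dat, "D", w, intercept = "search")
  expect_true(is.logical(b2$with_intercept))
})

test_that("increment models recover a known coefficient on synthetic cells", {
  set.seed(66)
  n <- 144
  xy <- expand.grid(x = 1:12, y = 1:12)
  cells <- tibble::tibble(
    cell_id = 1:n,
    centroid_x = xy$x * 3000, centroid_y = xy$y * 3000,
    dN_URBAN = round(rnorm(n, 0, 300)),
    dN_FOREST = round(rnorm(n, 0, 400)),
    dN_PASTURE = round(rnorm(n, 0, 300))
  )
  cells$ED_FOREST_1991 <- 30 + rnorm(n, sd = 0.5)
  cells$ED_FOREST_2000 <- cells$ED_FOREST_1991 + 0.01 * cells$dN_URBAN +
    rnorm(n, sd = 0.3)
  fits <- fit_increment_models(cells, t1 = "1991", t2 = "2000", k = 8,
                               responses = list(dED_FOREST = c("ED", "FOREST")))
  f <- fits$dED_FOREST
  expect_true("dN_URBAN" %in% f$chosen_terms)
  expect_equal(coef(f)[["dN_URBAN"]], 0.01, tolerance = 0.003)

  # zero increments: response is exactly zero, coefficients degenerate to 0
  cells0 <- cells
  cells0$ED_FOREST_2000 <- cells0$ED_FOREST_1991
  fits0 <- fit_increment_models(cells0, t1 = "1991", t2 = "2000", k = 8,
                                responses = list(dED_FOREST = c("ED", "FOREST")))
  expect_true(all(abs(coef(fits0$dED_FOREST)) < 1e-8))
})
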