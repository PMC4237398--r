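# Synthetic-data generators: determinism, proportion control, clumpiness
# behaviour, change-pair structure, covariates, and the SEM data draw.

test_that("every generator is a pure, seeded function of its recipe", {
  r <- landscape_recipe(rows = 60, cols = 60, seed = 4)
  g1 <- generate_landscape(r)
  g2 <- generate_landscape(r)
  expect_identical(g1$values, g2$values)
  g3 <- generate_landscape(landscape_recipe(rows = 60, cols = 60, seed = 5))
  expect_false(identical(g1$values, g3$values))

  cp1 <- generate_change_pair(g1, change_recipe(seed = 8))
  cp2 <- generate_change_pair(g1, change_recipe(seed = 8))
  expect_identical(cp1$grid_t2$values, cp2$grid_t2$values)

  cov1 <- generate_covariates(g1, seed = 2)
  cov2 <- generate_covariates(g1, seed = 2)
  expect_identical(cov1$elevation$values, cov2$elevation$values)

  d1 <- generate_sem_data(sem_recipe(n = 49, seed = 13))
  d2 <- generate_sem_data(sem_recipe(n = 49, seed = 13))
  expect_identical(d1$y, d2$y)

  # the caller's RNG stream is untouched
  set.seed(1000)
  before <- runif(1)
  set.seed(1000)
  invisible(generate_landscape(r))
  expect_identical(runif(1), before)
})

test_that("realized class proportions stay within 2 points of the recipe", {
  for (s in 1:3) {
    g <- generate_landscape(landscape_recipe(rows = 200, cols = 200, seed = s))
    tab <- table(factor(g$values[land_mask(g)], levels = LC_CLASSES))
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(LC_CLASSES)
    urban_total <- p[["URBAN"]] + p[["HIGH_DENSITY_URBAN"]]
    expect_lt(abs(urban_total - 0.12), 0.02)
    expect_lt(abs(p[["FOREST"]] - 0.40), 0.02)
    expect_lt(abs(p[["PASTURE"]] - 0.30), 0.02)
    expect_lt(abs(p[["WETLAND"]] - 0.04), 0.02)
  }
})

test_that("clumpiness 0 reduces to a per-pixel multinomial draw", {
  r <- landscape_recipe(rows = 120, cols = 120, clumpiness = 0,
                        n_urban_centers = 0, seed = 17)
  g <- generate_landscape(r)
  m <- class_metrics(label_patches(g, LC_CLASSES[["FOREST"]]))
  # independent multinomial oracle with the same proportions
  set.seed(900)
  oracle_vals <- matrix(sample(c(3L, 7L), 120 * 120, replace = TRUE,
                               prob = c(0.40, 0.60)), 120, 120)
  og <- lc_grid(oracle_vals, vocabulary = c(3L, 7L))
  om <- class_metrics(label_patches(og, 3L))
  # patch structure matches the independence oracle (8-connected clusters
  # of a 40% Bernoulli field, not the large patches a clustered draw gives)
  expect_lt(m$AREA_MN, 3 * om$AREA_MN)
  expect_gt(m$AREA_MN, om$AREA_MN / 3)
  expect_lt(m$ED, 1.5 * om$ED)
  expect_gt(m$ED, om$ED / 1.5)
})

test_that("higher clumpiness gives larger mean patches and less edge", {
  a01 <- numeric(10)
  a09 <- numeric(10)
  e01 <- numeric(10)
  e09 <- numeric(10)
  for (s in 1:10) {
    g1 <- generate_landscape(landscape_recipe(150, 150, clumpiness = 0.1,
                                              seed = s))
    g9 <- generate_landscape(landscape_recipe(150, 150, clumpiness = 0.9,
                                              seed = s))
    m1 <- class_metrics(label_patches(g1, LC_CLASSES[["FOREST"]]))
    m9 <- class_metrics(label_patches(g9, LC_CLASSES[["FOREST"]]))
    a01[s] <- m1$AREA_MN
    a09[s] <- m9$AREA_MN
    e01[s] <- m1$ED
    e09[s] <- m9$ED
  }
  expect_gte(sum(a09 > a01), 9)
  expect_gte(sum(e09 < e01), 9)
})

test_that("change pairs embed their own truth and honour the null recipe", {
  g <- generate_landscape(landscape_recipe(rows = 120, cols = 120, seed = 3))
  null_cp <- generate_change_pair(g, change_recipe(
    edge_reforestation_fraction = 0, interior_deforestation_fraction = 0,
    urban_growth_fraction = 0, seed = 1))
  expect_identical(null_cp$grid_t1$values, null_cp$grid_t2$values)

  cp <- generate_change_pair(g, change_recipe(seed = 2))
  redo <- classify_forest_change(cp$grid_t1, cp$grid_t2)
  expect_identical(redo$categories, cp$truth$categories)
})

test_that("reforestation hugs edges and deforestation sits in interiors", {
  wins <- 0
  for (s in 1:10) {
    g <- generate_landscape(landscape_recipe(rows = 150, cols = 150,
                                             seed = s))
    cp <- generate_change_pair(g, change_recipe(seed = s + 50))
    dr <- mean_distance_to_unchanged(cp$truth, "REFORESTED")
    dd <- mean_distance_to_unchanged(cp$truth, "DEFORESTED")
    wins <- wins + (dr > dd)
  }
  expect_gte(wins, 9)
})

test_that("reforested pixels obey the dilation rule, deforested the core rule", {
  g <- generate_landscape(landscape_recipe(rows = 150, cols = 150, seed = 6))
  cp <- generate_change_pair(g, change_recipe(urban_growth_fraction = 0,
                                              seed = 7))
  f1 <- class_mask(cp$grid_t1, LC_CLASSES[["FOREST"]])
  f2 <- class_mask(cp$grid_t2, LC_CLASSES[["FOREST"]])
  ref <- !f1 & f2
  # reforestation starts adjacent to first-year forest and extends outward
  d_to_f1 <- sqrt(fragscape:::edt_sq_cpp(f1))
  touching <- d_to_f1[ref] <= sqrt(2) + 1e-9
  expect_gt(mean(touching), 0.2)  # seeds are adjacent; growth extends out
  # deforested pixels lie inside first-year forest
  def <- f1 & !f2
  expect_true(all(f1[def]))
})

test_that("covariate surfaces have the stated structure", {
  g <- generate_landscape(landscape_recipe(rows = 100, cols = 100, seed = 12))
  cov <- generate_covariates(g, seed = 5)
  expect_true(all(cov$slope$values >= 0 & cov$slope$values <= 45))
  expect_true(all(cov$pop_density$values > 0))
  # density decreases with distance from urban on average
  rho <- cor(as.numeric(cov$dist_urban$values),
             as.numeric(cov$pop_density$values), method = "spearman")
  expect_lt(rho, -0.3)
  # all-urban landscape: distance surface identically zero
  gu <- lc_grid(matrix(1L, 10, 10), vocabulary = 1L)
  expect_true(all(distance_to_urban_surface(gu)$values == 0))
})

test_that("SEM data generator matches its own model", {
  # lambda = 0: residual spatial correlation near zero
  d0 <- generate_sem_data(sem_recipe(n = 400, beta = c(1, 2), lambda = 0,
                                     sigma = 1, seed = 31))
  eps0 <- d0$y - as.numeric(d0$X %*% c(1, 2))
  moran <- function(e, W) sum(e * as.numeric(W %*% e)) / sum(e^2)
  expect_lt(abs(moran(eps0, d0$weights$W)), 0.12)

  # Moran-style statistic increases with lambda
  w <- generate_sem_data(sem_recipe(n = 225, seed = 1))$weights
  mean_moran <- function(lam) {
    mean(vapply(1:20, function(s) {
      d <- generate_sem_data(sem_recipe(n = 225, beta = 0, lambda = lam,
                                        sigma = 1, seed = 1000 + s),
                             weights = w)
      moran(d$y, w$W)
    }, numeric(1)))
  }
  m0 <- mean_moran(0)
  m3 <- mean_moran(0.3)
  m6 <- mean_moran(0.6)
  expect_lt(m0, m3)
  expect_lt(m3, m6)

  # lambda outside the stationary interval is refused
  expect_error(generate_sem_data(sem_recipe(n = 49, lambda = 1.2, seed = 2)),
               "stationary")
})
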