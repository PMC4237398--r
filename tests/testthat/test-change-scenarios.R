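# Forest change classification, counterfactual scenarios, urban masking,
# and change-site distance statistics.

test_that("change classification covers the trivial and toy cases", {
  g <- grid_from_string("FF./FF./...")
  same <- classify_forest_change(g, g)
  expect_equal(sum(same$categories == CHANGE_CODES[["DEFORESTED"]]), 0)
  expect_equal(sum(same$categories == CHANGE_CODES[["REFORESTED"]]), 0)
  expect_equal(sum(same$categories == CHANGE_CODES[["UNCHANGED_FOREST"]]), 4)

  all_f <- lc_grid(matrix(3L, 3, 3), vocabulary = c(3L, 7L))
  none <- lc_grid(matrix(7L, 3, 3), vocabulary = c(3L, 7L))
  ch <- classify_forest_change(all_f, none)
  expect_true(all(ch$categories == CHANGE_CODES[["DEFORESTED"]]))

  t1 <- grid_from_string("FF./FF./...")
  t2 <- grid_from_string("FF./F../..F")
  ch2 <- classify_forest_change(t1, t2)
  expect_equal(sum(ch2$categories == CHANGE_CODES[["DEFORESTED"]]), 1)
  expect_equal(sum(ch2$categories == CHANGE_CODES[["REFORESTED"]]), 1)
  expect_equal(sum(ch2$categories == CHANGE_CODES[["UNCHANGED_FOREST"]]), 3)
})

test_that("change partition invariants hold on random pairs", {
  set.seed(88)
  for (i in 1:5) {
    a <- random_grid(15, 15, codes = c(3L, 5L, 7L))
    b <- random_grid(15, 15, codes = c(3L, 5L, 7L))
    ch <- classify_forest_change(a, b)
    f1 <- a$values == 3L
    f2 <- b$values == 3L
    un <- ch$categories == CHANGE_CODES[["UNCHANGED_FOREST"]]
    de <- ch$categories == CHANGE_CODES[["DEFORESTED"]]
    re <- ch$categories == CHANGE_CODES[["REFORESTED"]]
    expect_identical(un | de, f1)
    expect_identical(un | re, f2)
    expect_equal(sum(un & de) + sum(un & re) + sum(de & re), 0)
  }
})

test_that("misaligned grids are rejected", {
  a <- lc_grid(matrix(3L, 3, 3), vocabulary = 3L)
  b <- lc_grid(matrix(3L, 3, 3), origin = c(30, 0), vocabulary = 3L)
  expect_error(classify_forest_change(a, b), "aligned")
})

test_that("scenario forest masks follow the set arithmetic", {
  t1 <- grid_from_string("FFF../FF.../...../..F..")
  t2 <- grid_from_string("FF.../FF.../....F/..F..")
  ch <- classify_forest_change(t1, t2)
  n_ff <- sum(ch$categories == CHANGE_CODES[["UNCHANGED_FOREST"]])
  n_de <- sum(ch$categories == CHANGE_CODES[["DEFORESTED"]])
  n_re <- sum(ch$categories == CHANGE_CODES[["REFORESTED"]])

  def_only <- build_scenario(ch, "DEFORESTATION_ONLY")
  ref_only <- build_scenario(ch, "REFORESTATION_ONLY")
  s1 <- build_scenario(ch, "TRUE_T1")
  s2 <- build_scenario(ch, "TRUE_T2")

  f <- function(g) g$values == LC_CLASSES[["FOREST"]]
  expect_equal(sum(f(def_only)), n_ff)
  expect_equal(sum(f(ref_only)), n_ff + n_de + n_re)
  expect_identical(f(s1), t1$values == 3L)
  expect_identical(f(s2), t2$values == 3L)
  # containment chain: reforestation-only >= both true years >= def-only
  expect_true(all(f(s1) <= f(ref_only)))
  expect_true(all(f(s2) <= f(ref_only)))
  expect_true(all(f(def_only) <= f(s1)))
  expect_true(all(f(def_only) <= f(s2)))

  # zero change: all four scenarios coincide
  ch0 <- classify_forest_change(t1, t1)
  masks <- lapply(c("TRUE_T1", "TRUE_T2", "DEFORESTATION_ONLY",
                    "REFORESTATION_ONLY"),
                  function(w) build_scenario(ch0, w)$values == 3L)
  for (m in masks[-1]) expect_identical(m, masks[[1]])
})

test_that("urban-union mask removes pixels from the landscape", {
  g <- grid_from_string("FFU/FUP/PPW")
  u1 <- g$values == 1L
  u2 <- matrix(FALSE, 3, 3)
  u2[1, 1] <- TRUE
  masked <- apply_urban_mask(g, u1, u2)
  expect_equal(landscape_area(masked), (9 - 3) * 900)
  # empty masks leave metrics unchanged
  m0 <- apply_urban_mask(g, matrix(FALSE, 3, 3), matrix(FALSE, 3, 3))
  expect_identical(m0$values, g$values)
  # mask covering all forest removes the class
  mf <- apply_urban_mask(g, g$values == 3L, matrix(FALSE, 3, 3))
  expect_equal(label_patches(mf, 3)$n, 0)
  # masked metrics equal metrics of a hand-built reduced landscape
  by_hand <- g$values
  by_hand[u1 | u2] <- -9999L
  g_hand <- lc_grid(by_hand, vocabulary = g$vocabulary)
  expect_equal(class_metrics(label_patches(masked, 3)),
               class_metrics(label_patches(g_hand, 3)))
})

test_that("mean distance to unchanged forest: adjacency cases and oracle", {
  # category pixel 4-adjacent to unchanged forest contributes one cell size
  t1 <- grid_from_string("FF./.../...")
  t2 <- grid_from_string("FFF/.../...")
  ch <- classify_forest_change(t1, t2)
  expect_equal(mean_distance_to_unchanged(ch, "REFORESTED"), 30)

  # diagonal neighbour contributes 30 * sqrt(2)
  t2d <- grid_from_string("FF./..F/...")
  chd <- classify_forest_change(t1, t2d)
  expect_equal(mean_distance_to_unchanged(chd, "REFORESTED"), 30 * sqrt(2))

  # 12x12 toy map against the all-pairs brute-force oracle
  set.seed(99)
  a <- random_grid(12, 12, codes = c(3L, 7L))
  b <- random_grid(12, 12, codes = c(3L, 7L))
  ch2 <- classify_forest_change(a, b)
  un <- ch2$categories == CHANGE_CODES[["UNCHANGED_FOREST"]]
  for (cat in c("REFORESTED", "DEFORESTED")) {
    sites <- ch2$categories == CHANGE_CODES[[cat]]
    if (!any(sites)) next
    expect_equal(mean_distance_to_unchanged(ch2, cat),
                 mean(oracle_min_dists(sites, un)) * 30)
  }
})

test_that("mean distance errors on empty category or empty unchanged set", {
  t1 <- grid_from_string("FF/..")
  t2 <- grid_from_string("FF/..")
  ch <- classify_forest_change(t1, t2)
  expect_error(mean_distance_to_unchanged(ch, "REFORESTED"), "REFORESTED")
  t3 <- grid_from_string("../FF")
  ch2 <- classify_forest_change(t1, t3)  # nothing unchanged
  expect_error(mean_distance_to_unchanged(ch2, "REFORESTED"), "unchanged")
})

test_that("relative change reproduces the published scenario arithmetic", {
  # deforestation-only vs 1991 forest mean patch area: -24.4%
  expect_equal(round(relative_change(8.03, 6.07), 1), -24.4)
  # reforestation-only: +33.6%
  expect_equal(round(relative_change(8.03, 10.73), 1), 33.6)
  expect_equal(relative_change(5, 5), 0)
  expect_error(relative_change(0, 1), "non-zero")
})
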