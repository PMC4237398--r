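# Patch delineation and the four class indices, checked against analytic
# cases and brute-force flood-fill / face-count oracles.

test_that("single-pixel and 2x2 patches have analytic area and edge", {
  g <- grid_from_string("...../..F../...../")
  ps <- label_patches(g, LC_CLASSES[["FOREST"]])
  expect_equal(ps$n, 1)
  expect_equal(ps$patch_area, 900)
  expect_equal(ps$patch_edge, 120)

  g2 <- grid_from_string("..../.FF./.FF./....")
  ps2 <- label_patches(g2, LC_CLASSES[["FOREST"]])
  expect_equal(ps2$n, 1)
  expect_equal(ps2$patch_area, 4 * 900)
  expect_equal(ps2$patch_edge, 240)
})

test_that("diagonal adjacency joins patches under 8- but not 4-connectivity", {
  g <- grid_from_string("F../.F./...")
  expect_equal(label_patches(g, 3, connectivity = 8)$n, 1)
  expect_equal(label_patches(g, 3, connectivity = 4)$n, 2)
})

test_that("absent focal class gives n = 0 and flagged-undefined metrics", {
  g <- grid_from_string("PP/PP")
  ps <- label_patches(g, LC_CLASSES[["FOREST"]])
  expect_equal(ps$n, 0)
  m <- class_metrics(ps)
  expect_true(m$undefined)
  expect_true(is.na(m$AREA_MN) && is.na(m$LPI) && is.na(m$ED) &&
                is.na(m$EDGE_AREA))
})

test_that("full-coverage class has LPI 100 and analytic toy metrics hold", {
  g <- lc_grid(matrix(LC_CLASSES[["FOREST"]], 5, 5), vocabulary = 3L)
  m <- class_metrics(label_patches(g, 3))
  expect_equal(m$LPI, 100)

  # one 900 m^2 patch in a 100x100-pixel 30 m landscape (A_T = 900 ha)
  vals <- matrix(7L, 100, 100)
  vals[50, 50] <- 3L
  g2 <- lc_grid(vals, vocabulary = c(3L, 7L))
  m2 <- class_metrics(label_patches(g2, 3))
  expect_equal(m2$ED, 120 / 900)
  expect_equal(m2$AREA_MN, 0.09)
  expect_equal(m2$LPI, 100 * 900 / 9e6)
})

test_that("labels, edges and metrics match brute-force oracles on random grids", {
  set.seed(401)
  for (i in 1:6) {
    nr <- sample(10:50, 1)
    nc <- sample(10:50, 1)
    conn <- sample(c(4, 8), 1)
    pol <- sample(c("exclude", "include"), 1)
    vals <- matrix(sample(c(0L, 3L, -9999L), nr * nc, replace = TRUE,
                          prob = c(0.45, 0.4, 0.15)), nr, nc)
    g <- lc_grid(vals, vocabulary = c(0L, 3L))
    ps <- label_patches(g, 3L, connectivity = conn, boundary_policy = pol)

    mask <- g$values == 3L
    olab <- oracle_label(mask, conn)
    expect_equal(ps$n, max(olab))
    # label partitions agree up to renumbering
    if (ps$n > 0) {
      pairs <- unique(cbind(ps$labels[mask], olab[mask]))
      expect_equal(nrow(pairs), ps$n)
      ofaces <- oracle_edge_faces(olab, vals == -9999L, pol == "include")
      # map oracle patch ids to implementation ids via any shared pixel
      remap <- ps$labels[mask][match(seq_len(ps$n), olab[mask])]
      expect_equal(ps$patch_edge[remap] / 30, ofaces)
      osizes <- tabulate(olab[mask], nbins = ps$n)
      expect_equal(ps$patch_area[remap] / 900, osizes)

      m <- class_metrics(ps)
      A_T <- sum(vals != -9999L) * 900
      expect_equal(m$LPI, 100 * max(osizes) * 900 / A_T)
      expect_equal(m$ED, 1e4 * sum(ofaces) * 30 / A_T)
      expect_equal(m$AREA_MN, sum(osizes) * 900 / max(olab) / 1e4)
      expect_equal(m$EDGE_AREA, sum(ofaces) * 30 / (sum(osizes) * 900 / 1e4))
    }
  }
})

test_that("boundary policy include counts grid-border and nodata faces", {
  g <- grid_from_string("FF/FF")  # fills whole grid
  ps_ex <- label_patches(g, 3, boundary_policy = "exclude")
  expect_equal(sum(ps_ex$patch_edge), 0)
  ps_in <- compute_edges(ps_ex, "include")
  expect_equal(sum(ps_in$patch_edge), 8 * 30)
})

test_that("connecting two patches never decreases LPI nor increases n", {
  g_apart <- grid_from_string("FF.FF/...../.....")
  g_joined <- grid_from_string("FFFFF/...../.....")
  m1 <- class_metrics(label_patches(g_apart, 3))
  m2 <- class_metrics(label_patches(g_joined, 3))
  expect_lt(m2$n_patches, m1$n_patches)
  expect_gt(m2$LPI, m1$LPI)
})

test_that("ED is invariant to relabeling among background classes", {
  set.seed(77)
  vals <- matrix(sample(c(5L, 7L, 3L), 400, replace = TRUE), 20, 20)
  g1 <- lc_grid(vals, vocabulary = c(3L, 5L, 7L))
  vals2 <- vals
  vals2[vals == 5L] <- 6L
  g2 <- lc_grid(vals2, vocabulary = c(3L, 6L, 7L))
  expect_equal(class_metrics(label_patches(g1, 3))$ED,
               class_metrics(label_patches(g2, 3))$ED)
})

test_that("scattering a fixed composition raises ED and EDGE_AREA, lowers AREA_MN", {
  # 16 forest pixels as one 4x4 block vs 16 isolated pixels
  block <- matrix(7L, 12, 12)
  block[5:8, 5:8] <- 3L
  scattered <- matrix(7L, 12, 12)
  scattered[cbind(seq(1, 12, 3), rep(seq(1, 12, 3), each = 4))] <- 3L
  mb <- class_metrics(label_patches(lc_grid(block, vocabulary = c(3L, 7L)), 3))
  ms <- class_metrics(label_patches(lc_grid(scattered, vocabulary = c(3L, 7L)), 3))
  expect_equal(mb$A, ms$A)
  expect_gt(ms$ED, mb$ED)
  expect_gt(ms$EDGE_AREA, mb$EDGE_AREA)
  expect_lt(ms$AREA_MN, mb$AREA_MN)
})

test_that("checkerboard classes have symmetric metrics and tidy export works", {
  vals <- matrix(rep(c(1L, 3L), 50)[1:100], 10, 10)
  g <- lc_grid(vals, vocabulary = c(1L, 3L))
  m <- all_class_metrics(g, c(1L, 3L), connectivity = 4)
  expect_equal(m$ED[1], m$ED[2])
  expect_equal(m$AREA_MN[1], m$AREA_MN[2])
  expect_equal(m$n_patches[1], m$n_patches[2])

  td <- tidy_metrics(m, grid_id = "cb")
  expect_equal(nrow(td), 8)
  expect_setequal(unique(td$index), c("AREA_MN", "LPI", "ED", "EDGE_AREA"))
})

test_that("high-density urban is counted inside the urban class", {
  g <- grid_from_string("UH../..../")
  ps <- label_patches(g, LC_CLASSES[["URBAN"]])
  expect_equal(ps$n, 1)
  expect_equal(ps$patch_area, 2 * 900)
})
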