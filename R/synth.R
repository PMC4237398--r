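# Synthetic data generators: clustered categorical landscapes (modified
# random clusters), paired-year change with edge-biased reforestation,
# interior-biased deforestation and distance-decayed urban growth, covariate
# surfaces, and spatial-error regression data with known parameters. Every
# generator is a pure function of its recipe: the seed fully determines the
# output and the caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Recipe for a clustered synthetic landscape
#'
#' Default class proportions approximate the study island around 1991:
#' 40% forest, 12% urban, 4% wetland, 30% pasture, 6% agriculture, the
#' rest other. `clumpiness` in `[0, 1]` sets the block scale of the
#' modified-random-clusters percolation draw (0 = independent per-pixel
#' multinomial; larger values give larger patches).
#'
#' @param rows,cols Grid shape in pixels.
#' @param cell_size Pixel size, meters (default 30).
#' @param proportions Named vector of target class proportions over
#'   `URBAN`, `FOREST`, `WETLAND`, `PASTURE`, `AGRICULTURE`; must sum to
#'   at most 1, remainder is `OTHER`.
#' @param clumpiness In `[0, 1]`.
#' @param n_urban_centers Number of urban nuclei; clusters nearest these
#'   centers fill the urban quota, giving urban cover a spatial gradient
#'   (0 scatters urban like any other class).
#' @param urban_scatter_fraction Share of the urban quota assigned to
#'   randomly placed clusters instead of the nuclei — the villages and
#'   hamlets that keep remote cells from being entirely urban-free.
#' @param high_density_fraction Fraction of urban pixels, nearest the
#'   centers, labeled as the high-density urban subclass.
#' @param island Carve the landscape into an inscribed ellipse with nodata
#'   outside (emulates a coastline)? Default `FALSE`.
#' @param seed Integer seed.
#' @return A `landscape_recipe` list.
#' @export
landscape_recipe <- function(rows = 200, cols = 200, cell_size = 30,
                             proportions = c(URBAN = 0.12, FOREST = 0.40,
                                             WETLAND = 0.04, PASTURE = 0.30,
                                             AGRICULTURE = 0.06),
                             clumpiness = 0.55, n_urban_centers = 3,
                             urban_scatter_fraction = 0.15,
                             high_density_fraction = 0.25, island = FALSE,
                             seed = 1) {
  stopifnot(all(proportions >= 0), sum(proportions) <= 1 + 1e-9,
            clumpiness >= 0, clumpiness <= 1,
            urban_scatter_fraction >= 0, urban_scatter_fraction <= 1)
  structure(list(rows = rows, cols = cols, cell_size = cell_size,
                 proportions = proportions, clumpiness = clumpiness,
                 n_urban_centers = n_urban_centers,
                 urban_scatter_fraction = urban_scatter_fraction,
                 high_density_fraction = high_density_fraction,
                 island = island, seed = seed),
            class = "landscape_recipe")
}

#' Generate a clustered categorical landscape
#'
#' Modified random clusters: a Bernoulli percolation mask at a fixed
#' subcritical fill probability (0.35), drawn at a block scale that grows
#' with `clumpiness`, is labeled into 4-connected clusters; whole clusters
#' are
#' assigned to classes against per-class pixel quotas, urban quota first
#' from the clusters nearest the urban centers; the remaining land pixels
#' are claimed by growing the assigned clusters outward (multi-source
#' breadth-first propagation), which preserves spatial coherence so that
#' patches have true interiors. At `clumpiness = 0` every pixel is an
#' independent multinomial draw.
#'
#' @param recipe A [landscape_recipe()].
#' @return A categorical `fs_grid` with a `recipe` attribute.
#' @export
generate_landscape <- function(recipe) {
  stopifnot(inherits(recipe, "landscape_recipe"))
  with_seed(recipe$seed, {
    nr <- recipe$rows
    nc <- recipe$cols
    npx <- nr * nc
    nodata <- -9999L
    land <- matrix(TRUE, nr, nc)
    if (recipe$island) {
      rr <- (row(land) - (nr + 1) / 2) / (nr / 2)
      cc <- (col(land) - (nc + 1) / 2) / (nc / 2)
      land <- rr^2 + cc^2 <= 1
    }
    n_land <- sum(land)

    props <- recipe$proportions
    classes <- LC_CLASSES[names(props)]
    quota <- round(props * n_land)
    quota <- c(quota, OTHER = n_land - sum(quota))
    classes <- c(classes, OTHER = LC_CLASSES[["OTHER"]])

    vals <- matrix(0L, nr, nc)
    # percolation seeds at a fixed subcritical fill; clumpiness sets the
    # block scale of the draw, so expected patch area grows with it
    p_fill <- if (recipe$clumpiness > 0) 0.35 else 0
    b <- max(1, round(5 * recipe$clumpiness))
    nrs <- ceiling(nr / b)
    ncs <- ceiling(nc / b)
    mask_small <- matrix(runif(nrs * ncs) < p_fill, nrs, ncs)
    mask <- mask_small[rep(seq_len(nrs), each = b)[1:nr],
                       rep(seq_len(ncs), each = b)[1:nc], drop = FALSE] & land
    labels <- label_components_cpp(mask, 4L)
    n_clust <- attr(labels, "n")

    remaining <- quota
    if (n_clust > 0) {
      sizes <- tabulate(labels[labels > 0], nbins = n_clust)
      # growth hands each cluster territory proportional to its seed count,
      # so quotas are enforced in seed units
      remaining <- quota * sum(sizes) / n_land
      cl_class <- integer(n_clust)  # class code per cluster
      ord <- sample.int(n_clust)
      # urban nuclei: nearest clusters fill most of the urban quota; a
      # scatter share goes to random clusters (villages) so remote areas
      # are not urban-free
      if (recipe$n_urban_centers > 0 && remaining[["URBAN"]] > 0) {
        ctr_r <- runif(recipe$n_urban_centers, 1, nr)
        ctr_c <- runif(recipe$n_urban_centers, 1, nc)
        in_cl <- labels > 0
        cl_r <- vapply(split(row(labels)[in_cl], labels[in_cl]),
                       mean, numeric(1))
        cl_c <- vapply(split(col(labels)[in_cl], labels[in_cl]),
                       mean, numeric(1))
        dmin <- rep(Inf, n_clust)
        for (i in seq_len(recipe$n_urban_centers)) {
          dmin <- pmin(dmin, sqrt((cl_r - ctr_r[i])^2 + (cl_c - ctr_c[i])^2))
        }
        take_until <- function(order_vec, quota) {
          if (quota <= 0 || length(order_vec) == 0) return(integer(0))
          n_take <- which(cumsum(sizes[order_vec]) >= quota)[1]
          if (is.na(n_take)) n_take <- length(order_vec)
          order_vec[seq_len(n_take)]
        }
        scatter_quota <- recipe$urban_scatter_fraction * remaining[["URBAN"]]
        # remote settlements are compact towns, few and substantial: the
        # scatter quota goes to the largest clusters wherever they fall
        scattered <- take_until(order(sizes, decreasing = TRUE),
                                scatter_quota)
        # the main quota goes to the clusters nearest the nuclei, giving
        # compact urban cores
        core_order <- setdiff(order(dmin), scattered)
        cored <- take_until(core_order,
                            remaining[["URBAN"]] - sum(sizes[scattered]))
        taken <- c(scattered, cored)
        cl_class[taken] <- LC_CLASSES[["URBAN"]]
        remaining[["URBAN"]] <- remaining[["URBAN"]] - sum(sizes[taken])
        ord <- setdiff(ord, taken)
      }
      for (cl in ord) {
        pool <- pmax(remaining, 0)
        if (recipe$n_urban_centers > 0) pool["URBAN"] <- 0
        if (sum(pool) == 0) pool["OTHER"] <- 1
        pick <- sample(names(pool), 1, prob = pool)
        cl_class[cl] <- classes[[pick]]
        remaining[[pick]] <- remaining[[pick]] - sizes[cl]
      }
      in_cl <- labels > 0
      vals[in_cl] <- cl_class[labels[in_cl]]
      # grow clusters into the unclaimed land
      vals <- grow_classes_cpp(vals, land)
    }
    un <- land & vals == 0L
    n_un <- sum(un)
    if (n_un > 0) {  # no clusters at all (clumpiness ~ 0)
      pool <- pmax(remaining, 0)
      if (sum(pool) == 0) pool["OTHER"] <- 1
      vals[un] <- classes[sample(names(pool), n_un, replace = TRUE,
                                 prob = pool)]
    }
    # high-density urban: the urban pixels nearest the urban mass centre
    if (recipe$high_density_fraction > 0) {
      urb <- vals == LC_CLASSES[["URBAN"]]
      n_urb <- sum(urb)
      if (n_urb > 1) {
        wr <- mean(row(vals)[urb])
        wc <- mean(col(vals)[urb])
        d <- sqrt((row(vals)[urb] - wr)^2 + (col(vals)[urb] - wc)^2)
        n_hd <- round(recipe$high_density_fraction * n_urb)
        if (n_hd > 0) {
          hd <- which(urb)[order(d)[seq_len(n_hd)]]
          vals[hd] <- LC_CLASSES[["HIGH_DENSITY_URBAN"]]
        }
      }
    }
    vals[!land] <- nodata
    g <- lc_grid(vals, cell_size = recipe$cell_size, nodata = nodata,
                 vocabulary = unname(LC_CLASSES))
    attr(g, "recipe") <- recipe
    g
  })
}

#' Recipe for a paired-year change simulation
#'
#' Defaults follow the study's stated 1991–2000 magnitudes: 18% of the
#' first-year forest deforested (drawn from the forest interior), a
#' slightly larger reforested area (so forest grows about 2% net) drawn
#' from the forest edge, deforested pixels converted 75% to pasture and
#' 21% to urban, and urban area growing by 8% with placement probability
#' decaying in distance from existing urban cover.
#'
#' @param edge_reforestation_fraction Reforested pixels as a fraction of
#'   first-year forest, drawn from non-forest pixels within a 1-pixel
#'   dilation of forest.
#' @param interior_deforestation_fraction Deforested fraction of
#'   first-year forest, drawn from pixels at least 2 pixels inside the
#'   forest boundary (with a boundary fallback when the core is empty).
#' @param urban_growth_fraction New urban pixels as a fraction of
#'   first-year urban.
#' @param urban_distance_decay e-folding distance (m) of the urban growth
#'   placement probability.
#' @param deforestation_fate Named proportions splitting deforested pixels
#'   among replacement classes.
#' @param deforestation_blob_pixels Mean size (pixels) of a contiguous
#'   clearing; deforestation is applied as clearings grown from interior
#'   seeds — clearings, not scattered pixels, are what split forest
#'   patches. The default of 12 pixels (about 1 ha at 30 m) puts cleared
#'   pixels roughly two pixel-widths from the remaining forest, the scale
#'   of the published mean deforested-site distance (~56 m).
#' @param reforestation_blob_pixels Mean size (pixels) of a regrowth patch
#'   on the forest edge; the default of 30 pixels lets succession advance
#'   a few pixels outward where it occurs, the scale of the published mean
#'   reforested-site distance (~67 m).
#' @param urban_source_min_pixels Minimum patch size (pixels) for an urban
#'   patch to act as a sprawl source. The default of 1 lets every urban
#'   pixel seed further growth, so the development frontier creeps
#'   outward between epochs; a large value restricts sprawl to towns and
#'   cities.
#' @param new_town_fraction Share of the urban growth budget spent on new
#'   compact settlements placed anywhere on the land surface (municipal
#'   growth far from the existing cores). Because the distance-to-urban
#'   covariate is referenced to the earliest map, these towns are what
#'   puts compact, low edge-to-area urban at large distances.
#' @param new_town_pixels Size (pixels) of one new town, rasterized as a
#'   disc (default 500, 45 ha at 30 m).
#' @param seed Integer seed.
#' @return A `change_recipe` list.
#' @export
change_recipe <- function(edge_reforestation_fraction = 0.20,
                          interior_deforestation_fraction = 0.18,
                          urban_growth_fraction = 0.08,
                          urban_distance_decay = 1000,
                          deforestation_fate = c(PASTURE = 0.75, URBAN = 0.21,
                                                 OTHER = 0.04),
                          deforestation_blob_pixels = 12,
                          reforestation_blob_pixels = 30,
                          urban_source_min_pixels = 1,
                          new_town_fraction = 0,
                          new_town_pixels = 500,
                          seed = 1) {
  fr <- c(edge_reforestation_fraction, interior_deforestation_fraction,
          urban_growth_fraction, new_town_fraction)
  stopifnot(all(fr >= 0), all(fr <= 1), urban_distance_decay > 0,
            deforestation_blob_pixels >= 1, reforestation_blob_pixels >= 1,
            urban_source_min_pixels >= 1, new_town_pixels >= 1)
  structure(list(edge_reforestation_fraction = edge_reforestation_fraction,
                 interior_deforestation_fraction = interior_deforestation_fraction,
                 urban_growth_fraction = urban_growth_fraction,
                 urban_distance_decay = urban_distance_decay,
                 deforestation_fate = deforestation_fate,
                 deforestation_blob_pixels = deforestation_blob_pixels,
                 reforestation_blob_pixels = reforestation_blob_pixels,
                 urban_source_min_pixels = urban_source_min_pixels,
                 new_town_fraction = new_town_fraction,
                 new_town_pixels = new_town_pixels,
                 seed = seed),
            class = "change_recipe")
}

#' Simulate a pair of land-cover years with known forest change
#'
#' Starting from `base` (the first year), applies interior-biased
#' deforestation, edge-biased reforestation, then distance-decayed urban
#' growth, and returns both years plus the ground-truth change map
#' (computed from the two forest masks, so [classify_forest_change()] on
#' the pair reproduces it exactly).
#'
#' @param base Categorical `fs_grid` with forest and urban pixels.
#' @param recipe A [change_recipe()].
#' @return List `grid_t1`, `grid_t2`, `truth` (an `fs_changemap`).
#' @export
generate_change_pair <- function(base, recipe) {
  stopifnot(inherits(base, "fs_grid"), inherits(recipe, "change_recipe"))
  with_seed(recipe$seed, {
    vals <- base$values
    land <- land_mask(base)
    forest1 <- class_mask(base, LC_CLASSES[["FOREST"]])
    urban1 <- class_mask(base, LC_CLASSES[["URBAN"]])
    if (!any(forest1)) stop("base landscape has no forest", call. = FALSE)
    n_forest <- sum(forest1)

    # deforestation: contiguous clearings grown from seeds in the erosion
    # core (>= 2 pixels inside the forest boundary); clearings, not
    # scattered pixels, are what split forest patches apart
    n_def <- round(recipe$interior_deforestation_fraction * n_forest)
    if (n_def > 0) {
      d_edge <- sqrt(edt_sq_cpp(!forest1 | !land))
      core <- forest1 & d_edge >= 2
      pool <- which(core)
      if (length(pool) < ceiling(n_def / recipe$deforestation_blob_pixels)) {
        warning("forest erosion core smaller than requested deforestation; ",
                "falling back to boundary pixels")
        pool <- which(forest1)
      }
      n_seeds <- max(1, min(length(pool),
                            round(n_def / recipe$deforestation_blob_pixels)))
      seeds <- if (length(pool) == n_seeds) pool else sample(pool, n_seeds)
      def <- matrix(FALSE, nrow(vals), ncol(vals))
      def[seeds] <- TRUE
      nr <- nrow(vals)
      ncl <- ncol(vals)
      while (sum(def) < n_def) {
        # one dilation ring of the clearings, clipped to forest
        ring <- (rbind(def[-1, ], FALSE) | rbind(FALSE, def[-nr, ]) |
                   cbind(def[, -1], FALSE) | cbind(FALSE, def[, -ncl])) &
          forest1 & !def
        ring_px <- which(ring)
        if (length(ring_px) == 0) break
        need <- n_def - sum(def)
        if (length(ring_px) > need) ring_px <- sample(ring_px, need)
        def[ring_px] <- TRUE
      }
      # each clearing converts to a single class; urban-fated clearings
      # are the ones nearest existing urban (development does not appear
      # in the remote interior)
      def_labels <- label_components_cpp(def, 4L)
      n_blobs <- attr(def_labels, "n")
      blob_sizes <- tabulate(def_labels[def_labels > 0], nbins = n_blobs)
      fate <- recipe$deforestation_fate
      blob_fate <- rep(LC_CLASSES[["PASTURE"]], n_blobs)
      if (!is.null(fate[["URBAN"]]) && fate[["URBAN"]] > 0 && any(urban1)) {
        d_to_urb <- sqrt(edt_sq_cpp(urban1))
        blob_d <- vapply(split(d_to_urb[def_labels > 0],
                               def_labels[def_labels > 0]),
                         min, numeric(1))
        urb_quota <- fate[["URBAN"]] * sum(blob_sizes)
        near_order <- order(blob_d)
        n_take <- which(cumsum(blob_sizes[near_order]) >= urb_quota)[1]
        if (is.na(n_take)) n_take <- n_blobs
        blob_fate[near_order[seq_len(n_take)]] <- LC_CLASSES[["URBAN"]]
      }
      other_p <- fate[!names(fate) %in% c("URBAN", "PASTURE")]
      if (length(other_p) > 0 && sum(other_p) > 0) {
        pasture_blobs <- which(blob_fate == LC_CLASSES[["PASTURE"]])
        n_other <- round(sum(other_p) / (sum(other_p) + fate[["PASTURE"]]) *
                           length(pasture_blobs))
        if (n_other > 0) {
          oth <- sample(pasture_blobs, n_other)
          blob_fate[oth] <- LC_CLASSES[sample(names(other_p), n_other,
                                              replace = TRUE, prob = other_p)]
        }
      }
      in_def <- def_labels > 0
      vals[in_def] <- blob_fate[def_labels[in_def]]
    }

    # reforestation: abandoned-field patches regrow outward from seeds on
    # the forest edge (secondary succession); every patch stays connected
    # to the forest it sprang from, so each added pixel is within a
    # 1-pixel dilation of the forest standing when it is added
    n_ref <- round(recipe$edge_reforestation_fraction * n_forest)
    if (n_ref > 0) {
      nr <- nrow(vals)
      ncl <- ncol(vals)
      d_for <- sqrt(edt_sq_cpp(forest1))
      ring1 <- !forest1 & land & d_for <= sqrt(2) + 1e-9
      pool <- which(ring1)
      n_seeds <- max(1, min(length(pool),
                            round(n_ref / recipe$reforestation_blob_pixels)))
      if (length(pool) == 0) {
        warning("no edge candidates for reforestation")
      } else {
        seeds <- if (length(pool) == n_seeds) pool else sample(pool, n_seeds)
        ref <- matrix(FALSE, nr, ncl)
        ref[seeds] <- TRUE
        repeat {
          if (sum(ref) >= n_ref) break
          ring <- (rbind(ref[-1, ], FALSE) | rbind(FALSE, ref[-nr, ]) |
                     cbind(ref[, -1], FALSE) | cbind(FALSE, ref[, -ncl])) &
            !ref & land & !forest1
          ring_px <- which(ring)
          if (length(ring_px) == 0) break
          need <- n_ref - sum(ref)
          if (length(ring_px) > need) ring_px <- sample(ring_px, need)
          ref[ring_px] <- TRUE
        }
        if (sum(ref) < n_ref) {
          warning("fewer reforestation candidates than requested; added ",
                  sum(ref), " of ", n_ref, " pixels")
        }
        vals[ref] <- LC_CLASSES[["FOREST"]]
      }
    }

    # urban growth, placement decaying with distance from first-year urban
    # sources (patches large enough to act as towns)
    if (any(urban1) && recipe$urban_growth_fraction > 0) {
      n_urb <- round(recipe$urban_growth_fraction * sum(urban1))
      n_town_px <- round(recipe$new_town_fraction * n_urb)
      n_sprawl <- n_urb - n_town_px
      is_urban_now <- function() {
        matrix(vals %in% c(LC_CLASSES[["URBAN"]],
                           LC_CLASSES[["HIGH_DENSITY_URBAN"]]), nrow(vals))
      }
      if (n_sprawl > 0) {
        ups <- label_patches(base, LC_CLASSES[["URBAN"]])
        big <- which(ups$patch_area >=
                       recipe$urban_source_min_pixels * base$cell_size^2)
        src <- if (length(big) > 0) {
          matrix(ups$labels %in% big, nrow(ups$labels))
        } else urban1
        d_urb <- sqrt(edt_sq_cpp(src)) * base$cell_size
        cand <- which(land & !urban1 & !is_urban_now())
        # development attaches to existing settlement: probability decays
        # with distance and is cut off beyond three decay lengths
        reach <- d_urb[cand] <= 3 * recipe$urban_distance_decay
        cand <- cand[reach]
        if (length(cand) > 0) {
          n_sprawl <- min(n_sprawl, length(cand))
          wts <- exp(-d_urb[cand] / recipe$urban_distance_decay)
          new_urb <- sample(cand, n_sprawl, prob = wts)
          vals[new_urb] <- LC_CLASSES[["URBAN"]]
        }
      }
      if (n_town_px > 0) {
        n_towns <- max(1, round(n_town_px / recipe$new_town_pixels))
        r <- sqrt(recipe$new_town_pixels / pi)
        open <- which(land & !is_urban_now())
        centers <- sample(open, n_towns)
        nrv <- nrow(vals)
        rr <- row(vals)
        cc <- col(vals)
        for (ct in centers) {
          cr0 <- rr[ct]
          cc0 <- cc[ct]
          disc <- (rr - cr0)^2 + (cc - cc0)^2 <= r^2
          vals[disc & land] <- LC_CLASSES[["URBAN"]]
        }
      }
    }

    g2 <- lc_grid(vals, cell_size = base$cell_size, origin = base$origin,
                  nodata = base$nodata, vocabulary = base$vocabulary)
    truth <- classify_forest_change(base, g2)
    list(grid_t1 = base, grid_t2 = g2, truth = truth)
  })
}

# running mean over +-r rows, edge-truncated
row_running_mean <- function(m, r) {
  n <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  hi <- pmin(seq_len(n) + r, n)
  lo <- pmax(seq_len(n) - r, 1)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

box_blur <- function(m, radius, passes = 2) {
  for (i in seq_len(passes)) {
    m <- row_running_mean(m, radius)
    m <- t(row_running_mean(t(m), radius))
  }
  m
}

#' Generate covariate surfaces for a landscape
#'
#' Produces the regression covariates the pipeline consumes: smoothed-noise
#' elevation (m), a slope surface in degrees (Horn gradient of the
#' elevation, clipped to `[0, 45]`), population density as a sum of
#' Gaussian kernels centred on the largest urban patches (persons km^-2,
#' decaying with distance from urban mass), and the exact
#' distance-to-urban surface (m).
#'
#' @param grid Categorical `fs_grid` (urban pixels seed the density and
#'   distance surfaces).
#' @param seed Integer seed.
#' @param relief Elevation range in meters (default 900).
#' @return Named list of continuous `fs_grid`s: `elevation`, `slope`,
#'   `pop_density`, `dist_urban`.
#' @export
generate_covariates <- function(grid, seed = 1, relief = 900) {
  stopifnot(inherits(grid, "fs_grid"))
  with_seed(seed, {
    nr <- nrow(grid$values)
    nc <- ncol(grid$values)
    radius <- max(3, round(min(nr, nc) / 25))
    z <- box_blur(matrix(rnorm(nr * nc), nr, nc), radius, passes = 3)
    z <- (z - min(z)) / (max(z) - min(z)) * relief
    elevation <- covariate_grid(z, cell_size = grid$cell_size,
                                origin = grid$origin)
    slope <- horn_slope(elevation)
    slope$values <- pmin(pmax(slope$values, 0), 45)

    urb <- class_mask(grid, LC_CLASSES[["URBAN"]])
    if (!any(urb)) stop("landscape has no urban pixels", call. = FALSE)
    ps <- label_patches(grid, LC_CLASSES[["URBAN"]])
    n_top <- min(ps$n, 20)
    top <- order(ps$patch_area, decreasing = TRUE)[seq_len(n_top)]
    dens <- matrix(10, nr, nc)  # rural floor, persons km^-2
    rr <- row(dens)
    cc <- col(dens)
    sigma_px <- 2000 / grid$cell_size
    for (k in top) {
      px <- ps$labels == k
      kr <- mean(rr[px])
      kc <- mean(cc[px])
      amp <- 3000 * ps$patch_area[k] / max(ps$patch_area)
      dens <- dens + amp * exp(-((rr - kr)^2 + (cc - kc)^2) / (2 * sigma_px^2))
    }
    pop_density <- covariate_grid(dens, cell_size = grid$cell_size,
                                  origin = grid$origin)
    list(elevation = elevation, slope = slope, pop_density = pop_density,
         dist_urban = distance_to_urban_surface(grid))
  })
}

#' Recipe for spatial-error regression data with known parameters
#'
#' @param n Number of observations; a perfect square lays the points on a
#'   regular lattice, otherwise they are uniform random in the unit
#'   square.
#' @param beta True coefficient vector; the first element is the
#'   intercept.
#' @param lambda True spatial error coefficient (inside the stationary
#'   interval of the generated weights).
#' @param sigma Innovation standard deviation.
#' @param k Neighbours for the kNN weights.
#' @param seed Integer seed.
#' @return An `sem_recipe` list.
#' @export
sem_recipe <- function(n = 400, beta = c(1, 2), lambda = 0.5, sigma = 1,
                       k = 8, seed = 1) {
  stopifnot(n > k, length(beta) >= 1, sigma > 0)
  structure(list(n = n, beta = beta, lambda = lambda, sigma = sigma, k = k,
                 seed = seed),
            class = "sem_recipe")
}

#' Draw one dataset from the spatial error model
#'
#' Inverts the model: `y = X beta + (I - lambda W)^-1 xi` with
#' `xi ~ N(0, sigma^2 I)`, on kNN weights over lattice or random points.
#'
#' @param recipe An [sem_recipe()].
#' @param weights Optional pre-built `fs_weights` to reuse across
#'   replicates (its `n` must match); saves the eigendecomposition.
#' @return List `y`, `X`, `weights`, `coords`, `truth` (beta, lambda,
#'   sigma).
#' @export
generate_sem_data <- function(recipe, weights = NULL) {
  stopifnot(inherits(recipe, "sem_recipe"))
  with_seed(recipe$seed, {
    n <- recipe$n
    side <- sqrt(n)
    coords <- if (side == round(side)) {
      as.matrix(expand.grid(x = seq_len(side), y = seq_len(side)))
    } else {
      cbind(x = runif(n), y = runif(n))
    }
    if (is.null(weights)) {
      weights <- knn_weights(coords, k = recipe$k)
    } else {
      stopifnot(inherits(weights, "fs_weights"), weights$n == n)
    }
    iv <- lambda_interval(weights, eps = 0)
    if (recipe$lambda <= iv[1] || recipe$lambda >= iv[2]) {
      stop("lambda outside the stationary interval (",
           signif(iv[1], 4), ", ", signif(iv[2], 4), ")", call. = FALSE)
    }
    p <- length(recipe$beta)
    X <- cbind(intercept = rep(1, n))
    if (p > 1) {
      Xr <- matrix(rnorm(n * (p - 1)), n, p - 1)
      colnames(Xr) <- paste0("x", seq_len(p - 1))
      X <- cbind(X, Xr)
    }
    xi <- rnorm(n, sd = recipe$sigma)
    A <- Matrix::Diagonal(n) - recipe$lambda * weights$W
    eps <- as.numeric(Matrix::solve(A, xi))
    y <- as.numeric(X %*% recipe$beta + eps)
    list(y = y, X = X, weights = weights, coords = coords,
         truth = list(beta = recipe$beta, lambda = recipe$lambda,
                      sigma = recipe$sigma))
  })
}

#' Simulate the sprawl-gradient island scenario
#'
#' A three-date world built to exercise the whole pipeline: a monocentric
#' island (one urban core, no pre-existing remote settlement) undergoes two
#' epochs of change. Each epoch applies interior-biased deforestation,
#' edge-biased reforestation, sprawl around the core, and the founding of
#' compact new towns far from it; the second epoch's development reach is
#' longer than the first (accelerating sprawl). The distance-to-urban
#' covariate is referenced to the initial date, so later towns sit at
#' large distances with compact urban cover — the geometry that makes the
#' urban edge-to-area ratio rise and then fall along the distance axis,
#' with its peak moving outward between the two analysis dates.
#'
#' @param seed Integer seed (drives all three stages).
#' @param rows,cols Island size in pixels (default 600, i.e. 18 km at
#'   30 m).
#' @param decay_t1,decay_t2 Sprawl decay lengths (m) of the two epochs;
#'   the default lengthening from 1200 to 2000 m encodes accelerating
#'   sprawl.
#' @return List: `grid_t0` (reference date), `grid_t1`, `grid_t2`,
#'   `dist_urban` (distance surface from the reference date),
#'   `change_t1_t2` (truth map of the second epoch), and the recipes used.
#' @export
simulate_sprawl_island <- function(seed = 1, rows = 600, cols = 600,
                                   decay_t1 = 1200, decay_t2 = 2000) {
  base_recipe <- landscape_recipe(
    rows = rows, cols = cols, n_urban_centers = 1,
    urban_scatter_fraction = 0,
    proportions = c(URBAN = 0.06, FOREST = 0.40, WETLAND = 0.04,
                    PASTURE = 0.30, AGRICULTURE = 0.06),
    seed = seed)
  epoch <- function(s, decay) {
    change_recipe(urban_distance_decay = decay, urban_growth_fraction = 0.20,
                  urban_source_min_pixels = 2000, new_town_fraction = 0.4,
                  new_town_pixels = 300, seed = s)
  }
  g0 <- generate_landscape(base_recipe)
  r1 <- epoch(seed + 100, decay_t1)
  r2 <- epoch(seed + 200, decay_t2)
  e1 <- generate_change_pair(g0, r1)
  e2 <- generate_change_pair(e1$grid_t2, r2)
  list(grid_t0 = g0, grid_t1 = e1$grid_t2, grid_t2 = e2$grid_t2,
       dist_urban = distance_to_urban_surface(g0),
       change_t1_t2 = e2$truth,
       recipes = list(base = base_recipe, epoch1 = r1, epoch2 = r2))
}
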