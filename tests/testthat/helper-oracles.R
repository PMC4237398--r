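# Independent brute-force oracles. These deliberately share no code with
# the package implementation: labeling by recursive flood fill over an
# explicit stack, edge counting by face enumeration, distances by all-pairs
# search.

# flood-fill connected components, connectivity 4 or 8
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  nxt <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (i in seq_len(nrow(offs))) {
        r <- p[1] + offs[i, 1]
        cc <- p[2] + offs[i, 2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- nxt
          stack[[length(stack) + 1]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# per-patch edge faces by exhaustive face enumeration
oracle_edge_faces <- function(labels, nodata_mask, include_boundary = FALSE) {
  nr <- nrow(labels)
  nc <- ncol(labels)
  n <- max(labels)
  faces <- numeric(n)
  if (n == 0) return(faces)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    lab <- labels[r, cc]
    if (lab == 0) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]
      c2 <- cc + d[2]
      outside <- rr < 1 || rr > nr || c2 < 1 || c2 > nc
      if (outside || nodata_mask[rr, c2]) {
        if (include_boundary) faces[lab] <- faces[lab] + 1
      } else if (labels[rr, c2] != lab) {
        faces[lab] <- faces[lab] + 1
      }
    }
  }
  faces
}

# all-pairs minimum distance (pixel units) from each TRUE in `from` to the
# nearest TRUE in `to`
oracle_min_dists <- function(from, to) {
  fi <- which(from, arr.ind = TRUE)
  ti <- which(to, arr.ind = TRUE)
  apply(fi, 1, function(p) {
    min(sqrt((ti[, 1] - p[1])^2 + (ti[, 2] - p[2])^2))
  })
}

# random categorical grid with the given codes
random_grid <- function(nr, nc, codes = c(0L, 3L), cell_size = 30,
                        prob = NULL) {
  vals <- matrix(sample(codes, nr * nc, replace = TRUE, prob = prob), nr, nc)
  lc_grid(vals, cell_size = cell_size, vocabulary = codes)
}

# grid from a compact string: rows separated by /, "." = background (7),
# F = forest, U = urban, W = wetland, P = pasture, N = nodata
grid_from_string <- function(s, cell_size = 30) {
  rows <- strsplit(s, "/", fixed = TRUE)[[1]]
  code <- c("." = 7L, F = 3L, U = 1L, H = 2L, W = 4L, P = 5L, A = 6L,
            N = -9999L)
  m <- do.call(rbind, lapply(rows, function(r) {
    code[strsplit(r, "")[[1]]]
  }))
  dimnames(m) <- NULL
  lc_grid(m, cell_size = cell_size, vocabulary = unname(code[names(code) != "N"]))
}
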