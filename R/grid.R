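# Raster containers and ESRI ASCII grid I/O.
#
# Grids are stored as plain R matrices in row-major raster order: row 1 is
# the top of the map, column 1 the left. The origin is the projected
# coordinate of the top-left corner; pixel (r, c) has its center at
# origin + ((c - 0.5) * cell_size, -(r - 0.5) * cell_size).

#' Construct a land-cover or covariate grid
#'
#' `lc_grid()` builds a categorical land-cover grid whose non-nodata values
#' must all belong to `vocabulary`; `covariate_grid()` builds a continuous
#' surface (elevation, slope, density, distance).
#'
#' @param values Numeric or integer matrix; row 1 is the top of the map.
#' @param cell_size Pixel edge length in meters (> 0).
#' @param origin Numeric length-2, projected (x, y) of the top-left corner.
#' @param nodata Value marking non-landscape pixels.
#' @param vocabulary Integer codes that values may take; defaults to the
#'   codes present in `values`.
#' @return An object of class `fs_grid`.
#' @examples
#' g <- lc_grid(matrix(LC_CLASSES[["FOREST"]], 3, 3), cell_size = 30)
#' @export
lc_grid <- function(values, cell_size = 30, origin = c(0, 0), nodata = -9999L,
                    vocabulary = NULL) {
  values <- as_int_matrix(values)
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(values[values != nodata]))
  }
  g <- new_grid(values, cell_size, origin, nodata, kind = "categorical")
  g$vocabulary <- as.integer(vocabulary)
  validate_grid(g)
}

#' @rdname lc_grid
#' @export
covariate_grid <- function(values, cell_size = 30, origin = c(0, 0),
                           nodata = -9999) {
  storage.mode(values) <- "double"
  validate_grid(new_grid(values, cell_size, origin, nodata, kind = "continuous"))
}

new_grid <- function(values, cell_size, origin, nodata, kind) {
  structure(
    list(values = values, cell_size = cell_size, origin = as.numeric(origin),
         nodata = nodata, kind = kind),
    class = "fs_grid"
  )
}

as_int_matrix <- function(values) {
  if (!is.matrix(values)) stop("grid values must be a matrix", call. = FALSE)
  if (is.double(values) && any(values != round(values), na.rm = TRUE)) {
    stop("categorical grid values must be whole numbers", call. = FALSE)
  }
  storage.mode(values) <- "integer"
  values
}

validate_grid <- function(g) {
  stopifnot(is.matrix(g$values), nrow(g$values) >= 1, ncol(g$values) >= 1)
  if (!is.numeric(g$cell_size) || length(g$cell_size) != 1 || g$cell_size <= 0) {
    stop("cell_size must be a single positive number", call. = FALSE)
  }
  if (length(g$origin) != 2) stop("origin must be length 2", call. = FALSE)
  if (identical(g$kind, "categorical")) {
    bad <- setdiff(unique(g$values[g$values != g$nodata]), g$vocabulary)
    if (length(bad) > 0) {
      stop("grid contains codes outside its vocabulary: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  g
}

#' @export
print.fs_grid <- function(x, ...) {
  cat(sprintf("<fs_grid %s> %d x %d pixels, cell %g m, origin (%g, %g)\n",
              x$kind, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  if (x$kind == "categorical") {
    cat("  vocabulary:", paste(x$vocabulary, collapse = " "), "\n")
  }
  cat("  nodata:", x$nodata, "| land pixels:", sum(land_mask(x)), "\n")
  invisible(x)
}

#' Logical mask of land (non-nodata) pixels
#' @param grid An `fs_grid`.
#' @return Logical matrix, `TRUE` where the pixel is landscape.
#' @export
land_mask <- function(grid) {
  m <- grid$values != grid$nodata & !is.na(grid$values)
  m
}

#' Logical mask of a focal class
#'
#' For `URBAN` the mask includes `HIGH_DENSITY_URBAN`, which is a counted
#' subclass of urban for every metric.
#'
#' @param grid Categorical `fs_grid`.
#' @param focal_class Integer class code (see [LC_CLASSES]).
#' @return Logical matrix.
#' @export
class_mask <- function(grid, focal_class) {
  codes <- focal_class
  if (identical(as.integer(focal_class), LC_CLASSES[["URBAN"]])) {
    codes <- c(LC_CLASSES[["URBAN"]], LC_CLASSES[["HIGH_DENSITY_URBAN"]])
  }
  m <- matrix(grid$values %in% codes, nrow = nrow(grid$values))
  m & land_mask(grid)
}

#' Total landscape area of a grid, in square meters
#'
#' Nodata pixels are not landscape: they are excluded from the total area
#' `A_T` that normalizes LPI and edge density.
#' @inheritParams land_mask
#' @return Area in m^2.
#' @export
landscape_area <- function(grid) {
  sum(land_mask(grid)) * grid$cell_size^2
}

# ---- alignment ---------------------------------------------------------

#' Test whether grids share the same geometry
#'
#' Grids are aligned iff they have identical shape, cell size, and origin.
#' All cross-grid operations (change detection, masking, covariate
#' summaries) require alignment.
#'
#' @param grids A list of two or more `fs_grid` objects.
#' @return `TRUE` or `FALSE`.
#' @export
align_check <- function(grids) {
  stopifnot(length(grids) >= 2)
  ref <- grids[[1]]
  all(vapply(grids[-1], function(g) {
    identical(dim(g$values), dim(ref$values)) &&
      isTRUE(all.equal(g$cell_size, ref$cell_size)) &&
      isTRUE(all.equal(g$origin, ref$origin))
  }, logical(1)))
}

require_aligned <- function(..., what = "operation") {
  if (!align_check(list(...))) {
    stop(what, " requires aligned grids (same shape, cell size, origin)",
         call. = FALSE)
  }
  invisible(TRUE)
}

# ---- reclassification --------------------------------------------------

#' Read a reclassification table
#'
#' Two-column CSV `source_code,target_class`, with target classes named as
#' in [LC_CLASSES] (or `NODATA`). Stands in for the study-specific
#' crosswalk from original map legends to the analysis vocabulary.
#'
#' @param path CSV file path.
#' @return A data.frame with integer `source_code` and `target_class` code.
#' @export
read_reclass_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source_code", "target_class") %in% names(tab))) {
    stop("reclass table needs columns source_code,target_class", call. = FALSE)
  }
  legal <- c(names(LC_CLASSES), "NODATA")
  bad <- setdiff(tab$target_class, legal)
  if (length(bad) > 0) {
    stop("unknown target class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tab$source_code <- as.integer(tab$source_code)
  tab
}

#' Reclassify a categorical grid
#'
#' Maps every original class code to the analysis vocabulary. Every code
#' present in the grid must appear in the table; nodata maps to nodata.
#'
#' @param grid Categorical `fs_grid`.
#' @param table Data frame with `source_code` and `target_class` (class
#'   names from [LC_CLASSES] or `NODATA`), as from [read_reclass_table()].
#' @return A reclassified `fs_grid` with the target vocabulary.
#' @export
reclassify <- function(grid, table) {
  stopifnot(inherits(grid, "fs_grid"), grid$kind == "categorical")
  present <- unique(grid$values[grid$values != grid$nodata])
  missing <- setdiff(present, table$source_code)
  if (length(missing) > 0) {
    stop("no reclass rule for code(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  target_code <- ifelse(table$target_class == "NODATA",
                        grid$nodata, LC_CLASSES[table$target_class])
  lut <- structure(as.integer(target_code), names = table$source_code)
  out <- grid$values
  keep <- grid$values != grid$nodata
  out[keep] <- lut[as.character(grid$values[keep])]
  lc_grid(out, cell_size = grid$cell_size, origin = grid$origin,
          nodata = grid$nodata,
          vocabulary = sort(unique(as.integer(target_code[target_code != grid$nodata]))))
}

# ---- ESRI ASCII grid I/O ----------------------------------------------

#' Read an ESRI ASCII grid
#'
#' The header must declare `cellsize` and `NODATA_value`; a file without an
#' explicit nodata declaration is rejected rather than guessed at.
#'
#' @param path File path.
#' @param kind `"categorical"` or `"continuous"`.
#' @return An `fs_grid` of the requested kind.
#' @export
read_asc_grid <- function(path, kind = c("categorical", "continuous")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, n = 6)
  header <- list()
  n_header <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1]) &&
        !is.na(suppressWarnings(as.numeric(parts[2])))) {
      header[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_header <- n_header + 1
    } else break
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(header))) {
    stop("not an ESRI ASCII grid (missing ncols/nrows header): ", path,
         call. = FALSE)
  }
  if (is.null(header$cellsize)) {
    stop("grid header declares no cellsize; refusing to guess: ", path,
         call. = FALSE)
  }
  if (is.null(header$nodata_value)) {
    stop("grid header declares no NODATA_value; refusing to guess: ", path,
         call. = FALSE)
  }
  nc <- as.integer(header$ncols)
  nr <- as.integer(header$nrows)
  vals <- scan(path, what = double(), skip = n_header, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("grid body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  xll <- if (!is.null(header$xllcorner)) header$xllcorner else 0
  yll <- if (!is.null(header$yllcorner)) header$yllcorner else 0
  origin <- c(xll, yll + nr * header$cellsize)  # top-left corner
  if (kind == "categorical") {
    lc_grid(m, cell_size = header$cellsize, origin = origin,
            nodata = as.integer(header$nodata_value))
  } else {
    covariate_grid(m, cell_size = header$cellsize, origin = origin,
                   nodata = header$nodata_value)
  }
}

#' Write an ESRI ASCII grid
#'
#' @param grid An `fs_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_asc_grid <- function(grid, path) {
  stopifnot(inherits(grid, "fs_grid"))
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  header <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2] - nr * grid$cell_size),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", as.numeric(grid$nodata))
  )
  body <- apply(grid$values, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Pixel-center coordinates of a grid
#'
#' @inheritParams land_mask
#' @return List with vectors `x` (per column) and `y` (per row), projected
#'   meters at pixel centers.
#' @export
pixel_centers <- function(grid) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  list(
    x = grid$origin[1] + (seq_len(nc) - 0.5) * grid$cell_size,
    y = grid$origin[2] - (seq_len(nr) - 0.5) * grid$cell_size
  )
}
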