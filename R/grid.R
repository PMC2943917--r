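#' Construct a raster grid
#'
#' A `Grid` is the universal spatial carrier of the package: a 2-D matrix of
#' cell values plus the georeferencing needed to place it (origin, cell size,
#' nodata sentinel). Row 1 is always the northernmost row; cells are square.
#' Nodata cells are stored as `NA` internally and excluded from every
#' statistic and sampling pool; the `nodata` field only records the sentinel
#' used on disk.
#'
#' @param values numeric matrix; row 1 = north. `NA` marks nodata.
#' @param origin length-2 numeric, map coordinates (x, y) of the *outer*
#'   corner of the top-left cell (i.e. west edge, north edge).
#' @param cell_size positive number, map units; cells are square.
#' @param nodata sentinel value used when writing to disk (default -9999).
#' @param crs_label free-text tag carried along, never interpreted.
#' @return an object of class `nm_grid`.
#' @export
grid_create <- function(values, origin = c(0, 0), cell_size = 1,
                        nodata = -9999, crs_label = "unspecified") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values),
            length(origin) == 2, is.finite(cell_size), cell_size > 0,
            nrow(values) >= 1, ncol(values) >= 1)
  storage.mode(values) <- "double"
  structure(list(values = values,
                 origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size),
                 nodata = as.numeric(nodata),
                 crs_label = as.character(crs_label)),
            class = "nm_grid")
}

#' @export
print.nm_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<nm_grid> %d x %d cells, cell_size %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  defined cells: %d of %d; range [%g, %g]\n",
              sum(!is.na(v)), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.nm_grid <- function(x) dim(x$values)

is_grid <- function(x) inherits(x, "nm_grid")

#' Test exact alignment of two grids
#'
#' Grids are aligned iff origin, cell size and shape match exactly.
#' Every multi-layer operation in the package requires alignment.
#'
#' @param a,b `nm_grid` objects.
#' @return logical scalar.
#' @export
grids_aligned <- function(a, b) {
  is_grid(a) && is_grid(b) &&
    identical(dim(a$values), dim(b$values)) &&
    isTRUE(all(abs(a$origin - b$origin) < 1e-9)) &&
    isTRUE(abs(a$cell_size - b$cell_size) < 1e-12)
}

stop_if_unaligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b)) {
    stop(sprintf(
      "%s are not aligned: [%d x %d, origin (%g, %g), cell %g] vs [%d x %d, origin (%g, %g), cell %g]",
      what, nrow(a$values), ncol(a$values), a$origin[1], a$origin[2], a$cell_size,
      nrow(b$values), ncol(b$values), b$origin[1], b$origin[2], b$cell_size),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' Map coordinates of cell centers
#'
#' @param grid an `nm_grid`.
#' @param rows,cols integer vectors of equal length (1-based, row 1 = north).
#' @return matrix with columns `x`, `y`.
#' @export
cell_center <- function(grid, rows, cols) {
  cs <- grid$cell_size
  cbind(x = grid$origin[1] + (cols - 0.5) * cs,
        y = grid$origin[2] - (rows - 0.5) * cs)
}

#' Locate points on a grid (half-open cell membership)
#'
#' A point belongs to cell (r, c) iff x is in \[x_left, x_right) and y in
#' (y_bottom, y_top\], so every point on a shared edge resolves to exactly
#' one cell.
#'
#' @param grid an `nm_grid`.
#' @param x,y numeric vectors of map coordinates.
#' @return data.frame with columns `row`, `col`; `NA` where the point falls
#'   outside the grid extent.
#' @export
locate_cell <- function(grid, x, y) {
  cs <- grid$cell_size
  col <- floor((x - grid$origin[1]) / cs) + 1L
  row <- floor((grid$origin[2] - y) / cs) + 1L
  # top edge of the grid belongs to row 1
  row[!is.na(y) & y == grid$origin[2]] <- 1L
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  bad <- is.na(row) | is.na(col) | row < 1L | row > nr | col < 1L | col > nc
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Read a single-layer raster from disk
#'
#' Supports the ESRI ASCII grid format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header). Parsing is delegated to
#' \code{sp::read.asciigrid}; values equal to the nodata sentinel come back
#' as `NA`. GeoTIFF is not available in this build (no GDAL bindings) and
#' requesting it raises an informative error.
#'
#' @param path file path.
#' @param format `"esri_ascii"` (default) or `"geotiff"` (unsupported).
#' @return an `nm_grid`; row 1 is the northernmost row.
#' @export
read_grid <- function(path, format = c("esri_ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff") {
    stop("GeoTIFF support requires GDAL bindings, which this build does not ",
         "include; convert to ESRI ASCII (.asc) and use format = 'esri_ascii'.",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr <- read_asc_header(path)
  sg <- tryCatch(sp::read.asciigrid(path, colname = "z"),
                 error = function(e) stop(sprintf(
                   "cannot parse '%s' as ESRI ASCII grid: %s",
                   path, conditionMessage(e)), call. = FALSE))
  # sp stores the layer x-major; transpose back to row-1-north orientation
  m <- t(as.matrix(sg))
  grid_create(m,
              origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
              cell_size = hdr$cellsize,
              nodata = hdr$nodata)
}

# minimal header scan; sp hides the nodata sentinel so recover it here
read_asc_header <- function(path) {
  ln <- readLines(path, n = 6L)
  kv <- lapply(strsplit(trimws(ln), "\\s+"), function(p) p[1:2])
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, keys)
  if (length(miss)) {
    stop(sprintf("malformed ESRI ASCII header in '%s': missing field(s) %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(vals[match(need, keys)]))) {
    bad <- need[is.na(vals[match(need, keys)])][1]
    stop(sprintf("malformed ESRI ASCII header in '%s': field '%s' is not numeric",
                 path, bad), call. = FALSE)
  }
  nodata <- if ("nodata_value" %in% keys) vals[match("nodata_value", keys)] else -9999
  list(ncols = vals[match("ncols", keys)], nrows = vals[match("nrows", keys)],
       xllcorner = vals[match("xllcorner", keys)],
       yllcorner = vals[match("yllcorner", keys)],
       cellsize = vals[match("cellsize", keys)], nodata = nodata)
}

#' Write a single-layer raster to disk
#'
#' Writes ESRI ASCII via \code{sp::write.asciigrid}. `NA` cells are written
#' as the grid's nodata sentinel. Values round-trip through [read_grid()] to
#' double precision (15 significant digits).
#'
#' @param grid an `nm_grid`.
#' @param path destination file path.
#' @param format only `"esri_ascii"` is supported.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("esri_ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff") {
    stop("GeoTIFF support requires GDAL bindings, which this build does not ",
         "include; use format = 'esri_ascii'.", call. = FALSE)
  }
  stopifnot(is_grid(grid))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  # sp wants cell-centre offset of the SW cell and an x-major value vector
  topo <- sp::GridTopology(
    cellcentre.offset = c(grid$origin[1] + cs / 2,
                          grid$origin[2] - nr * cs + cs / 2),
    cellsize = c(cs, cs), cells.dim = c(nc, nr))
  sg <- sp::SpatialGridDataFrame(topo, data.frame(z = as.vector(t(grid$values))))
  ok <- tryCatch({
    sp::write.asciigrid(sg, path, na.value = grid$nodata)
    TRUE
  }, error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                      conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' Block-mean aggregation to a coarser resolution
#'
#' Each output cell is the mean of its `factor` x `factor` block of input
#' cells, ignoring nodata; a block that is entirely nodata yields nodata.
#' Ragged edge blocks (when the shape does not divide evenly) use whatever
#' cells are available. `factor = 1` returns the grid unchanged.
#'
#' @param grid an `nm_grid`.
#' @param factor positive integer aggregation factor.
#' @return an `nm_grid` with `cell_size * factor`.
#' @export
aggregate_grid <- function(grid, factor) {
  stopifnot(is_grid(grid))
  if (!(is.numeric(factor) && length(factor) == 1 && factor >= 1 &&
        factor == round(factor))) {
    stop("'factor' must be a positive integer", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  orow <- ceiling(nr / factor); ocol <- ceiling(nc / factor)
  ridx <- rep(seq_len(orow), each = factor)[seq_len(nr)]
  cidx <- rep(seq_len(ocol), each = factor)[seq_len(nc)]
  grp <- outer(ridx, cidx, function(r, c) (c - 1L) * orow + r)
  sums <- tapply(as.vector(v), as.vector(grp), function(z) {
    z <- z[!is.na(z)]
    if (length(z)) mean(z) else NA_real_
  })
  out <- matrix(NA_real_, orow, ocol)
  out[as.integer(names(sums))] <- as.numeric(sums)
  grid_create(out, origin = grid$origin, cell_size = grid$cell_size * factor,
              nodata = grid$nodata, crs_label = grid$crs_label)
}

#' Read / write point sets
#'
#' Point sets travel as delimited text with header `id,x,y` (UTF-8, "."
#' decimal). The returned data.frame may also carry `role`, `period` and
#' `seed` attributes when produced by the sampling functions.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `x`, `y`.
#' @export
read_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("point file must have header id,x,y: ", path, call. = FALSE)
  }
  df[need]
}

#' @rdname read_points
#' @param points data.frame with columns `id`, `x`, `y`.
#' @export
write_points <- function(points, path) {
  utils::write.csv(points[c("id", "x", "y")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
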