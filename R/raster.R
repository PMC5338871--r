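#' Bathymetry raster
#'
#' A regular grid of seafloor depth in meters (positive down), stored with
#' row 1 as the northernmost row, matching Esri ASCII grid row order. All
#' terrain derivatives in the package are computed from this container.
#'
#' @param values numeric matrix of depths (m, positive down); `NA` = nodata.
#' @param cell_size cell edge length in meters (grid must be projected).
#' @param origin length-2 numeric, `c(x, y)` of the lower-left corner.
#' @param nodata nodata marker used when writing to disk.
#' @return an object of class `bathy_grid`.
#' @export
bathy_grid <- function(values, cell_size, origin = c(0, 0), nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stopf("`cell_size` must be a single positive number")
  }
  if (any(values[!is.na(values)] < 0)) {
    stopf("depths must be >= 0 (positive down); found negative values")
  }
  structure(
    list(values = values, cell_size = cell_size,
         origin = as.numeric(origin), nodata = nodata),
    class = "bathy_grid"
  )
}

#' @export
print.bathy_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<bathy_grid> %d x %d cells, %.6g m resolution\n",
              nrow(v), ncol(v), x$cell_size))
  cat(sprintf("  origin (lower-left): %.6g, %.6g\n", x$origin[1], x$origin[2]))
  cat(sprintf("  depth range: %.6g - %.6g m (%d nodata cells)\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.bathy_grid <- function(x) dim(x$values)

# x coordinate of column centers / y coordinate of row centers (row 1 = north)
grid_x <- function(g) g$origin[1] + (seq_len(ncol(g$values)) - 0.5) * g$cell_size
grid_y <- function(g) g$origin[2] + (nrow(g$values) - seq_len(nrow(g$values)) + 0.5) * g$cell_size

# Map projected (x, y) to (row, col); NA when outside the grid extent.
cell_of_xy <- function(g, x, y) {
  nr <- nrow(g$values); nc <- ncol(g$values); cs <- g$cell_size
  j <- floor((x - g$origin[1]) / cs) + 1
  i <- nr - floor((y - g$origin[2]) / cs)
  bad <- !is.finite(j) | !is.finite(i) | j < 1 | j > nc | i < 1 | i > nr
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  cbind(row = as.integer(i), col = as.integer(j))
}

#' Read an Esri ASCII grid as a bathymetry raster
#'
#' Values in the file are interpreted as depth in meters, positive down.
#'
#' @param path file path.
#' @return a [bathy_grid()].
#' @export
read_ascii_grid <- function(path) {
  head_lines <- readLines(path, n = 6)
  kv <- lapply(strsplit(trimws(head_lines), "\\s+"), function(p) {
    list(key = tolower(p[1]), value = as.numeric(p[2]))
  })
  keys <- vapply(kv, `[[`, "", "key")
  vals <- vapply(kv, `[[`, 0, "value")
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% keys)) stopf("not an Esri ASCII grid: %s", path)
  get <- function(k, default = NA) if (k %in% keys) vals[match(k, keys)] else default
  nc <- as.integer(get("ncols")); nr <- as.integer(get("nrows"))
  cs <- get("cellsize")
  xll <- get("xllcorner", get("xllcenter", 0) - cs / 2)
  yll <- get("yllcorner", get("yllcenter", 0) - cs / 2)
  nodata <- get("nodata_value", -9999)
  n_header <- sum(keys %in% c("ncols", "nrows", "xllcorner", "xllcenter",
                              "yllcorner", "yllcenter", "cellsize",
                              "nodata_value"))
  vals_num <- scan(path, skip = n_header, quiet = TRUE)
  if (length(vals_num) != nr * nc) {
    stopf("expected %d values, found %d in %s", nr * nc, length(vals_num), path)
  }
  m <- matrix(vals_num, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  bathy_grid(m, cell_size = cs, origin = c(xll, yll), nodata = nodata)
}

#' Write a bathymetry raster as an Esri ASCII grid
#' @param grid a [bathy_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  ), con)
  apply(v, 1, function(row) writeLines(paste(format(row, trim = TRUE), collapse = " "), con))
  invisible(path)
}
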