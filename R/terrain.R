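# Terrain derivatives of a depth raster. All derivatives are computed on
# elevation = -depth, so that ridges (locally shallow seafloor) have positive
# bathymetric position index and domes have positive (convex) curvature.

# Shift a matrix by (di, dj); vacated cells become NA.
shift_matrix <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  ri <- max(1, 1 + di):min(nr, nr + di)
  rj <- max(1, 1 + dj):min(nc, nc + dj)
  if (length(ri) < 1 || length(rj) < 1) return(out)
  out[ri, rj] <- m[ri - di, rj - dj]
  out
}

#' Bathymetric position index
#'
#' BPI of a cell is its elevation minus the mean elevation over an annulus of
#' surrounding cells: negative values are valleys, zero is flat, positive
#' values are ridges. Annulus membership uses center-to-center Euclidean
#' distance in cell units, with cells at distance `d` included when
#' `inner_cells < d <= outer_cells`. Nodata cells and cells beyond the grid
#' edge are excluded from the annulus mean. Values are kept as floating
#' point; set `round_integer = TRUE` for parity with desktop tools that
#' round BPI to integers.
#'
#' @param grid a [bathy_grid()] of depths (m, positive down).
#' @param inner_cells inner annulus radius in cells (default 1).
#' @param outer_cells outer annulus radius in cells (18 for the broad scale,
#'   9 for the fine scale at 90 m resolution).
#' @param round_integer round the result to integers (default `FALSE`).
#' @return numeric matrix of BPI values (m), same shape as the grid.
#' @export
compute_bpi <- function(grid, inner_cells = 1, outer_cells, round_integer = FALSE) {
  stopifnot(inherits(grid, "bathy_grid"))
  if (!(inner_cells >= 0 && inner_cells < outer_cells)) {
    stopf("need 0 <= inner_cells < outer_cells")
  }
  elev <- -grid$values
  r <- ceiling(outer_cells)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  d <- sqrt(offs$di^2 + offs$dj^2)
  offs <- offs[d > inner_cells & d <= outer_cells, , drop = FALSE]
  if (nrow(offs) == 0) stopf("annulus is empty for inner %s, outer %s",
                             inner_cells, outer_cells)
  acc <- matrix(0, nrow(elev), ncol(elev))
  cnt <- matrix(0L, nrow(elev), ncol(elev))
  for (k in seq_len(nrow(offs))) {
    s <- shift_matrix(elev, offs$di[k], offs$dj[k])
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + s[ok]
    cnt <- cnt + ok
  }
  mean_ann <- acc / cnt
  mean_ann[cnt == 0] <- NA
  bpi <- elev - mean_ann
  if (round_integer) bpi <- round(bpi)
  bpi
}

#' Slope, aspect and curvature of a depth raster
#'
#' Slope and aspect by Horn's 3x3 weighted finite differences on elevation;
#' curvature from the 3x3 quadratic surface fit (Zevenbergen-Thorne), as
#' general curvature: the negative Laplacian of elevation, in units of
#' 1/100 m, so that convex (dome-like) cells are positive. Aspect is the
#' down-gradient direction in degrees clockwise from north and is nodata
#' where the surface is flat. Border cells and cells with nodata neighbors
#' are nodata.
#'
#' @param grid a [bathy_grid()] at least 3x3.
#' @return list of matrices `slope` (degrees), `aspect` (degrees), and
#'   `curvature` (1/100 m).
#' @export
compute_slope_aspect_curvature <- function(grid) {
  stopifnot(inherits(grid, "bathy_grid"))
  z <- -grid$values
  if (nrow(z) < 3 || ncol(z) < 3) stopf("grid must be at least 3x3")
  L <- grid$cell_size
  # 3x3 neighborhood, row 1 = north:
  #   nw n ne
  #   w  c e
  #   sw s se
  nw <- shift_matrix(z,  1,  1); n_ <- shift_matrix(z,  1, 0); ne <- shift_matrix(z,  1, -1)
  w_ <- shift_matrix(z,  0,  1);                                e_ <- shift_matrix(z,  0, -1)
  sw <- shift_matrix(z, -1,  1); s_ <- shift_matrix(z, -1, 0); se <- shift_matrix(z, -1, -1)
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * L)  # d(elev)/dx, east+
  gy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * L)  # d(elev)/dy, north+
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360  # down-gradient azimuth
  flat <- !is.na(gx) & gx == 0 & gy == 0
  aspect[flat] <- NA
  # Zevenbergen-Thorne: D = zxx/2, E = zyy/2 from central differences
  D <- ((w_ + e_) / 2 - z) / L^2
  E <- ((n_ + s_) / 2 - z) / L^2
  curvature <- -2 * (D + E) * 100
  list(slope = slope, aspect = aspect, curvature = curvature)
}

#' Terrain stack: all derivative layers of a depth raster
#'
#' Computes slope, aspect, curvature and broad- and fine-scale BPI, aligned
#' with the source grid.
#'
#' @param grid a [bathy_grid()].
#' @param inner_cells inner annulus radius for BPI (cells).
#' @param outer_broad,outer_fine outer annulus radii (cells) for the broad-
#'   and fine-scale BPI (defaults 18 and 9, the scales used with 90 m cells).
#' @param round_bpi round BPI layers to integers (default `FALSE`).
#' @return an object of class `terrain_stack`: list of matrices `slope`,
#'   `aspect`, `curvature`, `bpi_broad`, `bpi_fine` plus grid georeferencing.
#' @export
terrain_stack <- function(grid, inner_cells = 1, outer_broad = 18,
                          outer_fine = 9, round_bpi = FALSE) {
  sac <- compute_slope_aspect_curvature(grid)
  structure(
    list(
      layers = list(
        slope = sac$slope,
        aspect = sac$aspect,
        curvature = sac$curvature,
        bpi_broad = compute_bpi(grid, inner_cells, outer_broad, round_bpi),
        bpi_fine = compute_bpi(grid, inner_cells, outer_fine, round_bpi)
      ),
      cell_size = grid$cell_size,
      origin = grid$origin,
      dim = dim(grid$values)
    ),
    class = "terrain_stack"
  )
}

#' @export
print.terrain_stack <- function(x, ...) {
  cat(sprintf("<terrain_stack> %d x %d cells, %.6g m resolution\n",
              x$dim[1], x$dim[2], x$cell_size))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

# Circular mean of angles in degrees; NA if no finite input.
circular_mean_deg <- function(a) {
  a <- a[!is.na(a)]
  if (length(a) == 0) return(NA_real_)
  r <- a * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}

#' Summarize terrain layers within circular buffers around points
#'
#' For each point, the mean and maximum of every terrain layer over all cells
#' whose centers lie within `radius` meters of the point. The default radius
#' 381.8 m is the hypotenuse of a 3x3 block of 90 m cells; use 127 m for
#' fine (multibeam-scale) layers. Aspect means use circular (vector)
#' averaging, since arithmetic means of angles are meaningless; flat
#' (nodata-aspect) cells are excluded. Points covering zero non-nodata cells
#' are returned with `missing = TRUE` rather than raising an error.
#'
#' @param stack a [terrain_stack()].
#' @param points data.frame with projected coordinates `x`, `y` (m), and
#'   optionally an `id` column.
#' @param radius buffer radius in meters (default 381.8).
#' @return data.frame with one row per point: `id`, `n_cells`, `missing`,
#'   and `mean_<layer>` / `max_<layer>` for each layer.
#' @export
summarize_buffer <- function(stack, points, radius = 381.8) {
  stopifnot(inherits(stack, "terrain_stack"))
  if (radius <= 0) stopf("radius must be > 0")
  nr <- stack$dim[1]; nc <- stack$dim[2]; cs <- stack$cell_size
  xs <- stack$origin[1] + (seq_len(nc) - 0.5) * cs
  ys <- stack$origin[2] + (nr - seq_len(nr) + 0.5) * cs
  ids <- points$id %||% seq_len(nrow(points))
  out <- vector("list", nrow(points))
  rcell <- ceiling(radius / cs) + 1L
  for (p in seq_len(nrow(points))) {
    px <- points$x[p]; py <- points$y[p]
    jc <- round((px - stack$origin[1]) / cs + 0.5)
    ic <- nr - round((py - stack$origin[2]) / cs - 0.5)
    jj <- max(1, jc - rcell):min(nc, jc + rcell)
    ii <- max(1, ic - rcell):min(nr, ic + rcell)
    if (jc + rcell < 1 || jc - rcell > nc || ic + rcell < 1 || ic - rcell > nr) {
      ii <- integer(0); jj <- integer(0)
    }
    sel <- expand.grid(i = ii, j = jj)
    if (nrow(sel)) {
      d2 <- (xs[sel$j] - px)^2 + (ys[sel$i] - py)^2
      sel <- sel[d2 <= radius^2, , drop = FALSE]
    }
    row <- list(id = ids[p], n_cells = nrow(sel))
    for (nm in names(stack$layers)) {
      vals <- stack$layers[[nm]][cbind(sel$i, sel$j)]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) {
        row[[paste0("mean_", nm)]] <- NA_real_
        row[[paste0("max_", nm)]] <- NA_real_
      } else {
        row[[paste0("mean_", nm)]] <-
          if (nm == "aspect") circular_mean_deg(vals) else mean(vals)
        row[[paste0("max_", nm)]] <- max(vals)
      }
    }
    out[[p]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$missing <- res$n_cells == 0 | is.na(res$mean_slope)
  res
}
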