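# Peak-spawning prediction maps over a raster grid, Z-score conversion, and
# scoring of external-validation points.

# Block-aggregate a matrix by an integer factor; trailing partial blocks are
# dropped. fun is applied to each agg x agg block's non-NA values.
block_aggregate <- function(m, agg, fun) {
  nr <- nrow(m) %/% agg; nc <- ncol(m) %/% agg
  out <- matrix(NA_real_, nr, nc)
  for (bi in seq_len(nr)) {
    rows <- (bi - 1) * agg + seq_len(agg)
    for (bj in seq_len(nc)) {
      v <- m[rows, (bj - 1) * agg + seq_len(agg)]
      v <- v[!is.na(v)]
      if (length(v)) out[bi, bj] <- fun(v)
    }
  }
  out
}

#' Build gridded design covariates for prediction maps
#'
#' Aggregates the terrain stack and depth raster to coarser prediction cells
#' (3x3 block aggregation by default, e.g. 90 m terrain to 270 m prediction
#' cells): block means for the `mean_*` statistics (circular for aspect),
#' block maxima for the `max_*` statistics, block-mean depth. Cells deeper
#' than `max_depth`, on land, or without terrain coverage are nodata.
#' Latitude is taken from the cell-center northing through the domain
#' reference point.
#'
#' @param bathy a [bathy_grid()].
#' @param terrain an aligned [terrain_stack()].
#' @param agg block aggregation factor (default 3).
#' @param max_depth seaward prediction limit in meters (default 200).
#' @param ref `c(lon, lat)` reference anchoring the projected grid.
#' @return object of class `grid_covariates`: list with `rows` (one row per
#'   valid cell: `cell`, `row`, `col`, `x`, `y`, `lon`, `lat`, `depth_m`,
#'   and `mean_*`/`max_*` terrain columns), `dim`, `cell_size`, `origin`,
#'   `valid` (logical matrix).
#' @export
build_grid_covariates <- function(bathy, terrain, agg = 3, max_depth = 200,
                                  ref = c(-79, 32)) {
  stopifnot(inherits(bathy, "bathy_grid"), inherits(terrain, "terrain_stack"))
  if (!identical(dim(bathy$values), terrain$dim)) {
    stopf("terrain stack is not aligned with the bathymetry grid")
  }
  depth <- block_aggregate(bathy$values, agg, mean)
  covs <- list()
  for (nm in names(terrain$layers)) {
    m <- terrain$layers[[nm]]
    covs[[paste0("mean_", nm)]] <- if (nm == "aspect") {
      block_aggregate(m, agg, circular_mean_deg)
    } else {
      block_aggregate(m, agg, mean)
    }
    covs[[paste0("max_", nm)]] <- block_aggregate(m, agg, max)
  }
  nr <- nrow(depth); nc <- ncol(depth)
  cs <- bathy$cell_size * agg
  xs <- bathy$origin[1] + (rep(seq_len(nc), each = nr) - 0.5) * cs
  ys <- bathy$origin[2] + (nr - rep(seq_len(nr), nc) + 0.5) * cs
  ll <- xy_to_lonlat(xs, ys, ref)
  valid <- !is.na(depth) & depth > 0 & depth <= max_depth &
    !is.na(covs$mean_slope)
  rows <- data.frame(
    cell = which(as.vector(valid)),
    row = rep(seq_len(nr), nc)[as.vector(valid)],
    col = rep(seq_len(nc), each = nr)[as.vector(valid)],
    x = xs[as.vector(valid)], y = ys[as.vector(valid)],
    lon = ll$lon[as.vector(valid)], lat = ll$lat[as.vector(valid)],
    depth_m = as.vector(depth)[as.vector(valid)]
  )
  for (nm in names(covs)) rows[[nm]] <- as.vector(covs[[nm]])[as.vector(valid)]
  structure(list(rows = rows, dim = c(nr, nc), cell_size = cs,
                 origin = bathy$origin, valid = valid, ref = ref),
            class = "grid_covariates")
}

# Peak settings from a fitted model: the factor level / continuous value
# maximizing the fitted linear predictor, per temporal term.
auto_peak <- function(fit) {
  peak <- list()
  beta <- fit$coefficients
  if ("month" %in% fit$terms) {
    levs <- levels(fit$data$month)
    contrib <- vapply(levs, function(l) {
      nm <- paste0("month", l)
      if (nm %in% names(beta)) unname(beta[nm]) else 0
    }, 0)
    peak$month <- levs[which.max(contrib)]
  }
  if ("temperature" %in% fit$terms) {
    rng <- fit$meta$cont_range$temperature %||% range(fit$data$temperature)
    peak$temperature <- if (beta["temperature"] >= 0) rng[2] else rng[1]
  }
  if ("lunar" %in% fit$terms) {
    if (is.factor(fit$data$lunar)) {
      levs <- levels(fit$data$lunar)
      contrib <- vapply(levs, function(l) {
        nm <- paste0("lunar", l)
        if (nm %in% names(beta)) unname(beta[nm]) else 0
      }, 0)
      peak$lunar <- levs[which.max(contrib)]
    } else {
      peak$lunar <- if (beta["lunar"] >= 0) 1 else -1
    }
  }
  peak
}

#' Peak-spawning probability map
#'
#' Predicts the probability of encountering a spawning-condition female in
#' every valid grid cell, with month, temperature and/or lunar phase fixed
#' at their peak values — by default the level or value maximizing the
#' fitted linear predictor; supply `peak` to override (e.g. a published
#' species-specific peak). Probabilities come with delta-method standard
#' errors and are converted to Z-scores over the non-nodata domain.
#'
#' @param fit a `spawn_fit`.
#' @param grid_cov a [build_grid_covariates()] result.
#' @param peak optional named list with any of `month` (label like "Jun"),
#'   `temperature` (deg C), `lunar` (value in `[-1, 1]` or bin label).
#' @param zscore standardize to Z-scores (default `TRUE`).
#' @return object of class `prediction_grid`: matrices `probability`, `se`,
#'   `z`; `peak` settings used; grid georeferencing.
#' @export
predict_map <- function(fit, grid_cov, peak = NULL, zscore = TRUE) {
  stopifnot(inherits(fit, "spawn_fit"), inherits(grid_cov, "grid_covariates"))
  peak <- utils::modifyList(auto_peak(fit), as.list(peak %||% list()))
  nd <- grid_cov$rows
  if (!is.null(peak$month)) nd$month <- peak$month
  if (!is.null(peak$temperature)) nd$temperature <- peak$temperature
  if (!is.null(peak$lunar)) nd$lunar <- peak$lunar
  pr <- suppressWarnings(predict(fit, newdata = nd, se.fit = TRUE))
  nr <- grid_cov$dim[1]; nc <- grid_cov$dim[2]
  prob <- se <- matrix(NA_real_, nr, nc)
  idx <- cbind(nd$row, nd$col)
  prob[idx] <- pr$fit
  se[idx] <- pr$se.fit
  out <- structure(list(probability = prob, se = se, z = NULL, peak = peak,
                        dim = c(nr, nc), cell_size = grid_cov$cell_size,
                        origin = grid_cov$origin, ref = grid_cov$ref,
                        terms = fit$terms),
                   class = "prediction_grid")
  if (zscore) out <- zscore_grid(out) else out$z <- prob * NA
  out
}

#' Convert a prediction grid to Z-scores
#'
#' `z = (p - mean(p)) / sd(p)` over non-nodata cells, using the population
#' SD. A zero-variance grid yields all-zero Z with a warning.
#'
#' @param grid a `prediction_grid`.
#' @return the grid with its `z` component (re)computed.
#' @export
zscore_grid <- function(grid) {
  stopifnot(inherits(grid, "prediction_grid"))
  p <- grid$probability
  v <- p[!is.na(p)]
  if (length(v) < 2) stopf("need >= 2 non-nodata cells")
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  z <- p * NA
  if (sdv == 0) {
    warnf("zero variance across the grid; Z set to 0")
    z[!is.na(p)] <- 0
  } else {
    z <- (p - mu) / sdv
  }
  grid$z <- z
  grid
}

#' @export
print.prediction_grid <- function(x, ...) {
  p <- x$probability
  cat(sprintf("<prediction_grid> %d x %d cells (%d valid), %.6g m resolution\n",
              x$dim[1], x$dim[2], sum(!is.na(p)), x$cell_size))
  cat("  peak settings:", paste(names(x$peak), unlist(x$peak), sep = "=",
                                collapse = ", "), "\n")
  cat(sprintf("  probability range: %.4f - %.4f\n",
              min(p, na.rm = TRUE), max(p, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.prediction_grid <- function(x, what = c("probability", "se", "z"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  # flip to plot north up
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  main = paste("peak-spawning", what), axes = FALSE, ...)
  invisible(x)
}

#' Score external-validation points against a prediction grid
#'
#' Attaches the underlying Z-score to each independent validation point
#' (fisher interviews, fishery-dependent collections, ...). A point supports
#' the model when its Z-score is strictly positive, i.e. its predicted
#' probability exceeds the domain mean. Points outside the grid or on
#' nodata cells are flagged and excluded from the support fractions.
#'
#' @param grid a `prediction_grid`.
#' @param points data.frame with `lon`/`lat` (or projected `x`/`y`) and
#'   optional `id` and `source` columns.
#' @return object of class `validation_summary`: `points` (with `z_score`,
#'   `support`, `in_grid`) and `summary` (per source and overall: `n`,
#'   `n_support`, `support_fraction`).
#' @export
external_validation <- function(grid, points) {
  stopifnot(inherits(grid, "prediction_grid"))
  pts <- points
  if (is.null(pts$x) || is.null(pts$y)) {
    xy <- lonlat_to_xy(pts$lon, pts$lat, grid$ref)
    pts$x <- xy$x; pts$y <- xy$y
  }
  pts$id <- pts$id %||% seq_len(nrow(pts))
  pts$source <- pts$source %||% "all"
  g <- list(values = grid$z, cell_size = grid$cell_size, origin = grid$origin)
  rc <- cell_of_xy(g, pts$x, pts$y)
  z <- rep(NA_real_, nrow(pts))
  ok <- !is.na(rc[, 1])
  z[ok] <- grid$z[rc[ok, , drop = FALSE]]
  pts$z_score <- z
  pts$in_grid <- !is.na(z)
  pts$support <- !is.na(z) & z > 0
  if (!any(pts$in_grid)) warnf("all validation points fall outside the grid")
  per_source <- function(d) {
    d <- d[d$in_grid, , drop = FALSE]
    data.frame(n = nrow(d), n_support = sum(d$support),
               support_fraction = if (nrow(d)) mean(d$support) else NA_real_)
  }
  srcs <- unique(pts$source)
  summ <- do.call(rbind, lapply(srcs, function(s) {
    cbind(data.frame(source = s), per_source(pts[pts$source == s, , drop = FALSE]))
  }))
  summ <- rbind(summ, cbind(data.frame(source = "overall"), per_source(pts)))
  structure(list(points = pts, summary = summ), class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("<validation_summary>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
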