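test_that("grid covariates aggregate 3x3 blocks and respect the depth limit", {
  set.seed(1)
  m <- matrix(runif(81, 20, 120), 9, 9)
  m[1, 1] <- 250  # beyond the 200 m prediction limit
  g <- bathy_grid(m, cell_size = 90)
  st <- terrain_stack(g, outer_broad = 3, outer_fine = 2)
  gc <- build_grid_covariates(g, st, agg = 3, max_depth = 200)
  expect_equal(gc$dim, c(3, 3))
  # block containing the 250 m cell: depth mean may stay under 200, but a
  # block made deep enough must drop out
  m2 <- m; m2[1:3, 1:3] <- 250
  gc2 <- build_grid_covariates(bathy_grid(m2, 90), terrain_stack(bathy_grid(m2, 90),
                               outer_broad = 3, outer_fine = 2), agg = 3)
  expect_false(1 %in% gc2$rows$cell[gc2$rows$row == 1 & gc2$rows$col == 1])

  # covariates equal the brute-force mean over the nine member cells
  for (rr in 1:nrow(gc$rows)) {
    bi <- gc$rows$row[rr]; bj <- gc$rows$col[rr]
    cells <- st$layers$slope[(bi - 1) * 3 + 1:3, (bj - 1) * 3 + 1:3]
    expect_equal(gc$rows$mean_slope[rr], mean(cells[!is.na(cells)]),
                 tolerance = 1e-12)
    dcells <- m[(bi - 1) * 3 + 1:3, (bj - 1) * 3 + 1:3]
    expect_equal(gc$rows$depth_m[rr], mean(dcells), tolerance = 1e-12)
  }
})

test_that("peak settings are auto-selected by the fitted linear predictor", {
  w <- make_world(seed = 91, n_years = 3, n_sets_per_year = 60)
  d <- build_design(w$survey$records, terms = c("month", "temperature", "lunar"))
  fit <- spawn_glmm(d, nAGQ = 1)
  peak <- auto_peak(fit)
  # model with month: the level with the largest coefficient wins
  beta <- coef(fit)
  mcoef <- vapply(levels(fit$data$month), function(l) {
    nm <- paste0("month", l); if (nm %in% names(beta)) unname(beta[nm]) else 0
  }, 0)
  expect_equal(peak$month, names(which.max(mcoef)))
  expect_equal(peak$lunar, if (unname(beta["lunar"]) >= 0) 1 else -1)
  expect_equal(peak$temperature,
               if (unname(beta["temperature"]) >= 0) max(d$data$temperature)
               else min(d$data$temperature))
})

test_that("probability maps equal an independent linear-algebra recomputation", {
  w <- make_world(seed = 92, n_years = 3, n_sets_per_year = 40)
  d <- build_design(w$survey$records, terms = c("temperature", "mean_bpi_broad"),
                    buffers = w$buffers)
  fit <- spawn_glmm(d, nAGQ = 1)
  gc <- build_grid_covariates(w$bathy, w$terrain, ref = w$cfg$ref)
  pm <- predict_map(fit, gc, zscore = TRUE)
  # independent path: bin the grid covariate by stored edges, build the
  # indicator matrix by hand, apply inverse logit
  rows <- gc$rows
  peakT <- pm$peak$temperature
  edges <- fit$meta$edges$mean_bpi_broad
  bin <- findInterval(rows$mean_bpi_broad, edges) + 1
  levs <- levels(fit$data$mean_bpi_broad)
  lab <- paste0("bin", bin)
  lab[!lab %in% levs] <- levs[1]
  X <- cbind(1, peakT, vapply(levs[-1], function(l) as.numeric(lab == l), numeric(nrow(rows))))
  eta <- drop(X %*% coef(fit)[c("(Intercept)", "temperature", paste0("mean_bpi_broad", levs[-1]))])
  p_oracle <- 1 / (1 + exp(-eta))
  expect_equal(pm$probability[cbind(rows$row, rows$col)], p_oracle, tolerance = 1e-12)
  # constant covariates produce a constant map
  gc_const <- gc
  gc_const$rows$mean_bpi_broad <- 0.5
  pm_const <- suppressWarnings(predict_map(fit, gc_const, zscore = FALSE))
  pvals <- pm_const$probability[!is.na(pm_const$probability)]
  expect_lt(diff(range(pvals)), 1e-12)
})

test_that("Z-scores standardize exactly and handle degenerate grids", {
  # two cells {0.2, 0.4} -> z = {-1, +1} with the population SD
  pg <- structure(list(probability = matrix(c(0.2, 0.4), 1, 2),
                       se = matrix(0, 1, 2), z = NULL, peak = list(),
                       dim = c(1, 2), cell_size = 270, origin = c(0, 0),
                       ref = c(-79, 32), terms = character(0)),
                  class = "prediction_grid")
  pg <- zscore_grid(pg)
  expect_equal(as.vector(pg$z), c(-1, 1), tolerance = 1e-12)

  set.seed(2)
  m <- matrix(runif(100), 10, 10)
  m[c(3, 14)] <- NA
  pgr <- structure(list(probability = m, se = m * 0, z = NULL, peak = list(),
                        dim = c(10, 10), cell_size = 270, origin = c(0, 0),
                        ref = c(-79, 32), terms = character(0)),
                   class = "prediction_grid")
  pgr <- zscore_grid(pgr)
  zv <- pgr$z[!is.na(pgr$z)]
  expect_lt(abs(mean(zv)), 1e-6)
  expect_lt(abs(sqrt(mean(zv^2)) - 1), 1e-6)
  # nodata exactly where the probability is nodata
  expect_identical(is.na(pgr$z), is.na(m))
  # affine rescaling of probabilities leaves z unchanged
  pga <- pgr; pga$probability <- 0.3 * m + 0.2
  pga <- zscore_grid(pga)
  expect_equal(pga$z, pgr$z, tolerance = 1e-9)
  # constant grid: all-zero z with a warning
  pgc <- pgr; pgc$probability[] <- 0.5
  expect_warning(pgc <- zscore_grid(pgc), "zero variance")
  expect_true(all(pgc$z[!is.na(pgc$z)] == 0))
})

test_that("external validation scores points by strict positive Z support", {
  set.seed(3)
  m <- matrix(runif(144, 0.1, 0.9), 12, 12)
  pg <- structure(list(probability = m, se = m * 0, z = NULL, peak = list(),
                       dim = c(12, 12), cell_size = 100, origin = c(0, 0),
                       ref = c(-79, 32), terms = character(0)),
                  class = "prediction_grid")
  pg <- zscore_grid(pg)
  # all points at the maximum-z cell: support fraction 1
  best <- which(pg$z == max(pg$z), arr.ind = TRUE)
  bx <- (best[1, 2] - 0.5) * 100
  by <- (12 - best[1, 1] + 0.5) * 100
  xy <- xy_to_lonlat(rep(bx, 5), rep(by, 5), pg$ref)
  ev <- external_validation(pg, data.frame(lon = xy$lon, lat = xy$lat))
  expect_equal(ev$summary$support_fraction[ev$summary$source == "overall"], 1.0)

  # uniform points: support fraction tracks the fraction of positive-z cells
  n <- 4000
  ii <- sample(1:12, n, TRUE); jj <- sample(1:12, n, TRUE)
  px <- (jj - 0.5) * 100; py <- (12 - ii + 0.5) * 100
  ll <- xy_to_lonlat(px, py, pg$ref)
  ev2 <- external_validation(pg, data.frame(lon = ll$lon, lat = ll$lat))
  frac_cells <- mean(pg$z > 0)
  got <- ev2$summary$support_fraction[ev2$summary$source == "overall"]
  expect_lt(abs(got - frac_cells), 3 * sqrt(frac_cells * (1 - frac_cells) / n))

  # a point exactly at z = 0 is not supportive; off-grid points are flagged
  pg0 <- pg; pg0$z[1, 1] <- 0
  x0 <- xy_to_lonlat(0.5 * 100, 11.5 * 100, pg$ref)
  ev3 <- external_validation(pg0, data.frame(lon = x0$lon, lat = x0$lat))
  expect_false(ev3$points$support[1])
  far <- xy_to_lonlat(1e6, 1e6, pg$ref)
  expect_warning(ev4 <- external_validation(pg, data.frame(lon = far$lon, lat = far$lat)),
                 "outside")
  expect_false(ev4$points$in_grid[1])
})

test_that("true high-probability sites score higher Z than random sites", {
  cfg0 <- sim_config(seed = 1, n_years = 3, n_sets_per_year = 80,
                     grid_rows = 48, grid_cols = 64,
                     true_coefficients = c(intercept = -1, bpi = 0.4),
                     random_intercept_sd = 0.2)
  b <- generate_bathymetry(cfg0)
  tr <- terrain_stack(b, outer_broad = 6, outer_fine = 3)
  wins <- 0
  n_rep <- 20
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = 100 + s, n_years = 3, n_sets_per_year = 80,
                      grid_rows = 48, grid_cols = 64,
                      true_coefficients = c(intercept = -1, bpi = 0.4),
                      random_intercept_sd = 0.2)
    sv <- generate_survey(cfg, b, tr)
    xy <- lonlat_to_xy(sv$records$lon, sv$records$lat, cfg$ref)
    pts <- unique(data.frame(id = sv$records$set_id, x = xy$x, y = xy$y))
    buf <- summarize_buffer(tr, pts)
    d <- build_design(sv$records, terms = "mean_bpi_broad", buffers = buf)
    fit <- spawn_glmm(d, nAGQ = 1)
    gc <- build_grid_covariates(b, tr, ref = cfg$ref)
    pm <- suppressWarnings(predict_map(fit, gc))
    # true high-probability sites: top-decile generative linear predictor
    eta_true <- 0.4 * tr$layers$bpi_broad
    agg <- block_aggregate(eta_true, 3, mean)
    hi <- which(agg >= quantile(agg, 0.9, na.rm = TRUE) & !is.na(pm$z))
    zs <- pm$z[hi]
    if (mean(zs, na.rm = TRUE) > mean(pm$z, na.rm = TRUE)) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.9 * n_rep))
})
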