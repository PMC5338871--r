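test_that("BPI is zero on flat seafloor and positive on a shoal", {
  flat <- bathy_grid(matrix(50, 12, 12), cell_size = 90)
  bpi <- compute_bpi(flat, 1, 3)
  expect_true(all(abs(bpi) < 1e-12))

  shoal <- matrix(80, 12, 12)
  shoal[6, 6] <- 40  # locally shallow cell = ridge
  bpi <- compute_bpi(bathy_grid(shoal, 90), 1, 3)
  expect_gt(bpi[6, 6], 0)
})

test_that("BPI matches the brute-force annulus oracle on a random grid", {
  set.seed(11)
  g <- bathy_grid(matrix(runif(25 * 25, 20, 120), 25, 25), cell_size = 90)
  g$values[c(17, 300)] <- NA  # nodata handled identically
  expect_equal(compute_bpi(g, 1, 3), brute_bpi(g, 1, 3), tolerance = 1e-9)
  expect_equal(compute_bpi(g, 0, 2.5), brute_bpi(g, 0, 2.5), tolerance = 1e-9)
})

test_that("BPI is invariant to a constant depth offset and validates inputs", {
  set.seed(2)
  g1 <- bathy_grid(matrix(runif(100, 30, 60), 10, 10), 90)
  g2 <- bathy_grid(g1$values + 25, 90)
  expect_equal(compute_bpi(g1, 1, 3), compute_bpi(g2, 1, 3), tolerance = 1e-10)
  expect_error(compute_bpi(g1, 3, 3), "inner_cells < outer_cells")
  expect_error(compute_bpi(g1, 0.2, 0.4), "empty")
})

test_that("slope, aspect and curvature reproduce closed forms", {
  # flat: zero slope and curvature, undefined aspect
  flat <- bathy_grid(matrix(40, 9, 9), cell_size = 10)
  sac <- compute_slope_aspect_curvature(flat)
  inner <- sac$slope[2:8, 2:8]
  expect_true(all(abs(inner) < 1e-12))
  expect_true(all(is.na(sac$aspect[2:8, 2:8])))
  expect_true(all(abs(sac$curvature[2:8, 2:8]) < 1e-12))

  # inclined plane, elevation z = 0.1 * x (east-up): slope atan(0.1),
  # down-gradient points west (270 degrees)
  L <- 10
  xcoord <- matrix(rep((1:9) * L, each = 9), 9, 9)
  depth <- 100 - 0.1 * xcoord  # elevation = 0.1*x - 100
  g <- bathy_grid(depth, cell_size = L)
  sac <- compute_slope_aspect_curvature(g)
  expect_equal(sac$slope[5, 5], atan(0.1) * 180 / pi, tolerance = 1e-8)
  expect_equal(sac$slope[5, 5], 5.710593, tolerance = 1e-4)
  expect_true(all(abs(sac$aspect[2:8, 2:8] - 270) < 1e-8))

  # dome elevation z = -(x^2+y^2)/1000: convex, |curvature| = 100*(zxx+zyy)
  xc <- matrix(rep((-4:4) * L, each = 9), 9, 9)
  yc <- t(xc)
  depth <- (xc^2 + yc^2) / 1000 + 50  # elevation = -(x^2+y^2)/1000 - 50
  g <- bathy_grid(depth, cell_size = L)
  sac <- compute_slope_aspect_curvature(g)
  expect_true(all(sac$curvature[2:8, 2:8] > 0))
  expect_equal(sac$curvature[5, 5], 100 * (2 / 1000 + 2 / 1000), tolerance = 0.05 * 0.4)
  expect_error(compute_slope_aspect_curvature(bathy_grid(matrix(1, 2, 5), 10)),
               "3x3")
})

test_that("slope transforms correctly when elevations are scaled", {
  set.seed(3)
  base <- matrix(runif(144, 40, 80), 12, 12)
  g1 <- bathy_grid(base, 90)
  g2 <- bathy_grid(base + 13.7, 90)           # constant shift
  g3 <- bathy_grid(2 * base, 90)              # doubled relief
  s1 <- compute_slope_aspect_curvature(g1)$slope
  s2 <- compute_slope_aspect_curvature(g2)$slope
  s3 <- compute_slope_aspect_curvature(g3)$slope
  expect_equal(s1, s2, tolerance = 1e-9)
  expect_equal(s3, atan(2 * tan(s1 * pi / 180)) * 180 / pi, tolerance = 1e-8)
})

test_that("default buffer radius is the 3x3-block hypotenuse of 90 m cells", {
  expect_equal(round(sqrt((3 * 90)^2 + (3 * 90)^2), 1), 381.8)
  expect_equal(formals(summarize_buffer)$radius, 381.8)
})

test_that("buffer summaries match the brute-force scan oracle", {
  set.seed(13)
  g <- bathy_grid(matrix(runif(25 * 25, 20, 120), 25, 25), cell_size = 90)
  st <- terrain_stack(g, outer_broad = 6, outer_fine = 3)
  pts <- data.frame(
    id = 1:20,
    x = runif(20, 2 * 90, 23 * 90),
    y = runif(20, 2 * 90, 23 * 90)
  )
  bs <- summarize_buffer(st, pts, radius = 381.8)
  for (layer in names(st$layers)) {
    for (p in 1:20) {
      expect_equal(bs[[paste0("mean_", layer)]][p],
                   brute_buffer_stat(st, pts$x[p], pts$y[p], 381.8, layer, "mean"),
                   tolerance = 1e-12, label = paste("mean", layer, "pt", p))
      expect_equal(bs[[paste0("max_", layer)]][p],
                   brute_buffer_stat(st, pts$x[p], pts$y[p], 381.8, layer, "max"),
                   tolerance = 1e-12, label = paste("max", layer, "pt", p))
    }
  }
})

test_that("buffer max >= mean, constant fields collapse, and off-grid points flag missing", {
  g <- bathy_grid(matrix(55, 15, 15), cell_size = 90)
  st <- terrain_stack(g, outer_broad = 4, outer_fine = 2)
  # constant depth: every layer constant (slope/curv/bpi 0); mean == max
  pts <- data.frame(id = "c", x = 7 * 90, y = 7 * 90)
  bs <- summarize_buffer(st, pts)
  expect_equal(bs$mean_slope, bs$max_slope)
  expect_equal(bs$mean_bpi_broad, 0, tolerance = 1e-12)

  set.seed(5)
  g2 <- bathy_grid(matrix(runif(225, 10, 90), 15, 15), 90)
  st2 <- terrain_stack(g2, outer_broad = 4, outer_fine = 2)
  pts2 <- data.frame(id = 1:10, x = runif(10, 180, 1170), y = runif(10, 180, 1170))
  bs2 <- summarize_buffer(st2, pts2, radius = 381.8)
  for (layer in c("slope", "curvature", "bpi_broad", "bpi_fine")) {
    expect_true(all(bs2[[paste0("max_", layer)]] >= bs2[[paste0("mean_", layer)]] - 1e-12))
  }
  # radius covering a single cell: mean == max
  bs3 <- summarize_buffer(st2, data.frame(id = 1, x = 7 * 90 - 45, y = 7 * 90 - 45),
                          radius = 40)
  expect_equal(bs3$n_cells, 1)
  expect_equal(bs3$mean_slope, bs3$max_slope)
  # point far outside the grid
  bs4 <- summarize_buffer(st2, data.frame(id = 1, x = 1e6, y = 1e6), radius = 381.8)
  expect_true(bs4$missing)
  expect_true(is.na(bs4$mean_slope))
})

test_that("a synthetic ridge crest carries the maximum BPI at its column", {
  cfg <- sim_config(grid_rows = 24, grid_cols = 64, noise_sd = 0,
                    ridges = list(list(col = 0.5, amplitude = 20, width = 3)),
                    seed = 1)
  b <- generate_bathymetry(cfg)
  # oracle: crest = argmax of elevation residual about the cross-shelf ramp
  ramp <- seq(cfg$depth_range[1], cfg$depth_range[2], length.out = cfg$grid_cols)
  resid <- -(b$values[12, ] - ramp)
  crest <- which.max(resid)
  bpi <- compute_bpi(b, 1, 9)
  # search interior columns: the asymmetric annulus inflates BPI at the
  # cross-shelf ramp's grid edges
  interior <- 12:(cfg$grid_cols - 12)
  bpi_col <- interior[which.max(apply(bpi[5:20, interior], 2, mean))]
  expect_lte(abs(bpi_col - crest), 1)
})
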