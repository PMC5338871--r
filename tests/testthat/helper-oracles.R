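# Independent brute-force oracles and small fixture builders used across the
# test files. Oracles deliberately avoid the package's computation paths.

# BPI by explicit double loop over annulus members.
brute_bpi <- function(grid, inner, outer) {
  elev <- -grid$values
  nr <- nrow(elev); nc <- ncol(elev)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -ceiling(outer):ceiling(outer)) for (dj in -ceiling(outer):ceiling(outer)) {
      d <- sqrt(di^2 + dj^2)
      if (d > inner && d <= outer) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && !is.na(elev[ii, jj])) {
          vals <- c(vals, elev[ii, jj])
        }
      }
    }
    if (length(vals)) out[i, j] <- elev[i, j] - mean(vals)
  }
  out
}

# Buffer summary by scanning every cell of every layer.
brute_buffer_stat <- function(stack, px, py, radius, layer, stat) {
  m <- stack$layers[[layer]]
  nr <- nrow(m); nc <- ncol(m); cs <- stack$cell_size
  vals <- c()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cx <- stack$origin[1] + (j - 0.5) * cs
    cy <- stack$origin[2] + (nr - i + 0.5) * cs
    if ((cx - px)^2 + (cy - py)^2 <= radius^2 && !is.na(m[i, j])) {
      vals <- c(vals, m[i, j])
    }
  }
  if (!length(vals)) return(NA_real_)
  if (stat == "max") return(max(vals))
  if (layer == "aspect") {
    r <- vals * pi / 180
    return((atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360)
  }
  mean(vals)
}

# Classification threshold by brute force over observed-score candidates,
# classifying score >= t, maximizing TPR + TNR, lowest t on ties.
brute_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  best_j <- -Inf; best_t <- NA
  for (t in cand) {
    cls <- as.integer(scores >= t)
    tpr <- sum(cls == 1 & labels == 1) / sum(labels == 1)
    tnr <- sum(cls == 0 & labels == 0) / sum(labels == 0)
    if (tpr + tnr > best_j + 1e-12) {
      best_j <- tpr + tnr
      best_t <- t
    }
  }
  best_t
}

# Convex hull area by a triangulation fan from the first hull vertex.
fan_hull_area <- function(x, y) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  n <- length(hx)
  if (n < 3) return(0)
  a <- 0
  for (k in 2:(n - 1)) {
    a <- a + ((hx[k] - hx[1]) * (hy[k + 1] - hy[1]) -
                (hx[k + 1] - hx[1]) * (hy[k] - hy[1])) / 2
  }
  abs(a)
}

# Connected components of the "within distance h" graph by BFS.
cc_clusters <- function(x, y, h) {
  n <- length(x)
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      d2 <- (x - x[v])^2 + (y - y[v])^2
      nb <- which(d2 <= h^2 & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Wrap arbitrary columns as a spawn_design for direct model fitting.
make_design <- function(df, terms, response = "spawning") {
  if (!"year" %in% names(df)) df$year <- factor(2001)
  df$year <- factor(df$year)
  structure(list(data = df, terms = terms, response = response, meta = list()),
            class = "spawn_design")
}

# A small complete synthetic world (bathy + terrain + survey + buffers).
make_world <- function(seed = 7, n_years = 4, n_sets_per_year = 40, ...) {
  cfg <- sim_config(n_years = n_years, n_sets_per_year = n_sets_per_year,
                    seed = seed, ...)
  bathy <- generate_bathymetry(cfg)
  terrain <- terrain_stack(bathy)
  survey <- generate_survey(cfg, bathy, terrain)
  xy <- lonlat_to_xy(survey$records$lon, survey$records$lat, cfg$ref)
  pts <- unique(data.frame(id = survey$records$set_id, x = xy$x, y = xy$y))
  buffers <- summarize_buffer(terrain, pts, radius = 381.8)
  list(cfg = cfg, bathy = bathy, terrain = terrain, survey = survey,
       buffers = buffers)
}
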