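# Synthetic shelf-edge bathymetry and survey collections from a fully known
# generative spawning model, so every downstream stage has a parameter-
# recovery and calibration surface.

SIM_COEF_NAMES <- c("intercept", "temperature", "latitude", "depth", "lunar",
                    "month_amplitude", "bpi")

#' Simulation configuration
#'
#' Defines the synthetic world: a shelf-edge bathymetry grid and a multi-year
#' trap/longline survey whose per-female spawning probability follows a known
#' logistic model with a year random intercept.
#'
#' Coefficients are on the logit scale and apply to centered covariates:
#' `temperature` per degree C about 22 C, `latitude` per degree about the
#' domain reference latitude, `depth` per meter about 50 m, `lunar` per unit
#' of the signed lunar luminosity, `month_amplitude` times a cosine seasonal
#' shape peaking in June, and `bpi` per meter of broad-scale BPI at the set.
#' The default month weights put most sampling effort in May-September, the
#' core fishery-independent season, with light March-April and October
#' sampling. The per-set fish count range defaults to 1-12: survey gear
#' deployments rarely yield more than a dozen histologically examined mature
#' females of one species, but no canonical distribution exists, so this is
#' a configurable guess.
#'
#' @param grid_rows,grid_cols grid dimensions (>= 16 each).
#' @param cell_size cell size in meters.
#' @param n_years number of survey years.
#' @param n_sets_per_year gear deployments per year.
#' @param females_per_set_range integer range of examined mature females per
#'   set and species (lower bound >= 1).
#' @param species character vector of species codes; with several species
#'   each is present in a set with probability `species_presence`.
#' @param species_presence per-set presence probability when `species` has
#'   length > 1.
#' @param true_coefficients named numeric vector on the logit scale; names
#'   must be among `intercept`, `temperature`, `latitude`, `depth`, `lunar`,
#'   `month_amplitude`, `bpi`.
#' @param random_intercept_sd SD of the year random intercept (logit scale).
#' @param temperature_model named numeric vector `mean` (C), `amplitude`
#'   (seasonal C), `lapse` (C per m depth), `sd` (noise C).
#' @param month_weights length-12 sampling weights, January-December.
#' @param ridges list of shelf-edge ridge features, each a list with `col`
#'   (fractional column position in (0,1)), `amplitude` (m) and `width`
#'   (cells).
#' @param noise_sd,noise_scale amplitude (m) and Gaussian smoothing scale
#'   (cells) of the correlated bathymetric noise.
#' @param depth_range cross-shelf depth ramp endpoints (m).
#' @param ref reference `c(lon, lat)` anchoring the projected grid.
#' @param base_year first calendar survey year.
#' @param seed integer RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(grid_rows = 96, grid_cols = 128, cell_size = 90,
                       n_years = 10, n_sets_per_year = 60,
                       females_per_set_range = c(1, 12),
                       species = "SP1", species_presence = 0.7,
                       true_coefficients = c(intercept = -1.2,
                                             temperature = 0.25,
                                             lunar = -0.6,
                                             month_amplitude = 1.5,
                                             bpi = 0.12),
                       random_intercept_sd = 0.5,
                       temperature_model = c(mean = 26, amplitude = 4,
                                             lapse = 0.08, sd = 0.8),
                       month_weights = c(0, 0, 2, 3, 9, 10, 10, 9, 8, 3, 0, 0),
                       ridges = list(list(col = 0.72, amplitude = 40, width = 4)),
                       noise_sd = 2, noise_scale = 3,
                       depth_range = c(10, 200),
                       ref = c(-79, 32), base_year = 2004, seed = 1) {
  if (grid_rows < 16 || grid_cols < 16) stopf("grid dimensions must be >= 16 x 16")
  if (cell_size <= 0) stopf("cell_size must be > 0")
  if (random_intercept_sd < 0) stopf("random_intercept_sd must be >= 0")
  if (females_per_set_range[1] < 1) stopf("females_per_set_range lower bound must be >= 1")
  if (length(month_weights) != 12 || any(month_weights < 0)) {
    stopf("month_weights must be 12 non-negative values")
  }
  bad <- setdiff(names(true_coefficients), SIM_COEF_NAMES)
  if (length(bad)) {
    stopf("unsupported coefficient name(s): %s (supported: %s)",
          paste(bad, collapse = ", "), paste(SIM_COEF_NAMES, collapse = ", "))
  }
  structure(as.list(environment()), class = "sim_config")
}

# Gaussian smoothing of a matrix by separable kernel, cell units.
smooth_matrix <- function(m, scale) {
  if (scale <= 0) return(m)
  r <- ceiling(3 * scale)
  k <- stats::dnorm(-r:r, sd = scale)
  k <- k / sum(k)
  sm_rows <- apply(m, 2, function(col) {
    stats::filter(c(rev(col[seq_len(r)]), col, rev(col[length(col) - seq_len(r) + 1])),
                  k, sides = 2)[r + seq_along(col)]
  })
  t(apply(sm_rows, 1, function(row) {
    stats::filter(c(rev(row[seq_len(r)]), row, rev(row[length(row) - seq_len(r) + 1])),
                  k, sides = 2)[r + seq_along(row)]
  }))
}

#' Generate a synthetic shelf-edge bathymetry surface
#'
#' Depth is the sum of (i) a monotone cross-shelf ramp from shallow inshore
#' (column 1) to deep offshore, (ii) one or more Gaussian ridge features
#' running along-shelf (locally shallow, emulating a shelf-edge reef crest),
#' and (iii) smooth correlated noise. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return a [bathy_grid()].
#' @export
generate_bathymetry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  ramp <- seq(config$depth_range[1], config$depth_range[2], length.out = nc)
  depth <- matrix(ramp, nr, nc, byrow = TRUE)
  for (rg in config$ridges) {
    j0 <- rg$col * nc
    depth <- depth - matrix(rg$amplitude * exp(-((seq_len(nc) - j0)^2) / (2 * rg$width^2)),
                            nr, nc, byrow = TRUE)
  }
  if (config$noise_sd > 0) {
    noise <- with_seed(config$seed, matrix(stats::rnorm(nr * nc), nr, nc))
    noise <- smooth_matrix(noise, config$noise_scale)
    noise <- noise / stats::sd(noise) * config$noise_sd
    depth <- depth + noise
  }
  depth <- pmax(depth, 1)
  bathy_grid(depth, cell_size = config$cell_size, origin = c(0, 0))
}

# seasonal shape shared by the month effect; peaks at June
month_shape <- function(month) cos(2 * pi * (month - 6) / 12)

#' Generate a synthetic survey of histologically examined females
#'
#' Places gear sets uniformly over eligible cells (depth within
#' `depth_range`), draws sampling dates with month weights concentrated on
#' May-September, derives set depth from the bathymetry, bottom temperature
#' from the seasonal temperature model, and the lunar covariate from the
#' date. Each examined female's spawning flag is Bernoulli with logit equal
#' to the configured linear predictor plus her set's year random intercept.
#' Truth columns (true probability, year effects) are kept in a sidecar
#' table so the analysis path consumes exactly the public schema.
#'
#' @param config a [sim_config()].
#' @param bathy bathymetry from [generate_bathymetry()].
#' @param terrain terrain stack from [terrain_stack()], aligned with `bathy`.
#' @return object of class `spawn_survey`: list with `records` (collections
#'   schema), `truth` (per-record true probability and linear predictor,
#'   plus per-year intercepts as an attribute), and `config`.
#' @export
generate_survey <- function(config, bathy, terrain) {
  stopifnot(inherits(config, "sim_config"), inherits(bathy, "bathy_grid"),
            inherits(terrain, "terrain_stack"))
  if (!identical(dim(bathy$values), terrain$dim)) {
    stopf("terrain stack is not aligned with the bathymetry grid")
  }
  co <- vapply(SIM_COEF_NAMES, function(nm) {
    v <- config$true_coefficients[nm]
    if (is.na(v)) 0 else unname(v)
  }, 0)
  tm <- config$temperature_model

  with_seed(config$seed + 1, {
    n_sets <- config$n_years * config$n_sets_per_year
    eligible <- which(bathy$values >= config$depth_range[1] &
                        bathy$values <= config$depth_range[2])
    if (!length(eligible)) stopf("no eligible cells in depth range")
    cells <- sample(eligible, n_sets, replace = TRUE)
    nr <- nrow(bathy$values)
    i <- (cells - 1) %% nr + 1
    j <- (cells - 1) %/% nr + 1
    cs <- bathy$cell_size
    x <- bathy$origin[1] + (j - 1) * cs + stats::runif(n_sets, 0, cs)
    y <- bathy$origin[2] + (nr - i) * cs + stats::runif(n_sets, 0, cs)
    ll <- xy_to_lonlat(x, y, config$ref)

    year_idx <- rep(seq_len(config$n_years), each = config$n_sets_per_year)
    year <- config$base_year + year_idx - 1
    month <- sample(1:12, n_sets, replace = TRUE, prob = config$month_weights)
    day <- sample(1:28, n_sets, replace = TRUE)
    date <- as.Date(sprintf("%d-%02d-%02d", year, month, day))
    doy <- as.integer(format(date, "%j"))

    depth <- bathy$values[cbind(i, j)]
    temp <- tm["mean"] + tm["amplitude"] * cos(2 * pi * (doy - 181) / 365.25) -
      tm["lapse"] * depth + stats::rnorm(n_sets, 0, tm["sd"])
    lun <- lunar3(date)$value
    bpi <- terrain$layers$bpi_broad[cbind(i, j)]
    bpi[is.na(bpi)] <- 0
    u_year <- stats::rnorm(config$n_years, 0, config$random_intercept_sd)

    eta_set <- co["intercept"] +
      co["temperature"] * (temp - 22) +
      co["latitude"] * (ll$lat - config$ref[2]) +
      co["depth"] * (depth - 50) +
      co["lunar"] * lun +
      co["month_amplitude"] * month_shape(month) +
      co["bpi"] * bpi +
      u_year[year_idx]
    gear <- sample(c("CVT", "SBLL"), n_sets, replace = TRUE, prob = c(0.8, 0.2))
    habitat <- sample(c("HB", "PH", "NH", "UNK"), n_sets, replace = TRUE,
                      prob = c(0.6, 0.2, 0.1, 0.1))
    salinity <- round(stats::rnorm(n_sets, 36, 0.3), 1)

    recs <- vector("list", length(config$species))
    for (s in seq_along(config$species)) {
      present <- if (length(config$species) > 1) {
        stats::runif(n_sets) < config$species_presence
      } else rep(TRUE, n_sets)
      sets <- which(present)
      nf <- sample(seq(config$females_per_set_range[1], config$females_per_set_range[2]),
                   length(sets), replace = TRUE)
      idx <- rep(sets, nf)
      p <- stats::plogis(eta_set[idx])
      recs[[s]] <- data.frame(
        set_id = sprintf("S%04d", idx),
        date = date[idx], year = year[idx], month = month[idx],
        lon = round(ll$lon[idx], 6), lat = round(ll$lat[idx], 6),
        gear = gear[idx], depth_m = round(depth[idx], 1),
        temp_c = round(temp[idx], 2), salinity_ppt = salinity[idx],
        habitat = habitat[idx], species = config$species[s],
        spawning = stats::rbinom(length(idx), 1, p),
        true_prob = p,
        true_eta = eta_set[idx],
        stringsAsFactors = FALSE
      )
    }
    all <- do.call(rbind, recs)
    ord <- order(all$set_id, all$species)
    all <- all[ord, , drop = FALSE]
    truth <- data.frame(set_id = all$set_id, species = all$species,
                        true_prob = all$true_prob, true_eta = all$true_eta)
    attr(truth, "year_effects") <- data.frame(year = config$base_year + seq_len(config$n_years) - 1,
                                              u = u_year)
    records <- all[, c("set_id", "date", "year", "month", "lon", "lat", "gear",
                       "depth_m", "temp_c", "salinity_ppt", "habitat", "species",
                       "spawning")]
    rownames(records) <- NULL
    structure(list(records = records, truth = truth, config = config),
              class = "spawn_survey")
  })
}

#' @export
print.spawn_survey <- function(x, ...) {
  cat(sprintf("<spawn_survey> %d examined females, %d sets, %d year(s), %d species\n",
              nrow(x$records), length(unique(x$records$set_id)),
              length(unique(x$records$year)), length(unique(x$records$species))))
  cat(sprintf("  spawning fraction: %.3f\n", mean(x$records$spawning)))
  invisible(x)
}

#' Write a synthetic survey to disk
#'
#' Writes the public collections CSV and a `*_truth.csv` sidecar holding the
#' generative probabilities, so the analysis path consumes only the public
#' schema.
#'
#' @param survey a `spawn_survey` from [generate_survey()].
#' @param dir output directory (created if needed).
#' @param stem file name stem (default `"survey"`).
#' @return invisible character vector of the two file paths.
#' @export
write_survey <- function(survey, dir, stem = "survey") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(stem, ".csv"))
  p2 <- file.path(dir, paste0(stem, "_truth.csv"))
  utils::write.csv(survey$records, p1, row.names = FALSE)
  utils::write.csv(survey$truth, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a collections CSV
#' @param path CSV in the collections schema (see [build_design()]).
#' @return data.frame with `date` parsed as `Date`.
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("set_id", "date", "year", "month", "lon", "lat", "gear", "depth_m",
            "temp_c", "salinity_ppt", "habitat", "species", "spawning")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("collections CSV missing column(s): %s",
                          paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  df
}
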