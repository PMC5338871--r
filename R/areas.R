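# Multispecies spawning collections, multi-year spawning-area delineation by
# single-linkage clustering, and minimum-convex-polygon sizing.

#' Spawning events from survey records
#'
#' One event per gear set that retrieved at least one spawning-condition
#' female, with the set of species in spawning condition.
#'
#' @param records collections data.frame.
#' @return data.frame per event: `set_id`, `date`, `year`, `lon`, `lat`,
#'   `species` (comma-joined, sorted), `n_species`.
#' @export
spawning_events <- function(records) {
  r <- records[records$spawning == 1, , drop = FALSE]
  if (!nrow(r)) {
    return(data.frame(set_id = character(0), date = as.Date(character(0)),
                      year = integer(0), lon = numeric(0), lat = numeric(0),
                      species = character(0), n_species = integer(0)))
  }
  sp <- split(r, r$set_id)
  out <- lapply(sp, function(d) {
    u <- sort(unique(d$species))
    data.frame(set_id = d$set_id[1], date = d$date[1], year = d$year[1],
               lon = d$lon[1], lat = d$lat[1],
               species = paste(u, collapse = ","), n_species = length(u))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multispecies spawning collections
#'
#' Events where a single collection retrieved spawning-condition females of
#' two or more species, plus the pairwise co-occurrence matrix (symmetric,
#' zero diagonal).
#'
#' @param events from [spawning_events()].
#' @return list with `events` (rows with `n_species >= 2`) and
#'   `co_occurrence` (species x species counts of joint events).
#' @export
detect_multispecies <- function(events) {
  multi <- events[events$n_species >= 2, , drop = FALSE]
  all_sp <- sort(unique(unlist(strsplit(events$species, ","))))
  co <- matrix(0L, length(all_sp), length(all_sp), dimnames = list(all_sp, all_sp))
  for (i in seq_len(nrow(multi))) {
    sp <- strsplit(multi$species[i], ",")[[1]]
    for (a in sp) for (b in sp) if (a != b) co[a, b] <- co[a, b] + 1L
  }
  list(events = multi, co_occurrence = co)
}

#' Minimum convex polygon area
#'
#' Area of the convex hull of occurrence points, in square kilometers.
#' Geographic coordinates are projected to a Lambert azimuthal equal-area
#' plane centered on the point centroid before the hull is taken (hulls in
#' raw geographic coordinates are refused). Fewer than 3 non-collinear
#' points give area 0. Rounding to the nearest km^2 is left to report
#' formatting.
#'
#' @param lon,lat point coordinates in decimal degrees, or planar meters
#'   with `projected = TRUE`.
#' @param projected treat inputs as planar meters (default `FALSE`).
#' @return area in km^2.
#' @export
mcp_area <- function(lon, lat, projected = FALSE) {
  if (length(lon) < 1) stopf("need at least one point")
  if (length(lon) < 3) return(0)
  if (projected) {
    x <- lon; y <- lat
  } else {
    p <- laea_project(lon, lat, mean(lon), mean(lat))
    x <- p$x; y <- p$y
  }
  h <- grDevices::chull(x, y)
  polygon_area(x[h], y[h]) / 1e6
}

# Single-linkage clusters at a distance cutoff == connected components of
# the "within link_distance" graph.
single_linkage_clusters <- function(x, y, link_distance) {
  n <- length(x)
  if (n == 1) return(1L)
  d <- stats::dist(cbind(x, y))
  hc <- stats::hclust(d, method = "single")
  stats::cutree(hc, h = link_distance)
}

#' Multi-year spawning areas for a species
#'
#' Groups a species' spawning events by single-linkage clustering at
#' `link_distance` (default 1,100 m, the repeat-observation radius used to
#' assess site fidelity). Clusters whose events span two or more sampling
#' years become spawning areas, sized by minimum convex polygon. The percent
#' of years with spawning females uses as denominator the number of years in
#' which any histological sample of the species fell within `link_distance`
#' of a member event (the cluster's sampled footprint); it is `NA` when
#' `records` lacks non-spawning sampling information.
#'
#' @param records collections data.frame (all histological samples; used for
#'   both events and the sampled-years denominator).
#' @param species species code to delineate.
#' @param link_distance single-linkage cutoff in meters (default 1100).
#' @return object of class `spawning_areas`: list with `areas` (one row per
#'   multi-year area: `area_id`, `n_events`, `n_years`, `years`,
#'   `years_sampled`, `pct_years`, `mcp_km2`) and `events` (the species'
#'   events with their cluster assignment and multi-year flag).
#' @export
cluster_multiyear <- function(records, species, link_distance = 1100) {
  r <- records[records$species == species, , drop = FALSE]
  ev <- spawning_events(r)
  if (!nrow(ev)) {
    return(structure(list(areas = data.frame(), events = ev,
                          species = species, link_distance = link_distance),
                     class = "spawning_areas"))
  }
  ref <- c(mean(ev$lon), mean(ev$lat))
  exy <- lonlat_to_xy(ev$lon, ev$lat, ref)
  ev$cluster <- single_linkage_clusters(exy$x, exy$y, link_distance)

  # per-set sampling locations of the species (for the years-sampled denominator)
  sets <- r[!duplicated(r$set_id), c("set_id", "year", "lon", "lat")]
  sxy <- lonlat_to_xy(sets$lon, sets$lat, ref)

  areas <- list()
  for (cl in sort(unique(ev$cluster))) {
    m <- ev$cluster == cl
    yrs <- sort(unique(ev$year[m]))
    if (length(yrs) < 2) next
    # footprint: any sample within link_distance of a member event
    d2min <- rep(Inf, nrow(sets))
    for (e in which(m)) {
      d2 <- (sxy$x - exy$x[e])^2 + (sxy$y - exy$y[e])^2
      d2min <- pmin(d2min, d2)
    }
    sampled_years <- sort(unique(sets$year[d2min <= link_distance^2]))
    areas[[length(areas) + 1]] <- data.frame(
      area_id = length(areas) + 1L,
      n_events = sum(m),
      n_years = length(yrs),
      years = paste(yrs, collapse = ","),
      years_sampled = length(sampled_years),
      pct_years = if (length(sampled_years)) 100 * length(yrs) / length(sampled_years)
                  else NA_real_,
      mcp_km2 = mcp_area(ev$lon[m], ev$lat[m]),
      cluster = cl
    )
  }
  area_df <- if (length(areas)) do.call(rbind, areas) else data.frame()
  ev$multi_year <- ev$cluster %in% area_df$cluster
  structure(list(areas = area_df, events = ev, species = species,
                 link_distance = link_distance),
            class = "spawning_areas")
}

#' @export
print.spawning_areas <- function(x, ...) {
  cat(sprintf("<spawning_areas> %s: %d multi-year area(s) from %d event(s) (link %.0f m)\n",
              x$species, nrow(x$areas), nrow(x$events), x$link_distance))
  if (nrow(x$areas)) {
    cat(sprintf("  MCP area: mean %.2f km2 (range %.2f-%.2f)\n",
                mean(x$areas$mcp_km2), min(x$areas$mcp_km2), max(x$areas$mcp_km2)))
  }
  invisible(x)
}

#' Per-species multi-year spawning-area summary
#'
#' A summary table of apparent multi-year spawning-site use: number of
#' areas, years sampled, percent of sampled years with spawning females, and
#' MCP size (mean and SD), by species.
#'
#' @param records collections data.frame.
#' @param link_distance single-linkage cutoff in meters.
#' @return data.frame, one row per species with at least one multi-year area.
#' @export
spawning_area_summary <- function(records, link_distance = 1100) {
  sp <- sort(unique(records$species))
  out <- list()
  for (s in sp) {
    ca <- cluster_multiyear(records, s, link_distance)
    if (!nrow(ca$areas)) next
    a <- ca$areas
    out[[length(out) + 1]] <- data.frame(
      species = s,
      n_areas = nrow(a),
      years_sampled_mean = mean(a$years_sampled),
      years_sampled_sd = stats::sd(a$years_sampled),
      pct_years_mean = mean(a$pct_years, na.rm = TRUE),
      pct_years_sd = stats::sd(a$pct_years, na.rm = TRUE),
      mcp_km2_mean = mean(a$mcp_km2),
      mcp_km2_sd = stats::sd(a$mcp_km2)
    )
  }
  if (length(out)) do.call(rbind, out) else data.frame()
}
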