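# Design-variable construction: the spawning response, quantile/fixed
# binning, factor encoding with recorded bin edges and levels, interaction
# crosses, and phenology tabulations.

STAGE1_TERMS <- c("gear", "habitat", "month", "temperature", "latitude",
                  "depth", "lunar", "lat_x_depth", "lat_x_month", "lat_x_temp")
INTERACTION_MARGINS <- list(
  lat_x_depth = c("latitude", "depth"),
  lat_x_month = c("latitude", "month"),
  lat_x_temp  = c("latitude", "temperature")
)

#' Quantile binning of a numeric vector
#'
#' Cuts `x` into `k` bins at its empirical (type-7) quantiles. Bins are
#' left-closed/right-open with respect to the inner cut points, so the last
#' bin is closed on the right. Duplicate quantile edges (heavy ties) are
#' collapsed, returning fewer bins, and recorded in the `"warning"`
#' attribute; a constant vector yields a single bin.
#'
#' @param x numeric vector.
#' @param k target number of bins (>= 2).
#' @return factor with levels `bin1`, `bin2`, ...; attributes `edges` (inner
#'   cut points) and `warning` (character or `NULL`).
#' @export
bin_quantile <- function(x, k = 4) {
  if (k < 2) stopf("k must be >= 2")
  qs <- stats::quantile(x, probs = seq_len(k - 1) / k, na.rm = TRUE,
                        type = 7, names = FALSE)
  edges <- unique(qs)
  warn <- NULL
  if (length(edges) < k - 1) {
    warn <- sprintf("duplicate quantile edges collapsed: %d bins returned instead of %d",
                    length(edges) + 1, k)
  }
  if (length(unique(x[!is.na(x)])) < 2) {
    edges <- numeric(0)
    warn <- "constant input: single bin returned"
  }
  f <- bin_by_edges(x, edges)
  attr(f, "edges") <- edges
  attr(f, "warning") <- warn
  f
}

# Assign bins from inner cut points: bin j holds e_{j-1} <= x < e_j, with the
# outermost bins unbounded (so the top bin is right-closed by construction).
bin_by_edges <- function(x, edges) {
  nb <- length(edges) + 1
  idx <- findInterval(x, edges) + 1
  factor(paste0("bin", idx), levels = paste0("bin", seq_len(nb)))
}

#' Fixed-scheme binning
#'
#' Bins `x` at user-supplied edges, e.g. `c(10, 30, 50, 70)` for 20 m depth
#' bins from 10-70 m, or `seq(30.5, 34.5, by = 1)` for 1 degree latitude
#' bins. With `extend = TRUE` (default) values outside the scheme fall into
#' open-ended outer bins; otherwise they become `NA`.
#'
#' @param x numeric vector.
#' @param edges increasing numeric vector of bin boundaries.
#' @param extend keep values outside `[min(edges), max(edges)]` in outer bins.
#' @return factor with attribute `edges` (the interior boundaries used).
#' @export
bin_fixed <- function(x, edges, extend = TRUE) {
  if (is.unsorted(edges, strictly = TRUE)) stopf("edges must be strictly increasing")
  f <- bin_by_edges(x, edges)
  if (!extend) {
    f[x < edges[1] | x > edges[length(edges)]] <- NA
  }
  attr(f, "edges") <- edges
  f
}

#' Build the model design from survey records
#'
#' Encodes the spawning response (one row per histologically examined mature
#' female) together with the requested covariate terms: categorical terms are
#' factor-encoded with the first sorted label as reference, continuous
#' predictors (latitude, depth, terrain statistics, optionally the lunar
#' value) are binned by quantiles or by fixed schemes and treated as factors,
#' temperature stays continuous, and interactions are factor crosses. Empty
#' factor bins are removed, and rows with missing required covariates are
#' dropped and counted. Bin edges and factor levels are retained as metadata
#' so that predictions reproduce the encoding exactly.
#'
#' @param records data.frame in the collections schema:
#'   `set_id,date,year,month,lon,lat,gear,depth_m,temp_c,salinity_ppt,habitat,species,spawning`.
#' @param terms character vector of term names. Stage-1 terms: `gear`,
#'   `habitat`, `month`, `temperature`, `latitude`, `depth`, `lunar`,
#'   `lat_x_depth`, `lat_x_month`, `lat_x_temp`. Any column of `buffers`
#'   (e.g. `mean_bpi_broad`, `max_slope`) is a bathymetric term.
#' @param buffers optional buffer summary from [summarize_buffer()] keyed by
#'   `id` = `set_id`; required when bathymetric terms are requested.
#' @param k_bins quantile bins for binned predictors (default 4, quartiles).
#' @param latitude_edges,depth_edges optional fixed bin edges overriding the
#'   quantile scheme (e.g. `seq(30.5, 34.5, 1)`; `c(10, 30, 50, 70)`).
#' @param lunar_mode `"continuous"` (default) or `"binned"`.
#' @param quarter_round snap the lunar value to quarter moons.
#' @param drop_invalid_temp drop rows with missing or non-positive
#'   temperature when a temperature term is present (default `TRUE`).
#' @return an object of class `spawn_design`: list with `data` (model frame
#'   including the response, `year`, term columns and `raw_*` screening
#'   columns), `terms`, and `meta` (bin edges, levels, dropped-row count).
#' @export
build_design <- function(records, terms, buffers = NULL, k_bins = 4,
                         latitude_edges = NULL, depth_edges = NULL,
                         lunar_mode = c("continuous", "binned"),
                         quarter_round = FALSE, drop_invalid_temp = TRUE) {
  lunar_mode <- match.arg(lunar_mode)
  bath_avail <- if (is.null(buffers)) character(0) else {
    setdiff(names(buffers), c("id", "n_cells", "missing"))
  }
  unknown <- setdiff(terms, c(STAGE1_TERMS, bath_avail))
  if (length(unknown)) {
    stopf("unknown term(s): %s%s", paste(unknown, collapse = ", "),
          if (is.null(buffers)) " (no buffer summary supplied)" else "")
  }
  bath_terms <- intersect(terms, bath_avail)
  needs <- function(t) any(t %in% terms) ||
    any(unlist(INTERACTION_MARGINS[intersect(terms, names(INTERACTION_MARGINS))]) %in% t)

  df <- records
  n0 <- nrow(df)
  if (length(bath_terms)) {
    m <- match(df$set_id, buffers$id)
    if (anyNA(m)) {
      stopf("no buffer summary for set_id(s): %s",
            paste(utils::head(unique(df$set_id[is.na(m)]), 10), collapse = ", "))
    }
    for (bt in bath_terms) df[[paste0(".bath_", bt)]] <- buffers[[bt]][m]
  }

  keep <- !is.na(df$spawning)
  if (needs("temperature")) {
    keep <- keep & if (drop_invalid_temp) !is.na(df$temp_c) & df$temp_c > 0 else !is.na(df$temp_c)
  }
  if (needs("latitude")) keep <- keep & !is.na(df$lat)
  if (needs("depth")) keep <- keep & !is.na(df$depth_m)
  if (needs("lunar")) keep <- keep & !is.na(df$date)
  for (bt in bath_terms) keep <- keep & !is.na(df[[paste0(".bath_", bt)]])
  dropped <- n0 - sum(keep)
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stopf("no usable rows after dropping missing covariates")

  out <- data.frame(spawning = as.integer(df$spawning),
                    year = factor(df$year), row.names = NULL)
  edges <- list(); warnings <- character(0)

  add_binned <- function(x, name, fixed_edges = NULL) {
    f <- if (is.null(fixed_edges)) bin_quantile(x, k_bins) else bin_fixed(x, fixed_edges)
    if (!is.null(attr(f, "warning"))) {
      warnings <<- c(warnings, paste0(name, ": ", attr(f, "warning")))
    }
    edges[[name]] <<- attr(f, "edges")
    droplevels(f)
  }

  if ("gear" %in% terms) out$gear <- factor(df$gear)
  if ("habitat" %in% terms) out$habitat <- factor(df$habitat)
  if (needs("month")) {
    out$month <- factor(month.abb[df$month], levels = month.abb[sort(unique(df$month))])
  }
  if (needs("temperature")) out$temperature <- df$temp_c
  if (needs("latitude")) out$latitude <- add_binned(df$lat, "latitude", latitude_edges)
  if (needs("depth")) out$depth <- add_binned(df$depth_m, "depth", depth_edges)
  if (needs("lunar")) {
    lv <- lunar3(df$date, quarter_round = quarter_round)$value
    if (lunar_mode == "binned") {
      out$lunar <- add_binned(lv, "lunar")
    } else {
      out$lunar <- lv
    }
    out$raw_lunar <- lv
  }
  for (bt in bath_terms) out[[bt]] <- add_binned(df[[paste0(".bath_", bt)]], bt)

  if ("lat_x_depth" %in% terms) {
    out$lat_x_depth <- droplevels(interaction(out$latitude, out$depth, sep = ":", drop = TRUE))
  }
  if ("lat_x_month" %in% terms) {
    out$lat_x_month <- droplevels(interaction(out$latitude, out$month, sep = ":", drop = TRUE))
  }
  if ("lat_x_temp" %in% terms) {
    tb <- add_binned(df$temp_c, ".temp_interaction")
    out$lat_x_temp <- droplevels(interaction(out$latitude, tb, sep = ":", drop = TRUE))
  }

  # screening columns: underlying continuous values where they exist
  if (needs("latitude")) out$raw_latitude <- df$lat
  if (needs("depth")) out$raw_depth <- df$depth_m
  if (needs("temperature")) out$raw_temperature <- df$temp_c
  for (bt in bath_terms) out[[paste0("raw_", bt)]] <- df[[paste0(".bath_", bt)]]

  # a term whose factor has a single observed level cannot enter a model
  single <- vapply(terms, function(t) {
    is.factor(out[[t]]) && nlevels(droplevels(out[[t]])) < 2
  }, logical(1))
  if (any(single)) {
    warnings <- c(warnings, sprintf("term(s) with a single observed level dropped: %s",
                                    paste(terms[single], collapse = ", ")))
    terms <- terms[!single]
  }

  for (nm in names(out)) if (is.factor(out[[nm]])) out[[nm]] <- droplevels(out[[nm]])

  meta <- list(
    edges = edges,
    levels = lapply(Filter(is.factor, out), levels),
    dropped = dropped,
    k_bins = k_bins,
    lunar_mode = lunar_mode,
    warnings = warnings,
    cont_range = list(
      temperature = if (needs("temperature")) range(out$temperature) else NULL,
      lunar = if (needs("lunar")) range(out$raw_lunar) else NULL
    )
  )
  structure(list(data = out, terms = terms, response = "spawning", meta = meta),
            class = "spawn_design")
}

#' @export
print.spawn_design <- function(x, ...) {
  cat(sprintf("<spawn_design> %d rows (%d dropped), %d spawning\n",
              nrow(x$data), x$meta$dropped, sum(x$data$spawning)))
  cat("  terms:", if (length(x$terms)) paste(x$terms, collapse = ", ") else "(intercept only)", "\n")
  if (length(x$meta$warnings)) cat("  notes:", paste(x$meta$warnings, collapse = "; "), "\n")
  invisible(x)
}

# Row subset preserving metadata (used by cross-validation folds).
design_subset <- function(design, idx) {
  out <- design
  out$data <- design$data[idx, , drop = FALSE]
  out
}

# Re-encode raw covariates with a fitted design's stored edges and levels.
# Unseen factor levels map to the reference level (first stored level) with a
# warning, or raise an error under strict = TRUE. Values outside stored bin
# edges fall into the nearest outer bin.
apply_design_meta <- function(meta, terms, newdata, strict = FALSE) {
  out <- data.frame(row.names = seq_len(nrow(newdata)))
  unseen <- character(0)
  to_levels <- function(vals, levs, name) {
    f <- factor(as.character(vals), levels = levs)
    bad <- is.na(f) & !is.na(vals)
    if (any(bad)) {
      unseen <<- c(unseen, name)
      f[bad] <- levs[1]
    }
    f
  }
  rebin <- function(x, name) {
    e <- meta$edges[[name]]
    to_levels(as.character(bin_by_edges(x, e)), meta$levels[[name]], name)
  }
  defaulted <- character(0)
  for (t in terms) {
    if (t %in% c("gear", "habitat")) {
      if (is.null(newdata[[t]])) {
        # non-spatial term absent from prediction covariates: reference level
        defaulted <- c(defaulted, t)
        out[[t]] <- factor(rep(meta$levels[[t]][1], nrow(newdata)),
                           levels = meta$levels[[t]])
      } else {
        out[[t]] <- to_levels(newdata[[t]], meta$levels[[t]], t)
      }
    } else if (t == "month") {
      vals <- if (is.numeric(newdata$month)) month.abb[newdata$month] else newdata$month
      out[[t]] <- to_levels(vals, meta$levels$month, t)
    } else if (t == "temperature") {
      out[[t]] <- newdata$temperature %||% newdata$temp_c
    } else if (t == "latitude") {
      out[[t]] <- rebin(newdata$latitude %||% newdata$lat, "latitude")
    } else if (t == "depth") {
      out[[t]] <- rebin(newdata$depth %||% newdata$depth_m, "depth")
    } else if (t == "lunar") {
      lv <- newdata$lunar %||% lunar3(newdata$date)$value
      out[[t]] <- if (meta$lunar_mode == "binned") rebin(lv, "lunar") else lv
    } else if (t %in% names(INTERACTION_MARGINS)) {
      # composed after margins below
    } else {
      out[[t]] <- rebin(newdata[[t]], t)
    }
  }
  margin_level <- function(m) {
    if (m == "temperature") {
      as.character(bin_by_edges(newdata$temperature %||% newdata$temp_c,
                                meta$edges[[".temp_interaction"]]))
    } else if (!is.null(out[[m]])) as.character(out[[m]])
    else if (m == "latitude") as.character(bin_by_edges(newdata$latitude %||% newdata$lat,
                                                        meta$edges$latitude))
    else if (m == "depth") as.character(bin_by_edges(newdata$depth %||% newdata$depth_m,
                                                     meta$edges$depth))
    else if (m == "month") {
      if (is.numeric(newdata$month)) month.abb[newdata$month] else as.character(newdata$month)
    } else stopf("cannot resolve interaction margin '%s'", m)
  }
  for (t in intersect(terms, names(INTERACTION_MARGINS))) {
    mm <- INTERACTION_MARGINS[[t]]
    lab <- paste(margin_level(mm[1]), margin_level(mm[2]), sep = ":")
    out[[t]] <- to_levels(lab, meta$levels[[t]], t)
  }
  if (length(unseen)) {
    msg <- sprintf("unseen level(s) mapped to reference for: %s",
                   paste(unique(unseen), collapse = ", "))
    if (strict) stopf("%s", msg) else warnf("%s", msg)
  }
  if (length(defaulted)) {
    warnf("term(s) absent from newdata held at the reference level: %s",
          paste(defaulted, collapse = ", "))
  }
  out
}

#' Spawning phenology table
#'
#' Counts of examined and spawning females, and the spawning fraction, per
#' species x month x lunar-phase cell. Cells with zero examined females are
#' retained and flagged.
#'
#' @param records collections data.frame (see [build_design()] schema).
#' @return data.frame with columns `species`, `month`, `phase`, `n_examined`,
#'   `n_spawning`, `fraction`, `empty`.
#' @export
phenology_table <- function(records) {
  ph <- lunar3(records$date)$phase
  sp <- factor(records$species)
  mo <- factor(month.abb[records$month], levels = month.abb[sort(unique(records$month))])
  n_ex <- as.data.frame(table(species = sp, month = mo, phase = ph),
                        responseName = "n_examined")
  n_sp <- as.data.frame(
    table(species = sp[records$spawning == 1], month = mo[records$spawning == 1],
          phase = ph[records$spawning == 1]),
    responseName = "n_spawning"
  )
  out <- merge(n_ex, n_sp, all.x = TRUE, sort = TRUE)
  out$n_spawning[is.na(out$n_spawning)] <- 0L
  out$fraction <- ifelse(out$n_examined > 0, out$n_spawning / out$n_examined, NA)
  out$empty <- out$n_examined == 0
  out[order(out$species, out$month, out$phase), , drop = FALSE]
}
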