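#' Per-site and overall movement summary table
#'
#' Medians of the four movement outcomes by study site, with dog counts and
#' an overall row across all dogs.
#'
#' @param summaries data.frame of per-dog movement summaries (one row per
#'   dog, see [movement_summary()], with `core_hr_ha`/`extended_hr_ha`
#'   filled).
#' @param metadata metadata data.frame with `dog_id` and `site`.
#' @return data.frame: `site`, `n_dogs`, `median_daily_distance_km`,
#'   `median_core_hr_ha`, `median_extended_hr_ha`,
#'   `median_pct_time_household`; last row `site == "Overall"`.
#' @export
site_summary <- function(summaries, metadata) {
  stopifnot("dog_id" %in% names(summaries), "dog_id" %in% names(metadata))
  m <- merge(summaries, metadata[c("dog_id", "site")], by = "dog_id")
  if (nrow(m) < nrow(summaries)) {
    warning(nrow(summaries) - nrow(m), " dog(s) missing from metadata")
  }
  one <- function(d, label) {
    data.frame(site = label, n_dogs = nrow(d),
               median_daily_distance_km = stats::median(d$daily_distance_km),
               median_core_hr_ha = stats::median(d$core_hr_ha),
               median_extended_hr_ha = stats::median(d$extended_hr_ha),
               median_pct_time_household =
                 stats::median(d$pct_time_household))
  }
  per_site <- do.call(rbind, lapply(split(m, m$site),
                                    function(d) one(d, d$site[1])))
  out <- rbind(per_site, one(m, "Overall"))
  rownames(out) <- NULL
  out
}

#' Build the centroid inventory for ground-truthing
#'
#' One record per isopleth polygon at the surveyed levels (10, 50 and 90%),
#' with planar and geographic centroid coordinates, the polygon area, and
#' an empty free-text label column to be completed after visiting the site.
#'
#' @param isopleths named list per dog: each element a list of
#'   `isopleth_set`s (any levels; only 10/50/90 are inventoried).
#' @return data.frame: `dog_id`, `level`, `polygon`, `x`, `y`, `lon`,
#'   `lat`, `area_m2`, `label` (empty).
#' @export
centroid_records <- function(isopleths) {
  rows <- list()
  for (dog in names(isopleths)) {
    for (iso in isopleths[[dog]]) {
      if (!iso$level %in% c(10, 50, 90)) next
      cc <- isopleth_centroids(iso)
      if (nrow(cc) == 0) next
      cc$dog_id <- dog
      cc$level <- iso$level
      rows[[length(rows) + 1L]] <- cc
    }
  }
  if (!length(rows)) {
    return(data.frame(dog_id = character(0), level = numeric(0),
                      polygon = integer(0), x = numeric(0), y = numeric(0),
                      area_m2 = numeric(0), label = character(0)))
  }
  out <- do.call(rbind, rows)
  out$label <- ""
  cols <- c("dog_id", "level", "polygon", "x", "y",
            intersect(c("lon", "lat"), names(out)), "area_m2", "label")
  out[cols]
}

#' Dog pairs whose centroids fall at a shared location
#'
#' Flags every pair of distinct dogs with at least one pair of centroids
#' within `distance_threshold` metres, reporting the closest such pair of
#' points. The relation is symmetric; each unordered dog pair appears once.
#'
#' @param records centroid inventory from [centroid_records()] (needs
#'   planar `x`, `y`).
#' @param distance_threshold metres; default 50.
#' @return data.frame: `dog_a`, `dog_b`, `distance_m`, `x`, `y` (midpoint
#'   of the closest centroid pair), `level_a`, `level_b`.
#' @export
centroid_overlap <- function(records, distance_threshold = 50) {
  dogs <- unique(records$dog_id)
  if (length(dogs) < 2) stop("need centroid records for at least 2 dogs")
  out <- list()
  for (a in seq_along(dogs)) {
    ra <- records[records$dog_id == dogs[a], , drop = FALSE]
    for (b in seq_len(a - 1L)) {
      rb <- records[records$dog_id == dogs[b], , drop = FALSE]
      dm <- outer(seq_len(nrow(ra)), seq_len(nrow(rb)), function(i, j) {
        sqrt((ra$x[i] - rb$x[j])^2 + (ra$y[i] - rb$y[j])^2)
      })
      if (min(dm) <= distance_threshold) {
        hit <- which(dm == min(dm), arr.ind = TRUE)[1, ]
        out[[length(out) + 1L]] <- data.frame(
          dog_a = dogs[b], dog_b = dogs[a], distance_m = min(dm),
          x = (ra$x[hit[1]] + rb$x[hit[2]]) / 2,
          y = (ra$y[hit[1]] + rb$y[hit[2]]) / 2,
          level_a = rb$level[hit[2]], level_b = ra$level[hit[1]])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(dog_a = character(0), dog_b = character(0),
                      distance_m = numeric(0), x = numeric(0),
                      y = numeric(0), level_a = numeric(0),
                      level_b = numeric(0)))
  }
  do.call(rbind, out)
}

#' Write a UD raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange format readable by standard GIS tools.
#' Rows are written north to south as the format requires.
#'
#' @param ud a `ud_grid`.
#' @param path output path (conventionally `.asc`).
#' @export
write_ud_asc <- function(ud, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ud$n_cols),
    paste("nrows", ud$n_rows),
    paste("xllcorner", ud$xmin),
    paste("yllcorner", ud$ymin),
    paste("cellsize", ud$cell_size),
    "NODATA_value -9999"), con)
  for (i in rev(seq_len(ud$n_rows))) {
    writeLines(paste(format(ud$mass[i, ], scientific = TRUE, digits = 8),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Export isopleths and centroids as GeoJSON
#'
#' Writes one FeatureCollection: a (Multi)Polygon feature per isopleth
#' (rings inverse-projected to WGS84) and a Point feature per centroid,
#' with dog, level, and area properties, plus the estimation parameters in
#' the collection's `properties`.
#'
#' @param isopleths list of `isopleth_set`s (projected; CRS attached).
#' @param path output path.
#' @param params optional list of parameter metadata to embed.
#' @export
write_isopleth_geojson <- function(isopleths, path, params = NULL) {
  feats <- list()
  for (iso in isopleths) {
    crs <- iso$crs
    ring_ll <- lapply(iso$rings, function(poly) {
      lapply(poly, function(ring) {
        ll <- utm_inverse(ring[, "x"], ring[, "y"], zone = crs$zone,
                          north = crs$north)
        lapply(seq_len(nrow(ll)), function(r) c(ll[r, "lon"], ll[r, "lat"]))
      })
    })
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "MultiPolygon", coordinates = ring_ll),
      properties = list(dog_id = iso$dog_id %||% NA, level = iso$level,
                        total_area_ha = iso$total_area_ha))
    cc <- isopleth_centroids(iso)
    for (r in seq_len(nrow(cc))) {
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(cc$lon[r], cc$lat[r])),
        properties = list(dog_id = iso$dog_id %||% NA, level = iso$level,
                          polygon = cc$polygon[r], area_m2 = cc$area_m2[r]))
    }
  }
  obj <- list(type = "FeatureCollection", features = feats)
  if (!is.null(params)) obj$properties <- params
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
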