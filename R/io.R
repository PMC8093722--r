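#' Logger CSV dialect
#'
#' Column-name and timestamp-format mapping for a GPS logger export. The
#' default matches the files this package writes (`write_logger_csv()`):
#' `index, timestamp, latitude, longitude, elevation` with ISO 8601 times.
#' Deposited field exports with other headers are accommodated by overriding
#' the column names and format here rather than editing files.
#'
#' @param time_col,lat_col,lon_col column names in the CSV.
#' @param time_format a `strptime()` format string.
#' @param tz timezone of the logger clock; the study area uses East Africa
#'   Time (`"Africa/Nairobi"`).
#' @return a `logger_dialect` list.
#' @export
logger_dialect <- function(time_col = "timestamp",
                           lat_col = "latitude",
                           lon_col = "longitude",
                           time_format = "%Y-%m-%dT%H:%M:%S",
                           tz = "Africa/Nairobi") {
  structure(list(time_col = time_col, lat_col = lat_col, lon_col = lon_col,
                 time_format = time_format, tz = tz),
            class = "logger_dialect")
}

#' Read a per-dog logger CSV
#'
#' Parses one logger export into a [sampled_track]: timestamps are parsed in
#' the dialect's timezone, rows are sorted by time, and rows duplicating an
#' earlier timestamp are dropped (first occurrence kept, with a warning).
#'
#' @param path CSV file path.
#' @param dog_id identifier; defaults to the file name without extension.
#' @param dialect a [logger_dialect].
#' @param household optional named numeric `c(lon = , lat = )` household
#'   coordinates.
#' @return a [sampled_track] (not yet projected).
#' @export
read_logger_csv <- function(path, dog_id = NULL, dialect = logger_dialect(),
                            household = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(dog_id)) dog_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(dialect$time_col, dialect$lat_col, dialect$lon_col)
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  }
  ts <- as.POSIXct(raw[[dialect$time_col]], format = dialect$time_format,
                   tz = dialect$tz)
  if (anyNA(ts)) {
    stop("unparseable timestamp at row ", which(is.na(ts))[1],
         " of ", basename(path))
  }
  ord <- order(ts)
  ts <- ts[ord]
  lat <- raw[[dialect$lat_col]][ord]
  lon <- raw[[dialect$lon_col]][ord]
  dup <- duplicated(ts)
  if (any(dup)) {
    warning(sum(dup), " duplicate-timestamp fix(es) dropped for dog ", dog_id)
    ts <- ts[!dup]; lat <- lat[!dup]; lon <- lon[!dup]
  }
  if (!is.null(household)) {
    household <- c(lon = unname(household["lon"]),
                   lat = unname(household["lat"]))
  }
  sampled_track(dog_id,
                data.frame(timestamp = ts, lon = lon, lat = lat),
                household = household)
}

#' Write a track as a logger-dialect CSV
#'
#' Emits `index, timestamp, latitude, longitude, elevation` (RFC 4180,
#' ISO 8601 timestamps). The elevation column is a placeholder carried for
#' dialect compatibility.
#'
#' @param track a [sampled_track].
#' @param path output path.
#' @export
write_logger_csv <- function(track, path) {
  f <- track$fixes
  out <- data.frame(
    index = seq_len(nrow(f)),
    timestamp = format(f$timestamp, "%Y-%m-%dT%H:%M:%S",
                       tz = attr(f$timestamp, "tzone") %||% "Africa/Nairobi"),
    latitude = sprintf("%.9f", f$lat),
    longitude = sprintf("%.9f", f$lon),
    elevation = 0
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Project a track onto a planar UTM grid
#'
#' Fills the `x`, `y` columns (metres) of the track's fixes, and of its
#' household if geographic household coordinates are present, using the
#' configured UTM zone. Inverse projection recovers lon/lat to well below
#' 1e-6 degrees. Coordinates far outside the zone (more than ~6 degrees from
#' the central meridian) trigger a warning, not an error: distances remain
#' accurate to much better than 0.1% in adjacent zones.
#'
#' @param track a [sampled_track].
#' @param zone UTM zone (default taken from the track's `crs`).
#' @param north northern-hemisphere convention flag.
#' @return the track with planar coordinates filled.
#' @export
project_to_planar <- function(track, zone = track$crs$zone,
                              north = track$crs$north) {
  f <- track$fixes
  lon0 <- zone * 6 - 183
  if (any(abs(f$lon - lon0) > 6)) {
    warning("track dog ", track$dog_id, " extends > 6 degrees from the ",
            "central meridian of UTM zone ", zone)
  }
  xy <- utm_forward(f$lon, f$lat, zone = zone, north = north)
  track$fixes$x <- xy[, "x"]
  track$fixes$y <- xy[, "y"]
  hh <- track$household
  if (!is.null(hh) && all(c("lon", "lat") %in% names(hh))) {
    hxy <- utm_forward(hh[["lon"]], hh[["lat"]], zone = zone, north = north)
    track$household <- c(hh[c("lon", "lat")],
                         x = unname(hxy[, "x"]), y = unname(hxy[, "y"]))
  }
  track$crs <- list(zone = zone, north = north)
  track
}

#' Read a dog metadata table
#'
#' Questionnaire covariates keyed by `dog_id`. Categorical fields are checked
#' against their closed category sets and converted to factors with the
#' referent level first (intact male; age <1 yr; <2 h outside).
#'
#' @param path CSV with columns `dog_id, site, age_class, sex_status,
#'   reported_time_outside` and optionally `purpose, feeding_frequency,
#'   household_lon, household_lat`.
#' @return data.frame of metadata.
#' @export
read_metadata_csv <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dog_id", "site", "age_class", "sex_status",
            "reported_time_outside")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  levels_of <- list(
    age_class = c("<1 yr", "1-5 yr", ">5 yr"),
    sex_status = c("intact male", "castrated male",
                   "intact female", "spayed female"),
    reported_time_outside = c("<2 h", "2-6 h", ">6 h")
  )
  for (col in names(levels_of)) {
    bad <- setdiff(unique(md[[col]]), levels_of[[col]])
    if (length(bad)) {
      stop("unknown ", col, " value(s): ", paste(bad, collapse = ", "))
    }
    md[[col]] <- factor(md[[col]], levels = levels_of[[col]])
  }
  md$dog_id <- as.character(md$dog_id)
  md
}

`%||%` <- function(a, b) if (is.null(a)) b else a
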