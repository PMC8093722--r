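#' Construct a sampled GPS track
#'
#' A `sampled_track` bundles the ordered fixes of one dog with its household
#' location and the planar coordinate reference used downstream. Fixes carry
#' geographic coordinates (WGS84 decimal degrees) and, once projected, planar
#' easting/northing in metres.
#'
#' @param dog_id character scalar identifying the dog.
#' @param fixes data.frame with columns `timestamp` (POSIXct), `lon`, `lat`
#'   (decimal degrees) and optionally `x`, `y` (metres).
#' @param household named numeric with elements `lon`, `lat` and/or `x`, `y`;
#'   the household location.
#' @param crs list with `zone` (UTM zone) and `north` (logical); the planar
#'   reference.
#' @return an object of class `sampled_track`.
#' @export
sampled_track <- function(dog_id, fixes, household = NULL,
                          crs = list(zone = 36L, north = TRUE)) {
  stopifnot(is.data.frame(fixes), nrow(fixes) >= 1)
  if (!all(c("timestamp", "lon", "lat") %in% names(fixes))) {
    stop("`fixes` needs columns timestamp, lon, lat")
  }
  if (!inherits(fixes$timestamp, "POSIXct")) {
    stop("`fixes$timestamp` must be POSIXct")
  }
  bad_lat <- which(abs(fixes$lat) > 90)
  bad_lon <- which(abs(fixes$lon) > 180)
  if (length(bad_lat)) stop("latitude outside [-90, 90] at row ", bad_lat[1])
  if (length(bad_lon)) stop("longitude outside [-180, 180] at row ", bad_lon[1])
  if (is.unsorted(fixes$timestamp, strictly = TRUE)) {
    stop("fix timestamps must be strictly increasing")
  }
  if (!"x" %in% names(fixes)) fixes$x <- NA_real_
  if (!"y" %in% names(fixes)) fixes$y <- NA_real_
  structure(
    list(dog_id = as.character(dog_id), fixes = fixes,
         household = household, crs = crs),
    class = "sampled_track"
  )
}

#' @export
print.sampled_track <- function(x, ...) {
  n <- nrow(x$fixes)
  span <- if (n > 1) {
    sprintf("%.1f h", as.numeric(difftime(x$fixes$timestamp[n],
                                          x$fixes$timestamp[1], units = "hours")))
  } else "0 h"
  cat(sprintf("<sampled_track> dog %s: %d fixes spanning %s%s\n",
              x$dog_id, n, span,
              if (all(is.na(x$fixes$x))) " (not projected)" else ""))
  invisible(x)
}

#' Number of fixes in a track
#' @param x a `sampled_track`.
#' @export
n_fixes <- function(x) nrow(x$fixes)

#' Recording span of a track in hours
#'
#' Elapsed time between the first and last fix.
#' @param track a `sampled_track`.
#' @return hours (numeric scalar); 0 for a single-fix track.
#' @export
recording_hours <- function(track) {
  ts <- track$fixes$timestamp
  as.numeric(difftime(ts[length(ts)], ts[1], units = "hours"))
}

# planar step lengths (m) and durations (s) between consecutive fixes
.track_steps <- function(track) {
  f <- track$fixes
  if (any(is.na(f$x))) stop("track is not projected; call project_to_planar()")
  n <- nrow(f)
  if (n < 2) {
    return(data.frame(length_m = numeric(0), duration_s = numeric(0)))
  }
  data.frame(
    length_m = sqrt(diff(f$x)^2 + diff(f$y)^2),
    duration_s = as.numeric(diff(f$timestamp), units = "secs")
  )
}
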