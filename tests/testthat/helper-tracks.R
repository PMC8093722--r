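# build a projected track directly from planar coordinates (metres) and
# fix times (seconds from an arbitrary origin); geographic coordinates are
# derived by inverse projection so the object stays internally consistent
make_track <- function(x, y, t_s, dog_id = "toy", zone = 36L,
                       household = NULL) {
  ll <- utm_inverse(x, y, zone = zone)
  fixes <- data.frame(
    timestamp = as.POSIXct("2017-05-15 08:00:00", tz = "Africa/Nairobi") +
      t_s,
    lon = ll[, "lon"], lat = ll[, "lat"], x = x, y = y)
  hh <- NULL
  if (!is.null(household)) {
    hll <- utm_inverse(household[1], household[2], zone = zone)
    hh <- c(lon = unname(hll[, "lon"]), lat = unname(hll[, "lat"]),
            x = unname(household[1]), y = unname(household[2]))
  }
  sampled_track(dog_id, fixes, household = hh,
                crs = list(zone = zone, north = TRUE))
}

# a two-fix stand-in track spanning `hours`, for exclusion-rule tests
span_track <- function(hours, dog_id) {
  make_track(x = c(622000, 622010), y = c(50000, 50010),
             t_s = c(0, hours * 3600), dog_id = dog_id)
}

# construct a ud_grid by hand from a mass matrix (rows index y ascending)
manual_ud <- function(mass, cell_size = 10, xmin = 0, ymin = 0) {
  structure(list(xmin = xmin, ymin = ymin, cell_size = cell_size,
                 n_rows = nrow(mass), n_cols = ncol(mass),
                 mass = mass / sum(mass),
                 crs = list(zone = 36L, north = TRUE), dog_id = "manual",
                 params = NULL),
            class = "ud_grid")
}
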