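fake_summaries <- function(values) {
  do.call(rbind, lapply(names(values), function(id) {
    v <- values[[id]]
    data.frame(dog_id = id, daily_distance_km = v[1], total_distance_km = 5,
               core_hr_ha = v[2], extended_hr_ha = v[3],
               pct_time_household = v[4], recording_hours = 120,
               fixes_per_hour = 20)
  }))
}

test_that("site summaries reduce to medians per site plus an overall row", {
  vals <- list(a = c(10, 0.2, 5, 30), b = c(12, 0.4, 8, 40),
               c = c(14, 0.6, 11, 50))
  sm <- fake_summaries(vals)
  md <- data.frame(dog_id = c("a", "b", "c"),
                   site = c("s1", "s2", "s2"))
  out <- site_summary(sm, md)
  expect_equal(nrow(out), 3)  # two sites + overall
  # a one-dog site reports that dog's values
  s1 <- out[out$site == "s1", ]
  expect_equal(s1$median_daily_distance_km, 10)
  expect_equal(s1$n_dogs, 1)
  # a two-dog site gets the midpoint, the overall row the middle dog
  s2 <- out[out$site == "s2", ]
  expect_equal(s2$median_daily_distance_km, 13)
  ov <- out[out$site == "Overall", ]
  expect_equal(ov$n_dogs, 3)
  expect_equal(ov$median_daily_distance_km, 12)
  expect_equal(ov$median_core_hr_ha, 0.4)
  expect_equal(ov$median_pct_time_household, 40)
})

test_that("table medians survive a CSV round-trip exactly", {
  vals <- list(a = c(13.47, 0.39, 9.3, 31.91), b = c(11.2, 0.25, 4.6, 45.7),
               c = c(16.03, 0.49, 11.38, 33.94))
  sm <- fake_summaries(vals)
  md <- data.frame(dog_id = c("a", "b", "c"), site = "s1")
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(sm, p, row.names = FALSE)
  out <- site_summary(read.csv(p, stringsAsFactors = FALSE), md)
  expect_identical(out, site_summary(sm, md))
})

test_that("the centroid inventory keeps the surveyed levels only", {
  res <- simulate_track(sim_config(seed = 9, deployment_hours = 12))
  ud <- compute_brb_ud(clean_track(res$track)$track)
  isos <- lapply(c(10, 50, 90, 95), function(l) extract_isopleth(ud, l))
  rec <- centroid_records(list(dog009 = isos))
  expect_true(all(rec$level %in% c(10, 50, 90)))
  expect_true(all(rec$label == ""))
  expect_true(all(c("lon", "lat", "area_m2") %in% names(rec)))
  # one record per polygon at each level
  expect_equal(sum(rec$level == 50),
               isos[[2]]$n_polygons)
})

test_that("centroid overlap flags dog pairs at shared locations", {
  rec <- data.frame(
    dog_id = c("a", "b", "c", "c"),
    level = c(50, 50, 50, 90), polygon = 1,
    x = c(1000, 1000, 1049, 5000),
    y = c(2000, 2000, 2000, 9000),
    area_m2 = 100, label = "")
  out <- centroid_overlap(rec, distance_threshold = 50)
  pairs <- paste(out$dog_a, out$dog_b)
  expect_true("a b" %in% pairs)       # identical centroids, distance 0
  expect_equal(out$distance_m[pairs == "a b"], 0)
  expect_true(all(c("a c", "b c") %in% pairs))  # 49 m apart: flagged
  expect_equal(nrow(out), 3)          # the 5000/9000 centroid pairs with no one
  # 51 m apart: not flagged
  rec2 <- rec[1:3, ]
  rec2$x[3] <- 1051
  out2 <- centroid_overlap(rec2, distance_threshold = 50)
  expect_false(any(paste(out2$dog_a, out2$dog_b) %in% c("a c", "b c")))
  expect_error(centroid_overlap(rec[1, , drop = FALSE]), "2 dogs")
})

test_that("three dogs sharing one site produce all three pairs", {
  shared <- c(x = 3000, y = 4000)
  rec <- do.call(rbind, lapply(c("d1", "d2", "d3"), function(id) {
    data.frame(dog_id = id, level = 50, polygon = 1,
               x = shared["x"] + runif(1, -10, 10),
               y = shared["y"] + runif(1, -10, 10), area_m2 = 50, label = "")
  }))
  out <- centroid_overlap(rec, distance_threshold = 50)
  expect_equal(nrow(out), 3)  # C(3,2)
  expect_true(all(out$distance_m <= 50))
})

test_that("UD rasters export as valid ESRI ASCII grids", {
  res <- simulate_track(sim_config(seed = 2, deployment_hours = 6))
  ud <- compute_brb_ud(clean_track(res$track)$track,
                       brb_params(cell_size = 40))
  p <- withr::local_tempfile(fileext = ".asc")
  write_ud_asc(ud, p)
  hdr <- readLines(p, n = 6)
  expect_match(hdr[1], "^ncols")
  vals <- scan(p, skip = 6, quiet = TRUE)
  expect_length(vals, ud$n_rows * ud$n_cols)
  expect_equal(sum(vals), 1, tolerance = 1e-6)
  # first data row is the northernmost grid row
  expect_equal(matrix(vals, ud$n_rows, ud$n_cols, byrow = TRUE)[1, ],
               unname(ud$mass[ud$n_rows, ]), tolerance = 1e-6)
})

test_that("isopleths and centroids export as GeoJSON features", {
  res <- simulate_track(sim_config(seed = 2, deployment_hours = 6))
  ud <- compute_brb_ud(clean_track(res$track)$track)
  isos <- lapply(c(50, 95), function(l) extract_isopleth(ud, l))
  p <- withr::local_tempfile(fileext = ".geojson")
  write_isopleth_geojson(isos, p, params = list(hmin = 25))
  gj <- jsonlite::read_json(p)
  expect_equal(gj$type, "FeatureCollection")
  n_centroids <- sum(vapply(isos, function(i) i$n_polygons, 0L))
  expect_length(gj$features, 2 + n_centroids)
  types <- vapply(gj$features, function(f) f$geometry$type, "")
  expect_equal(sum(types == "MultiPolygon"), 2)
  expect_equal(gj$properties$hmin, 25)
})
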