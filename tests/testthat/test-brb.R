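test_that("the plug-in diffusion estimate matches its closed form", {
  # every step 20 m in 60 s: D = 400 / 240
  tr <- make_track(x = 6e5 + seq(0, 200, by = 20), y = rep(5e4, 11),
                   t_s = seq(0, 600, by = 60))
  expect_equal(estimate_diffusion(tr), 400 / 240, tolerance = 1e-12)
  # all steps below Lmin: no movement to estimate from
  still <- make_track(x = 6e5 + cumsum(rep(1, 6)), y = rep(5e4, 6),
                      t_s = seq(0, 300, by = 60))
  expect_error(estimate_diffusion(still), "diffusion_D")
})

test_that("diffusion recovery on weakly-reverting tracks is within 2x", {
  D_true <- 0.5
  est <- vapply(1:30, function(s) {
    r <- simulate_track(sim_config(
      seed = s, deployment_hours = 6, diffusion_true = D_true,
      home_attraction_rate = 5e-4, attraction_sites = list(),
      move_speed_threshold = 0, gps_noise_sd = 0,
      rest_mean_s = 600, travel_mean_s = 3000))
    estimate_diffusion(r$track, brb_params(Tmax = 120))
  }, 0)
  expect_gt(mean(est), D_true / 2)
  expect_lt(mean(est), D_true * 2)
})

test_that("a single-fix track yields an isotropic Gaussian of sd hmin", {
  tr <- make_track(6e5, 5e4, 0)
  prm <- brb_params(diffusion_D = 1, Tmax = 300, cell_size = 10,
                    extent_pad = 200)
  ud <- compute_brb_ud(tr, prm)
  expect_equal(sum(ud$mass), 1, tolerance = 1e-9)
  xc <- ud$xmin + (seq_len(ud$n_cols) - 0.5) * ud$cell_size
  yc <- ud$ymin + (seq_len(ud$n_rows) - 0.5) * ud$cell_size
  ref <- tcrossprod(dnorm(yc, 5e4, prm$hmin), dnorm(xc, 6e5, prm$hmin))
  expect_lt(max(abs(ud$mass - ref / sum(ref))), 1e-12)
})

test_that("the grid builder agrees with brute-force kernel summation", {
  prm <- brb_params(diffusion_D = 0.8, Tmax = 200, hmin = 25,
                    Lmin = 5, cell_size = 20, extent_pad = 140,
                    n_substeps = 10)
  # 3-fix track: two bridged steps
  t3 <- make_track(x = 6e5 + c(0, 60, 90), y = 5e4 + c(0, 20, -30),
                   t_s = c(0, 60, 150))
  # 5-fix track mixing bridged, short (< Lmin) and long-gap (> Tmax) steps
  t5 <- make_track(x = 6e5 + c(0, 50, 52, 110, 115),
                   y = 5e4 + c(0, 30, 31, -20, 60),
                   t_s = c(0, 60, 120, 600, 660))
  for (tr in list(t3, t5)) {
    ud <- compute_brb_ud(tr, prm)
    expect_lte(ud$n_rows * ud$n_cols, 400)
    expect_lt(max(abs(ud$mass - oracle_brb_ud(tr, prm))), 1e-10)
    expect_equal(sum(ud$mass), 1, tolerance = 1e-9)
  }
})

test_that("a stationary track reproduces the Gaussian isopleth-area ratio", {
  # all mass in one kernel of sd hmin: area(p) = 2 pi sigma^2 ln(1/(1-p)),
  # so the 95/50 area ratio is ln 20 / ln 2
  tr <- make_track(x = rep(6e5, 8), y = rep(5e4, 8),
                   t_s = seq(0, 420, by = 60))
  prm <- brb_params(diffusion_D = 0.5, hmin = 25, Tmax = 300,
                    cell_size = 5, extent_pad = 200)
  ud <- compute_brb_ud(tr, prm)
  ratio <- extract_isopleth(ud, 95)$total_area_ha /
    extract_isopleth(ud, 50)$total_area_ha
  expect_equal(ratio, log(20) / log(2), tolerance = 0.05)
})

test_that("isopleth selection handles uniform mass and the 100% level", {
  ud <- manual_ud(matrix(1, 10, 10), cell_size = 10)
  iso50 <- extract_isopleth(ud, 50)
  expect_equal(nrow(iso50$cells), 50)
  expect_equal(iso50$total_area_ha, 50 * 100 / 1e4)
  iso100 <- extract_isopleth(ud, 100)
  expect_equal(nrow(iso100$cells), 100)
  expect_error(extract_isopleth(ud, 0), "level")
  expect_error(extract_isopleth(ud, 101), "level")
})

test_that("isopleths nest and areas grow with the probability level", {
  res <- simulate_track(sim_config(seed = 14, deployment_hours = 18))
  ud <- compute_brb_ud(clean_track(res$track)$track)
  levels <- c(10, 50, 90, 95)
  isos <- lapply(levels, function(l) extract_isopleth(ud, l))
  keys <- lapply(isos, function(i) paste(i$cells$row, i$cells$col))
  for (k in 1:3) {
    expect_true(all(keys[[k]] %in% keys[[k + 1]]))
  }
  areas <- vapply(isos, function(i) i$total_area_ha, 0)
  expect_true(all(diff(areas) > 0))
})

test_that("halving the cell size leaves isopleth areas nearly unchanged", {
  res <- simulate_track(sim_config(seed = 6, deployment_hours = 12))
  tr <- clean_track(res$track)$track
  a10 <- homerange_areas(tr, brb_params(cell_size = 10))
  a5 <- homerange_areas(tr, brb_params(cell_size = 5))
  expect_lt(abs(a5["50"] - a10["50"]) / a10["50"], 0.05)
  expect_lt(abs(a5["95"] - a10["95"]) / a10["95"], 0.05)
})

test_that("polygon centroids are arithmetic means of member cells", {
  # one 2x2 square block: centroid at its geometric centre
  m <- matrix(1e-9, 8, 8)
  m[3:4, 3:4] <- 1
  ud <- manual_ud(m, cell_size = 10)
  iso <- extract_isopleth(ud, 90)
  expect_equal(iso$n_polygons, 1)
  cc <- isopleth_centroids(iso)
  expect_equal(cc$x, 30)  # cells centred at 25 and 35
  expect_equal(cc$y, 30)
  # two disjoint blocks: two polygons, two centroids
  m2 <- matrix(1e-9, 8, 8)
  m2[2, 2] <- 1
  m2[7, 7] <- 1
  iso2 <- extract_isopleth(manual_ud(m2, cell_size = 10), 90)
  expect_equal(iso2$n_polygons, 2)
  expect_equal(nrow(isopleth_centroids(iso2)), 2)
  # L-shape of cells centred at (0,0), (10,0), (0,10)
  m3 <- matrix(1e-9, 4, 4)
  m3[1, 1] <- 1; m3[1, 2] <- 1; m3[2, 1] <- 1
  iso3 <- extract_isopleth(manual_ud(m3, cell_size = 10, xmin = -5,
                                     ymin = -5), 90)
  cc3 <- isopleth_centroids(iso3)
  expect_equal(iso3$n_polygons, 1)
  expect_equal(cc3$x, 10 / 3, tolerance = 1e-9)
  expect_equal(cc3$y, 10 / 3, tolerance = 1e-9)
  # diagonal-touching cells are separate polygons (4-connectivity)
  m4 <- matrix(1e-9, 4, 4)
  m4[1, 1] <- 1; m4[2, 2] <- 1
  expect_equal(extract_isopleth(manual_ud(m4), 90)$n_polygons, 2)
})

test_that("boundary rings close and enclose the right area", {
  m <- matrix(1e-9, 6, 6)
  m[2, 2] <- 1
  iso <- extract_isopleth(manual_ud(m, cell_size = 10), 90)
  ring <- iso$rings[[1]][[1]]
  expect_equal(ring[1, ], ring[nrow(ring), ])  # closed
  # shoelace area of a single 10 m cell
  xs <- ring[-1, 1]; ys <- ring[-1, 2]
  n <- length(xs)
  area <- abs(sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)) / 2
  expect_equal(area, 100)
})

test_that("oversized grids are refused with advice", {
  tr <- make_track(x = c(6e5, 6e5 + 5e4), y = c(5e4, 5e4), t_s = c(0, 60))
  expect_error(compute_brb_ud(tr, brb_params(cell_size = 1, diffusion_D = 1,
                                             max_cells = 1e5)),
               "cell_size")
})
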