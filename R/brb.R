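#' Parameters of the movement-based (biased random bridge) UD estimator
#'
#' The utilization distribution is built by spreading Gaussian kernel mass
#' along the straight segment joining each pair of successive fixes. At
#' interpolation fraction `p` along a step of duration `T`, the kernel
#' variance is `hmin^2 + 4 * D * T * p * (1 - p)`: zero extra spread at the
#' fixes themselves (where the animal's position is known up to GPS error
#' `hmin`) and maximal mid-step, the Brownian-bridge scaling. Steps longer
#' than `Tmax` in time are not bridged (the interpolation is no longer
#' credible across a long gap) and steps shorter than `Lmin` are treated as
#' resting; both deposit their time weight at their endpoints with variance
#' `hmin^2`.
#'
#' @param diffusion_D movement diffusion coefficient, m^2/s; `NULL` to
#'   estimate it from the track with [estimate_diffusion()].
#' @param hmin minimum smoothing, m (GPS error scale).
#' @param Tmax maximum bridged step duration, s; `NULL` for 3x the median
#'   fix interval of the track.
#' @param Lmin minimum step length treated as movement, m.
#' @param cell_size raster cell side, m.
#' @param extent_pad padding added around the track bounding box, m.
#' @param n_substeps interpolation points per bridged step.
#' @param max_cells guard on grid size.
#' @return a `brb_params` list.
#' @export
brb_params <- function(diffusion_D = NULL, hmin = 25, Tmax = NULL,
                       Lmin = 5, cell_size = 10, extent_pad = 200,
                       n_substeps = 10, max_cells = 4e6) {
  for (v in c(hmin, Lmin, cell_size, extent_pad, n_substeps, max_cells)) {
    if (!is.finite(v) || v <= 0) stop("brb_params values must be positive")
  }
  if (!is.null(diffusion_D) && (!is.finite(diffusion_D) || diffusion_D < 0)) {
    stop("diffusion_D must be >= 0")
  }
  if (!is.null(Tmax) && (!is.finite(Tmax) || Tmax <= 0)) {
    stop("Tmax must be > 0")
  }
  if (cell_size > extent_pad) stop("cell_size must not exceed extent_pad")
  structure(list(diffusion_D = diffusion_D, hmin = hmin, Tmax = Tmax,
                 Lmin = Lmin, cell_size = cell_size,
                 extent_pad = extent_pad,
                 n_substeps = as.integer(n_substeps),
                 max_cells = max_cells),
            class = "brb_params")
}

.resolve_tmax <- function(track, params) {
  if (!is.null(params$Tmax)) return(params$Tmax)
  st <- .track_steps(track)
  if (nrow(st) == 0) return(Inf)
  3 * stats::median(st$duration_s)
}

#' Plug-in diffusion estimate from a cleaned track
#'
#' For each qualifying step (duration at most `Tmax`, length at least
#' `Lmin`), the squared displacement over elapsed time gives a local
#' diffusion estimate `L^2 / (4 T)`; the plug-in estimator is their mean.
#' It is biased low for strongly mean-reverting motion, but sets the
#' smoothing scale of the bridge kernel adequately.
#'
#' @param track cleaned, projected [sampled_track].
#' @param params a [brb_params].
#' @return diffusion coefficient in m^2/s.
#' @export
estimate_diffusion <- function(track, params = brb_params()) {
  st <- .track_steps(track)
  tmax <- .resolve_tmax(track, params)
  ok <- st$duration_s > 0 & st$duration_s <= tmax & st$length_m >= params$Lmin
  if (!any(ok)) {
    stop("no steps qualify for diffusion estimation (all shorter than Lmin ",
         "or longer than Tmax); supply a fixed diffusion_D in brb_params()")
  }
  mean(st$length_m[ok]^2 / (4 * st$duration_s[ok]))
}

# deposit table for a track: one row per Gaussian kernel
# (x, y, sigma2, weight); shared by the grid builder and the test oracle
.brb_deposits <- function(track, params) {
  f <- track$fixes
  n <- nrow(f)
  if (n == 1) {
    return(data.frame(x = f$x, y = f$y, sigma2 = params$hmin^2, w = 1))
  }
  D <- params$diffusion_D
  if (is.null(D)) D <- estimate_diffusion(track, params)
  tmax <- .resolve_tmax(track, params)
  st <- .track_steps(track)
  out <- vector("list", nrow(st))
  p <- (seq_len(params$n_substeps) - 0.5) / params$n_substeps
  for (i in seq_len(nrow(st))) {
    Tt <- st$duration_s[i]
    if (Tt <= tmax && st$length_m[i] >= params$Lmin) {
      out[[i]] <- data.frame(
        x = f$x[i] + p * (f$x[i + 1] - f$x[i]),
        y = f$y[i] + p * (f$y[i + 1] - f$y[i]),
        sigma2 = params$hmin^2 + 4 * D * Tt * p * (1 - p),
        w = Tt / params$n_substeps)
    } else {
      out[[i]] <- data.frame(
        x = f$x[c(i, i + 1)], y = f$y[c(i, i + 1)],
        sigma2 = params$hmin^2, w = Tt / 2)
    }
  }
  do.call(rbind, out)
}

#' Compute the biased-random-bridge utilization distribution
#'
#' Deposits the bridge kernels of [brb_params()] onto a regular raster
#' covering the track's bounding box plus `extent_pad`, evaluates each
#' Gaussian at cell centres, and normalizes total mass to 1. The result is
#' a time-weighted probability raster: cells where the dog spent long
#' stationary gaps carry correspondingly large mass.
#'
#' @param track cleaned, projected [sampled_track].
#' @param params a [brb_params].
#' @return a `ud_grid`: `xmin`, `ymin` (grid corner), `cell_size`,
#'   `n_rows`, `n_cols`, `mass` (matrix, rows indexing y ascending), `crs`,
#'   and the resolved parameter values in `params`.
#' @export
compute_brb_ud <- function(track, params = brb_params()) {
  f <- track$fixes
  if (nrow(f) < 1) stop("empty track")
  if (any(is.na(f$x))) stop("track is not projected")
  cs <- params$cell_size
  xmin <- floor((min(f$x) - params$extent_pad) / cs) * cs
  ymin <- floor((min(f$y) - params$extent_pad) / cs) * cs
  xmax <- ceiling((max(f$x) + params$extent_pad) / cs) * cs
  ymax <- ceiling((max(f$y) + params$extent_pad) / cs) * cs
  n_cols <- as.integer(round((xmax - xmin) / cs))
  n_rows <- as.integer(round((ymax - ymin) / cs))
  if (as.double(n_rows) * n_cols > params$max_cells) {
    stop("grid would have ", n_rows, " x ", n_cols, " cells; increase ",
         "cell_size or max_cells")
  }
  dep <- .brb_deposits(track, params)
  if (is.null(params$diffusion_D)) {
    params$diffusion_D <- if (nrow(f) > 1) estimate_diffusion(track, params)
                          else 0
  }
  params$Tmax <- .resolve_tmax(track, params)

  xc <- xmin + (seq_len(n_cols) - 0.5) * cs
  yc <- ymin + (seq_len(n_rows) - 0.5) * cs
  mass <- matrix(0, n_rows, n_cols)
  trunc_sd <- 8  # Gaussian support truncated at 8 sd: tail < 1e-14
  for (i in seq_len(nrow(dep))) {
    s <- sqrt(dep$sigma2[i])
    jx <- which(abs(xc - dep$x[i]) <= trunc_sd * s)
    jy <- which(abs(yc - dep$y[i]) <= trunc_sd * s)
    if (!length(jx) || !length(jy)) next
    mass[jy, jx] <- mass[jy, jx] +
      dep$w[i] * tcrossprod(stats::dnorm(yc[jy], dep$y[i], s),
                            stats::dnorm(xc[jx], dep$x[i], s))
  }
  tot <- sum(mass)
  if (tot <= 0) stop("all kernel mass fell outside the grid")
  structure(list(xmin = xmin, ymin = ymin, cell_size = cs,
                 n_rows = n_rows, n_cols = n_cols, mass = mass / tot,
                 crs = track$crs, dog_id = track$dog_id, params = params),
            class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf("<ud_grid> %d x %d cells of %g m (dog %s), mass sum %.6f\n",
              x$n_rows, x$n_cols, x$cell_size, x$dog_id %||% "?",
              sum(x$mass)))
  invisible(x)
}

#' Extract an isopleth (volume contour) from a UD
#'
#' Cells are ranked by probability mass, descending, and the smallest set
#' whose cumulative mass reaches `level`% is selected (ties resolved in
#' row-major order for determinism). Selected cells are merged into
#' disjoint polygons under 4-connectivity; diagonal-touching cells remain
#' separate polygons, a conservative choice for centroid counts. The area
#' is the selected cell count times the cell area.
#'
#' @param ud a `ud_grid`.
#' @param level percentage in (0, 100); 50 gives the core home range, 95
#'   the extended one.
#' @return an `isopleth_set`: `level`, `cells` (data.frame `row`, `col`,
#'   `x`, `y`, `polygon`), `n_polygons`, `polygon_areas_m2`,
#'   `centroids` (matrix `x`, `y`, one row per polygon), `total_area_ha`,
#'   `rings` (list of polygon outlines, each a list of closed coordinate
#'   matrices, outer ring first), `cell_size`, `crs`.
#' @export
extract_isopleth <- function(ud, level) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level > 100) {
    stop("level must be a single percentage in (0, 100]")
  }
  # row-major flattening so that ties break along rows then columns
  v <- as.vector(t(ud$mass))
  ord <- order(-v)             # stable: ties keep row-major order
  k <- which(cumsum(v[ord]) >= level / 100)[1]
  if (is.na(k)) k <- length(v)
  sel <- ord[seq_len(k)]
  row <- (sel - 1L) %/% ud$n_cols + 1L
  col <- (sel - 1L) %% ud$n_cols + 1L

  member <- matrix(FALSE, ud$n_rows, ud$n_cols)
  member[cbind(row, col)] <- TRUE
  lab <- .label_components(member)
  poly_id <- lab[cbind(row, col)]

  cells <- data.frame(
    row = row, col = col,
    x = ud$xmin + (col - 0.5) * ud$cell_size,
    y = ud$ymin + (row - 0.5) * ud$cell_size,
    polygon = poly_id)
  np <- max(poly_id)
  centroids <- t(vapply(seq_len(np), function(pn) {
    c(x = mean(cells$x[cells$polygon == pn]),
      y = mean(cells$y[cells$polygon == pn]))
  }, c(x = 0, y = 0)))
  areas <- as.vector(table(factor(poly_id, levels = seq_len(np)))) *
    ud$cell_size^2
  rings <- lapply(seq_len(np), function(pn) {
    .trace_rings(lab == pn, ud$xmin, ud$ymin, ud$cell_size)
  })
  structure(list(level = level, cells = cells, n_polygons = np,
                 polygon_areas_m2 = areas,
                 centroids = centroids,
                 total_area_ha = nrow(cells) * ud$cell_size^2 / 1e4,
                 rings = rings, cell_size = ud$cell_size,
                 crs = ud$crs, dog_id = ud$dog_id),
            class = "isopleth_set")
}

#' @export
print.isopleth_set <- function(x, ...) {
  cat(sprintf("<isopleth_set> %g%%: %.3f ha in %d polygon(s)\n",
              x$level, x$total_area_ha, x$n_polygons))
  invisible(x)
}

#' Centroids of the polygons of an isopleth
#'
#' One centroid per polygon, the unweighted arithmetic mean of its member
#' cell centres, reported in planar metres and (when the isopleth carries a
#' coordinate reference) in WGS84 degrees.
#'
#' @param iso an `isopleth_set`.
#' @return data.frame with one row per polygon: `polygon`, `x`, `y`,
#'   `area_m2`, and `lon`, `lat` when a CRS is available. Zero rows for an
#'   empty polygon set.
#' @export
isopleth_centroids <- function(iso) {
  if (iso$n_polygons == 0 || nrow(iso$cells) == 0) {
    return(data.frame(polygon = integer(0), x = numeric(0), y = numeric(0),
                      area_m2 = numeric(0)))
  }
  out <- data.frame(polygon = seq_len(iso$n_polygons),
                    x = iso$centroids[, "x"], y = iso$centroids[, "y"],
                    area_m2 = iso$polygon_areas_m2)
  if (!is.null(iso$crs)) {
    ll <- utm_inverse(out$x, out$y, zone = iso$crs$zone,
                      north = iso$crs$north)
    out$lon <- ll[, "lon"]
    out$lat <- ll[, "lat"]
  }
  out
}

#' Core and extended home-range areas of a track
#'
#' Convenience wrapper: estimates the UD and returns isopleth areas in
#' hectares at the requested levels.
#'
#' @param track cleaned, projected [sampled_track].
#' @param params a [brb_params].
#' @param levels isopleth percentages.
#' @return named numeric of areas (ha), names like `"50"`, `"95"`.
#' @export
homerange_areas <- function(track, params = brb_params(),
                            levels = c(50, 95)) {
  ud <- compute_brb_ud(track, params)
  vapply(levels, function(l) extract_isopleth(ud, l)$total_area_ha,
         0, USE.NAMES = FALSE) |>
    stats::setNames(as.character(levels))
}

# 4-connected component labelling of a logical matrix (iterative flood fill)
.label_components <- function(member) {
  lab <- matrix(0L, nrow(member), ncol(member))
  nxt <- 0L
  idx <- which(member)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    nr <- nrow(member)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L),
                      c(i, j + 1L))) {
        if (nb[1] >= 1L && nb[1] <= nr && nb[2] >= 1L &&
            nb[2] <= ncol(member)) {
          lin <- (nb[2] - 1L) * nr + nb[1]
          if (member[lin] && lab[lin] == 0L) {
            lab[lin] <- nxt
            queue <- c(queue, lin)
          }
        }
      }
    }
  }
  lab
}

# boundary rings of a cell mask: collects cell edges not shared by two
# selected cells, directed with the interior on the left, and chains them
# into closed loops (outer rings counter-clockwise, holes clockwise)
.trace_rings <- function(mask, xmin, ymin, cs) {
  nr <- nrow(mask); nc <- ncol(mask)
  sel <- which(mask, arr.ind = TRUE)
  segs <- list()
  for (r in seq_len(nrow(sel))) {
    i <- sel[r, 1]; j <- sel[r, 2]
    x0 <- j - 1L; x1 <- j; y0 <- i - 1L; y1 <- i   # lattice coords
    if (i == 1L || !mask[i - 1L, j]) segs[[length(segs) + 1L]] <-
        c(x0, y0, x1, y0)                           # south edge, east-going
    if (j == nc || !mask[i, j + 1L]) segs[[length(segs) + 1L]] <-
        c(x1, y0, x1, y1)                           # east edge, north-going
    if (i == nr || !mask[i + 1L, j]) segs[[length(segs) + 1L]] <-
        c(x1, y1, x0, y1)                           # north edge, west-going
    if (j == 1L || !mask[i, j - 1L]) segs[[length(segs) + 1L]] <-
        c(x0, y1, x0, y0)                           # west edge, south-going
  }
  if (!length(segs)) return(list())
  segm <- do.call(rbind, segs)
  key <- paste(segm[, 1], segm[, 2])
  used <- rep(FALSE, nrow(segm))
  rings <- list()
  for (s0 in seq_len(nrow(segm))) {
    if (used[s0]) next
    path <- segm[s0, 1:2, drop = TRUE]
    cur <- s0
    repeat {
      used[cur] <- TRUE
      nxt_v <- segm[cur, 3:4]
      path <- rbind(path, nxt_v)
      cand <- which(!used & key == paste(nxt_v[1], nxt_v[2]))
      if (!length(cand)) break
      if (length(cand) > 1) {
        # diagonal pinch point: prefer the sharpest right turn so rings
        # stay simple; deterministic by construction
        din <- segm[cur, 3:4] - segm[cur, 1:2]
        cross <- vapply(cand, function(cc) {
          dout <- segm[cc, 3:4] - segm[cc, 1:2]
          din[1] * dout[2] - din[2] * dout[1]
        }, 0)
        cand <- cand[which.min(cross)]
      }
      cur <- cand[1]
    }
    rings[[length(rings) + 1L]] <-
      cbind(x = xmin + path[, 1] * cs, y = ymin + path[, 2] * cs)
  }
  rings
}
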