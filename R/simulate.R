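#' Configuration for a simulated dog trajectory
#'
#' Describes the data-generating model used to emulate a free-roaming dog
#' wearing a motion-triggered GPS logger. The dog alternates between resting
#' bouts (stationary, so the logger records nothing) and travelling bouts in
#' which it follows an Ornstein--Uhlenbeck pull towards a target: either its
#' household or one of a set of attraction sites (other compounds, fields,
#' rubbish dumps), chosen with probability proportional to the attraction
#' weights. Fixes are emitted on a regular nominal schedule but only when the
#' displacement rate over the preceding interval exceeds
#' `move_speed_threshold`, reproducing motion-triggered logging and its
#' informative gaps.
#'
#' @param household_center planar household coordinates `c(x =, y =)` in
#'   metres. The default sits at the UTM zone-36 image of a point in Busia
#'   county, western Kenya.
#' @param attraction_sites list of `list(center = c(x =, y =), weight = w)`;
#'   `list()` gives a home-pinned dog that only roams around its household.
#' @param home_weight attraction weight of the household itself.
#' @param home_attraction_rate OU mean-reversion rate towards the current
#'   target, 1/s. `Inf` pins the dog at its target exactly.
#' @param diffusion_true OU diffusion coefficient, m^2/s.
#' @param deployment_hours collar deployment length, h (the study deployed
#'   for five days).
#' @param fix_interval nominal logging interval, s (1 fix/min in the study).
#' @param move_speed_threshold displacement rate (m/s) below which the
#'   logger stays silent.
#' @param gps_noise_sd isotropic GPS error standard deviation, m.
#' @param outlier_rate per-fix probability of a spurious jump (default 0).
#' @param outlier_jump displacement of a spurious fix, m.
#' @param rest_mean_s,travel_mean_s mean duration of resting and travelling
#'   bouts, s (exponential clocks).
#' @param seed integer seed; identical configs give bit-identical output.
#' @param start_time POSIXct deployment start.
#' @param zone,north UTM zone used to report geographic coordinates.
#' @param sim_dt integration step of the continuous-time path, s; must divide
#'   `fix_interval`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(household_center = c(x = 622511, y = 50855),
                       attraction_sites = list(
                         list(center = c(x = 622511 + 425, y = 50855 + 162),
                              weight = 0.45),
                         list(center = c(x = 622511 - 340, y = 50855 + 493),
                              weight = 0.35)
                       ),
                       home_weight = 0.55,
                       home_attraction_rate = 0.01,
                       diffusion_true = 0.5,
                       deployment_hours = 120,
                       fix_interval = 60,
                       move_speed_threshold = 0.12,
                       gps_noise_sd = 1.5,
                       outlier_rate = 0,
                       outlier_jump = 1000,
                       rest_mean_s = 1700,
                       travel_mean_s = 1300,
                       seed = 1L,
                       start_time = as.POSIXct("2017-05-15 08:00:00",
                                               tz = "Africa/Nairobi"),
                       zone = 36L, north = TRUE,
                       sim_dt = 5) {
  cfg <- list(household_center = household_center,
              attraction_sites = attraction_sites,
              home_weight = home_weight,
              home_attraction_rate = home_attraction_rate,
              diffusion_true = diffusion_true,
              deployment_hours = deployment_hours,
              fix_interval = fix_interval,
              move_speed_threshold = move_speed_threshold,
              gps_noise_sd = gps_noise_sd,
              outlier_rate = outlier_rate,
              outlier_jump = outlier_jump,
              rest_mean_s = rest_mean_s,
              travel_mean_s = travel_mean_s,
              seed = as.integer(seed),
              start_time = start_time,
              zone = zone, north = north,
              sim_dt = sim_dt)
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  num <- c(cfg$household_center, cfg$home_weight,
           cfg$diffusion_true, cfg$deployment_hours, cfg$fix_interval,
           cfg$move_speed_threshold, cfg$gps_noise_sd, cfg$outlier_rate,
           cfg$outlier_jump, cfg$rest_mean_s, cfg$travel_mean_s, cfg$sim_dt)
  if (any(!is.finite(num))) stop("non-finite value in sim_config")
  if (!(is.finite(cfg$home_attraction_rate) ||
        is.infinite(cfg$home_attraction_rate)) ||
      is.na(cfg$home_attraction_rate) || cfg$home_attraction_rate < 0) {
    stop("home_attraction_rate must be a nonnegative rate (Inf allowed)")
  }
  if (cfg$deployment_hours <= 0) stop("deployment_hours must be > 0")
  if (cfg$fix_interval <= 0) stop("fix_interval must be > 0")
  if (cfg$outlier_rate < 0 || cfg$outlier_rate >= 1) {
    stop("outlier_rate must lie in [0, 1)")
  }
  if (cfg$diffusion_true < 0) stop("diffusion_true must be >= 0")
  for (s in cfg$attraction_sites) {
    if (!is.finite(s$weight) || s$weight < 0) {
      stop("attraction weights must be finite and >= 0")
    }
    if (any(!is.finite(s$center))) stop("non-finite attraction site center")
  }
  if (cfg$fix_interval %% cfg$sim_dt != 0) {
    stop("sim_dt must divide fix_interval")
  }
  invisible(cfg)
}

# evaluate `expr` under a private RNG stream, restoring global state after
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate one dog's GPS track with known ground truth
#'
#' Integrates the two-state movement model of [sim_config()] on a fine time
#' grid, emits motion-gated fixes with GPS noise, and returns both the
#' observed track and a `truth_summary` computed from the noise-free path:
#' the percentage of deployment time spent within `truth_radius` of the
#' household, per-site visit percentages, and the length of the noise-free
#' path sampled at the emitted fix times (the distance a perfect logger on
#' the same schedule would have measured).
#'
#' @param config a [sim_config].
#' @param dog_id identifier for the returned track.
#' @param truth_radius radius (m) defining "at the household" and "at a
#'   site" in the truth summary; 20 m matches the standardized household
#'   area used downstream.
#' @param return_path also return the dense noise-free path (`path`: matrix
#'   of planar positions at `sim_dt` resolution), for auditing the truth
#'   summary.
#' @return list with elements `track` (a [sampled_track], planar and
#'   geographic coordinates filled) and `truth` (a `truth_summary`);
#'   plus `path` and `dt` when `return_path = TRUE`.
#' @export
simulate_track <- function(config, dog_id = "sim", truth_radius = 20,
                           return_path = FALSE) {
  .validate_sim_config(config)
  with_seed(config$seed, {
    dt <- config$sim_dt
    n_steps <- floor(config$deployment_hours * 3600 / dt)
    home <- unname(config$household_center)
    sites <- config$attraction_sites
    weights <- c(config$home_weight, vapply(sites, `[[`, 0, "weight"))
    targets <- c(list(home), lapply(sites, function(s) unname(s$center)))

    # alternating rest/travel bout schedule (exponential clocks)
    total_s <- n_steps * dt
    bout_state <- character(0)
    bout_len <- numeric(0)
    acc <- 0
    state <- "rest"
    while (acc < total_s) {
      len <- stats::rexp(1, 1 / if (state == "rest") config$rest_mean_s
                         else config$travel_mean_s)
      len <- max(dt, round(len / dt) * dt)
      bout_state <- c(bout_state, state)
      bout_len <- c(bout_len, len)
      acc <- acc + len
      state <- if (state == "rest") "travel" else "rest"
    }
    bout_len[length(bout_len)] <- bout_len[length(bout_len)] -
      (acc - total_s)

    pos <- matrix(NA_real_, n_steps + 1, 2)
    pos[1, ] <- home
    i <- 1L
    k <- config$home_attraction_rate
    sd_step <- sqrt(2 * config$diffusion_true * dt)
    for (b in seq_along(bout_state)) {
      m <- as.integer(round(bout_len[b] / dt))
      if (m <= 0) next
      idx <- (i + 1):(i + m)
      if (bout_state[b] == "rest" || (is.finite(k) && k == 0 &&
                                      config$diffusion_true == 0)) {
        pos[idx, 1] <- pos[i, 1]
        pos[idx, 2] <- pos[i, 2]
      } else {
        tgt <- targets[[sample.int(length(targets), 1, prob = weights)]]
        if (is.infinite(k)) {
          pos[idx, 1] <- tgt[1]
          pos[idx, 2] <- tgt[2]
        } else {
          a <- 1 - k * dt
          if (a < 0) stop("home_attraction_rate too large for sim_dt ",
                          "(need rate * dt < 1)")
          for (d in 1:2) {
            u <- (1 - a) * tgt[d] + stats::rnorm(m, 0, sd_step)
            pos[idx, d] <- as.numeric(
              stats::filter(u, a, method = "recursive", init = pos[i, d]))
          }
        }
      }
      i <- i + m
    }

    # truth: time-weighted occupancy of the dense noise-free path
    d_home <- sqrt((pos[, 1] - home[1])^2 + (pos[, 2] - home[2])^2)
    frac_home <- 100 * mean(d_home[seq_len(n_steps)] <= truth_radius)
    site_frac <- vapply(sites, function(s) {
      ds <- sqrt((pos[, 1] - s$center[1])^2 + (pos[, 2] - s$center[2])^2)
      100 * mean(ds[seq_len(n_steps)] <= truth_radius)
    }, 0)

    # motion-gated fix emission on the nominal schedule
    stride <- as.integer(config$fix_interval / dt)
    fix_idx <- seq(stride + 1L, n_steps + 1L, by = stride)
    disp <- sqrt((pos[fix_idx, 1] - pos[fix_idx - stride, 1])^2 +
                 (pos[fix_idx, 2] - pos[fix_idx - stride, 2])^2)
    emit <- disp / config$fix_interval >= config$move_speed_threshold
    fix_idx <- fix_idx[emit]

    true_xy <- pos[fix_idx, , drop = FALSE]
    true_total_path_m <- if (nrow(true_xy) >= 2) {
      sum(sqrt(diff(true_xy[, 1])^2 + diff(true_xy[, 2])^2))
    } else 0

    truth <- structure(
      list(true_fraction_at_household = frac_home,
           true_total_path_m = true_total_path_m,
           site_visit_fractions = site_frac,
           n_true_fixes = length(fix_idx)),
      class = "truth_summary")

    if (length(fix_idx) == 0) {
      warning("no fixes emitted (dog never exceeded the movement threshold)")
      fixes <- data.frame(timestamp = config$start_time[0],
                          lon = numeric(0), lat = numeric(0),
                          x = numeric(0), y = numeric(0))
      track <- structure(list(dog_id = dog_id, fixes = fixes,
                              household = NULL,
                              crs = list(zone = config$zone,
                                         north = config$north)),
                         class = "sampled_track")
      out <- list(track = track, truth = truth)
      if (return_path) {
        out$path <- pos
        out$dt <- dt
      }
      return(out)
    }

    obs_xy <- true_xy + matrix(stats::rnorm(2 * nrow(true_xy), 0,
                                            config$gps_noise_sd),
                               ncol = 2)
    ll <- utm_inverse(obs_xy[, 1], obs_xy[, 2],
                      zone = config$zone, north = config$north)
    hh_ll <- utm_inverse(home[1], home[2],
                         zone = config$zone, north = config$north)
    fixes <- data.frame(
      timestamp = config$start_time + (fix_idx - 1L) * dt,
      lon = ll[, "lon"], lat = ll[, "lat"],
      x = obs_xy[, 1], y = obs_xy[, 2])
    track <- sampled_track(dog_id, fixes,
                           household = c(lon = unname(hh_ll[, "lon"]),
                                         lat = unname(hh_ll[, "lat"]),
                                         x = home[1], y = home[2]),
                           crs = list(zone = config$zone,
                                      north = config$north))
    if (config$outlier_rate > 0) {
      track <- inject_outliers(track, config$outlier_rate,
                               config$outlier_jump,
                               seed = config$seed + 104729L)
    }
    out <- list(track = track, truth = truth)
    if (return_path) {
      out$path <- pos
      out$dt <- dt
    }
    out
  })
}

#' @export
print.truth_summary <- function(x, ...) {
  cat(sprintf("<truth_summary> %.1f%% at household, %.0f m noise-free path\n",
              x$true_fraction_at_household, x$true_total_path_m))
  invisible(x)
}

#' Displace random fixes to emulate spurious GPS positions
#'
#' Each fix is independently displaced by `jump` metres in a uniformly random
#' direction with probability `rate`, producing the implausible-speed
#' artefacts the cleaning stage removes. Geographic coordinates are
#' re-derived from the displaced planar ones.
#'
#' @param track a projected [sampled_track] with at least one fix.
#' @param rate displacement probability per fix, in `[0, 1)` (1 accepted for
#'   the degenerate all-displaced case).
#' @param jump displacement distance in metres (> 0).
#' @param seed integer seed.
#' @return the track with displaced fixes; attribute `n_displaced` carries
#'   the count.
#' @export
inject_outliers <- function(track, rate, jump, seed = 1L) {
  if (n_fixes(track) == 0) stop("cannot inject outliers into an empty track")
  if (!is.finite(rate) || rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!is.finite(jump) || jump <= 0) stop("jump must be > 0")
  with_seed(seed, {
    n <- n_fixes(track)
    hit <- stats::runif(n) < rate
    if (any(hit)) {
      theta <- stats::runif(sum(hit), 0, 2 * pi)
      track$fixes$x[hit] <- track$fixes$x[hit] + jump * cos(theta)
      track$fixes$y[hit] <- track$fixes$y[hit] + jump * sin(theta)
      ll <- utm_inverse(track$fixes$x[hit], track$fixes$y[hit],
                        zone = track$crs$zone, north = track$crs$north)
      track$fixes$lon[hit] <- ll[, "lon"]
      track$fixes$lat[hit] <- ll[, "lat"]
    }
    attr(track, "n_displaced") <- sum(hit)
    track
  })
}

#' Write a simulated dog's ground truth as JSON
#'
#' @param truth a `truth_summary`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a study cohort of dogs across sites
#'
#' Generates a multi-site cohort emulating the field study design: `n_sites`
#' sites with roughly `n_dogs / n_sites` collared dogs each, questionnaire
#' metadata drawn with the cohort's category frequencies, heterogeneous
#' per-dog movement parameters, and a site-level random multiplier on
#' roaming propensity that induces within-site clustering of the movement
#' outcomes. Deployments are mostly 4--6 days with a minority of shorter
#' records; `n_short` dogs are forced below 24 h to exercise the dog-level
#' exclusion rule.
#'
#' @param n_dogs number of dogs.
#' @param n_sites number of study sites.
#' @param seed integer seed.
#' @param n_short number of dogs given a sub-24 h deployment.
#' @param base_config template [sim_config] supplying defaults.
#' @return list with `dogs` (list of `simulate_track()` results), and
#'   `metadata` (data.frame in the [read_metadata_csv()] layout).
#' @export
simulate_cohort <- function(n_dogs = 73, n_sites = 8, seed = 1L,
                            n_short = 0, base_config = sim_config()) {
  stopifnot(n_dogs >= 1, n_sites >= 1, n_short <= n_dogs)
  with_seed(seed, {
    site_names <- paste0("site", seq_len(n_sites))
    site_of <- sort(rep_len(seq_len(n_sites), n_dogs))
    # site-level multipliers on roaming propensity and household
    # attachment: induce intracluster correlation of the movement
    # outcomes comparable to the field study's
    site_mult <- exp(stats::rnorm(n_sites, 0, 0.35))
    site_home <- exp(stats::rnorm(n_sites, 0, 0.22))
    age <- sample(c("<1 yr", "1-5 yr", ">5 yr"), n_dogs, replace = TRUE,
                  prob = c(0.07, 0.77, 0.16))
    sex <- sample(c("intact male", "castrated male", "intact female",
                    "spayed female"), n_dogs, replace = TRUE,
                  prob = c(0.31, 0.14, 0.48, 0.07))
    rto <- sample(c("<2 h", "2-6 h", ">6 h"), n_dogs, replace = TRUE,
                  prob = c(0.64, 0.24, 0.12))
    dep <- ifelse(stats::runif(n_dogs) < 0.86,
                  stats::runif(n_dogs, 96, 152),
                  stats::runif(n_dogs, 25, 96))
    if (n_short > 0) dep[seq_len(n_short)] <- stats::runif(n_short, 6, 23)
    dog_seed <- sample.int(2^30, n_dogs)
    dog_ids <- sprintf("dog%03d", seq_len(n_dogs))

    dogs <- vector("list", n_dogs)
    for (j in seq_len(n_dogs)) {
      mult <- site_mult[site_of[j]] * exp(stats::rnorm(1, 0, 0.25))
      hh <- base_config$household_center +
        c(stats::runif(1, -2000, 2000), stats::runif(1, -2000, 2000)) +
        c(site_of[j] * 8000, 0)  # separate sites spatially
      n_site_visits <- sample(2:3, 1)
      ang <- stats::runif(n_site_visits, 0, 2 * pi)
      rad <- stats::runif(n_site_visits, 210, 640) * sqrt(mult)
      sites_j <- lapply(seq_len(n_site_visits), function(s) {
        list(center = c(x = unname(hh[1]) + rad[s] * cos(ang[s]),
                        y = unname(hh[2]) + rad[s] * sin(ang[s])),
             weight = stats::runif(1, 0.25, 0.5))
      })
      cfg <- base_config
      cfg$household_center <- c(x = unname(hh[1]), y = unname(hh[2]))
      cfg$attraction_sites <- sites_j
      cfg$home_weight <- base_config$home_weight * site_home[site_of[j]] *
        exp(stats::rnorm(1, 0, 0.3))
      cfg$diffusion_true <- base_config$diffusion_true * mult
      cfg$travel_mean_s <- base_config$travel_mean_s * mult
      cfg$deployment_hours <- dep[j]
      cfg$seed <- dog_seed[j]
      dogs[[j]] <- simulate_track(cfg, dog_id = dog_ids[j])
    }
    hh_ll <- t(vapply(dogs, function(d) {
      cfg_hh <- d$track$household
      if (is.null(cfg_hh)) c(NA_real_, NA_real_)
      else c(cfg_hh[["lon"]], cfg_hh[["lat"]])
    }, c(0, 0)))
    metadata <- data.frame(
      dog_id = dog_ids,
      site = site_names[site_of],
      age_class = age, sex_status = sex, reported_time_outside = rto,
      purpose = "security", feeding_frequency = "daily",
      household_lon = hh_ll[, 1], household_lat = hh_ll[, 2],
      stringsAsFactors = FALSE)
    list(dogs = dogs, metadata = metadata)
  })
}

#' Write a simulated cohort to disk as logger CSV / truth JSON pairs
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of CSV paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (d in cohort$dogs) {
    if (n_fixes(d$track) == 0) next
    p <- file.path(dir, paste0(d$track$dog_id, ".csv"))
    write_logger_csv(d$track, p)
    write_truth_json(d$truth, file.path(dir,
                                        paste0(d$track$dog_id, "_truth.json")))
    paths <- c(paths, p)
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(paths)
}
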