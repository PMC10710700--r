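# Synthetic trajectory, sensor, weather and decision-dataset generator with
# known ground truth. The generator works in kinematic space (headings,
# airspeeds, climb rates in a local tangent plane); the classifier works in
# sensor space, so ground-truth labels and classifier features stay decoupled.

.MODES <- c("flapping", "gliding", "spiral", "staircase", "s_shape")

#' Simulation configuration
#'
#' Collects every free parameter of the synthetic-data generator. Defaults
#' emulate the logger duty cycle used in the field (5-min bursts at 1 fix/s
#' separated by 10-15 min pauses) and sensor scales in milli-g (accelerometer
#' z-axis) and milliGauss (magnetometer x-axis).
#'
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param n_birds Number of simulated individuals.
#' @param n_bursts Bursts per bird.
#' @param burst_s Burst length in seconds (default 300, i.e. 5 min at 1 Hz).
#' @param gap_min Two-element range of the inter-burst pause in minutes.
#' @param wind_u,wind_v Ambient wind components, m/s (toward-east,
#'   toward-north).
#' @param pattern_mix Named probabilities over the five flight modes
#'   `flapping`, `gliding`, `spiral`, `staircase`, `s_shape`; must sum to 1.
#' @param soaring_logit Coefficients (intercept, tailwind, sidewind, delta_T,
#'   tailwind:delta_T) of the soaring-probability logistic model on the
#'   standardized covariate scale.
#' @param departure_logit Coefficients (intercept, wind_support) of the
#'   crossing-departure logistic model.
#' @param re_sd Standard deviation of the per-bird normal random intercept in
#'   the decision-dataset generators.
#' @param noise List of noise scales: `gps_m` (GPS position sigma, metres),
#'   `acc_passive_mg` and `acc_flap_mg` (accelerometer sigma in milli-g for
#'   passive and flapping flight), `mag_mgauss` (magnetometer sigma), `alt_m`
#'   (altitude sigma, metres).
#' @param airspeed List of two-element airspeed ranges in m/s for `soaring`,
#'   `gliding`, `flapping`.
#' @param migration_heading Mean travel heading in compass degrees (default
#'   225, toward the south-west).
#' @param origin Named vector `c(lon=, lat=)` around which tracks are placed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_birds = 4L,
                       n_bursts = 4L,
                       burst_s = 300L,
                       gap_min = c(10, 15),
                       wind_u = 0.5,
                       wind_v = -0.5,
                       pattern_mix = c(flapping = 0.25, gliding = 0.25,
                                       spiral = 0.2, staircase = 0.2,
                                       s_shape = 0.1),
                       soaring_logit = c(intercept = 0, tailwind = 1.51,
                                         sidewind = 1.65, delta_T = 1.97,
                                         interaction = 1.65),
                       departure_logit = c(intercept = -1.97,
                                           wind_support = 0.99),
                       re_sd = 0.5,
                       noise = list(gps_m = 1, acc_passive_mg = 40,
                                    acc_flap_mg = 300, mag_mgauss = 30,
                                    alt_m = 1.5),
                       airspeed = list(soaring = c(8, 12),
                                       gliding = c(12, 18),
                                       flapping = c(10, 14)),
                       migration_heading = 225,
                       origin = c(lon = 13.5, lat = 43.8)) {
  pattern_mix <- pattern_mix[.MODES]
  names(pattern_mix) <- .MODES
  pattern_mix[is.na(pattern_mix)] <- 0
  if (abs(sum(pattern_mix) - 1) > 1e-8) stop("pattern_mix must sum to 1")
  if (burst_s < 11) stop("burst_s must be at least 11")
  if (any(unlist(noise) < 0)) stop("noise sigmas must be non-negative")
  if (length(gap_min) != 2 || gap_min[1] > gap_min[2]) {
    stop("gap_min must be an increasing range of minutes")
  }
  cfg <- list(
    seed = as.integer(seed), n_birds = as.integer(n_birds),
    n_bursts = as.integer(n_bursts), burst_s = as.integer(burst_s),
    gap_min = gap_min, wind_u = wind_u, wind_v = wind_v,
    pattern_mix = pattern_mix, soaring_logit = soaring_logit,
    departure_logit = departure_logit, re_sd = re_sd, noise = noise,
    airspeed = airspeed, migration_heading = migration_heading,
    origin = origin
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed ", x$seed, ": ", x$n_birds, " bird(s) x ",
      x$n_bursts, " burst(s) of ", x$burst_s, " s\n", sep = "")
  mix <- x$pattern_mix[x$pattern_mix > 0]
  cat("  pattern mix: ",
      paste(names(mix), signif(mix, 3), sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  wind (", x$wind_u, ", ", x$wind_v, ") m/s\n", sep = "")
  invisible(x)
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

# Air-relative velocity, climb and truth label for one burst of n seconds.
# Returns list(vax, vay, climb) in m/s, one value per 1 Hz sample.
.burst_kinematics <- function(mode, n, cfg) {
  h0 <- (cfg$migration_heading + stats::rnorm(1, 0, 20)) %% 360
  rad <- pi / 180
  if (mode == "flapping") {
    spd <- runif1(cfg$airspeed$flapping)
    h <- h0 + stats::rnorm(n, 0, 3)
    list(vax = spd * sin(h * rad), vay = spd * cos(h * rad),
         climb = stats::rnorm(n, 0, 0.1))
  } else if (mode == "gliding") {
    spd <- runif1(cfg$airspeed$gliding)
    h <- h0 + stats::rnorm(n, 0, 1)
    list(vax = spd * sin(h * rad), vay = spd * cos(h * rad),
         climb = -runif1(c(0.5, 1.5)) + stats::rnorm(n, 0, 0.05))
  } else if (mode == "spiral") {
    # tight circling: diameter below 10 m; turn period bounded below by the
    # 1 Hz sampling so that full turns remain resolvable in the ground track
    D <- runif1(c(5, 9))
    T_s <- runif1(c(8, 12))
    dir <- sample(c(-1, 1), 1)
    omega <- dir * 2 * pi / T_s
    theta <- stats::runif(1, 0, 2 * pi) + omega * (seq_len(n) - 1)
    vt <- (D / 2) * abs(omega)
    list(vax = vt * sign(omega) * cos(theta),
         vay = -vt * sign(omega) * sin(theta),
         climb = runif1(c(0.3, 1.5)) + stats::rnorm(n, 0, 0.05))
  } else if (mode == "staircase") {
    # alternating blocks: two full wide turns, then a straight run
    D <- runif1(c(20, 40))
    T_s <- runif1(c(9, 16))
    dir <- sample(c(-1, 1), 1)
    omega <- dir * 2 * pi / T_s
    vt <- (D / 2) * abs(omega)
    run_s <- round(runif1(c(8, 14)))
    spd_run <- runif1(c(10, 15))
    theta0 <- stats::runif(1, 0, 2 * pi)
    vax <- vay <- climb <- numeric(n)
    i <- 1L
    circling <- TRUE
    theta <- theta0
    while (i <= n) {
      len <- if (circling) ceiling(2 * T_s) else run_s
      idx <- i:min(n, i + len - 1L)
      if (circling) {
        th <- theta + omega * (seq_along(idx) - 1)
        vax[idx] <- vt * sign(omega) * cos(th)
        vay[idx] <- -vt * sign(omega) * sin(th)
        climb[idx] <- runif1(c(0.5, 1.5))
        theta <- theta + omega * length(idx)
      } else {
        vax[idx] <- spd_run * sin(h0 * rad)
        vay[idx] <- spd_run * cos(h0 * rad)
        climb[idx] <- -0.2
      }
      i <- i + len
      circling <- !circling
    }
    list(vax = vax, vay = vay, climb = climb + stats::rnorm(n, 0, 0.05))
  } else { # s_shape
    A <- runif1(c(40, 80))
    T_s <- runif1(c(20, 40))
    spd <- runif1(cfg$airspeed$soaring)
    h <- h0 + A * sin(2 * pi * (seq_len(n) - 1) / T_s)
    list(vax = spd * sin(h * rad), vay = spd * cos(h * rad),
         climb = runif1(c(0.3, 1.0)) + stats::rnorm(n, 0, 0.05))
  }
}

#' Simulate a labelled multi-bird track
#'
#' Generates 1 Hz GPS/accelerometer/magnetometer bursts for `n_birds` birds,
#' each burst drawn from the configured mix of the five flight modes, with
#' per-fix ground-truth labels. Sensor signatures follow the field's sorting
#' rules: flapping shows strong accelerometer z-axis oscillation, passive
#' flight stays smooth inside the 800-1400 milli-g band, and circling modes
#' produce periodic magnetometer x-axis oscillation via
#' `mag_x = 400 * cos(heading + phase) + noise`.
#'
#' @param config A [sim_config()].
#' @return A `labeled_track` tibble: the canonical track columns plus
#'   `burst_id`, `true_mode` (five-level), `true_behavior`
#'   (flapping/gliding/soaring) and `true_pattern`
#'   (spiral/staircase/s_shape/none). The config is attached as attribute
#'   `sim_config`.
#' @export
simulate_flight <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  rad <- pi / 180
  rows <- vector("list", cfg$n_birds * cfg$n_bursts)
  t0 <- as.POSIXct("2020-10-01 06:00:00", tz = "UTC")
  k <- 0L
  for (b in seq_len(cfg$n_birds)) {
    bird <- sprintf("bird%02d", b)
    lon0 <- cfg$origin["lon"] + stats::runif(1, -0.3, 0.3)
    lat0 <- cfg$origin["lat"] + stats::runif(1, -0.3, 0.3)
    alt0 <- stats::runif(1, 150, 600)
    t_cur <- t0 + b * 3600
    for (j in seq_len(cfg$n_bursts)) {
      k <- k + 1L
      n <- cfg$burst_s
      mode <- sample(.MODES, 1, prob = cfg$pattern_mix)
      kin <- .burst_kinematics(mode, n, cfg)
      vx <- kin$vax + cfg$wind_u
      vy <- kin$vay + cfg$wind_v
      x <- cumsum(c(0, vx[-n]))
      y <- cumsum(c(0, vy[-n]))
      gx <- x + stats::rnorm(n, 0, cfg$noise$gps_m)
      gy <- y + stats::rnorm(n, 0, cfg$noise$gps_m)
      ll <- local_lonlat(gx, gy, lon0, lat0)
      alt <- alt0 + cumsum(c(0, kin$climb[-n])) +
        stats::rnorm(n, 0, cfg$noise$alt_m)
      heading <- (atan2(kin$vax, kin$vay) / rad) %% 360
      phase <- stats::runif(1, 0, 2 * pi)
      mag <- 400 * cos(heading * rad + phase) +
        stats::rnorm(n, 0, cfg$noise$mag_mgauss)
      acc_sigma <- if (mode == "flapping") cfg$noise$acc_flap_mg else cfg$noise$acc_passive_mg
      acc <- 1100 + stats::rnorm(n, 0, acc_sigma)
      rows[[k]] <- tibble::tibble(
        bird_id = bird,
        timestamp = t_cur + (seq_len(n) - 1),
        lon = ll$lon, lat = ll$lat,
        altitude_msl = alt,
        ground_speed = sqrt(vx^2 + vy^2) * 3.6,
        acc_z = acc, mag_x = mag,
        burst_id = sprintf("%s_b%02d", bird, j),
        true_mode = mode,
        true_behavior = switch(mode, flapping = "flapping",
                               gliding = "gliding", "soaring"),
        true_pattern = if (mode %in% c("spiral", "staircase", "s_shape")) mode else "none"
      )
      gap_s <- round(runif1(cfg$gap_min) * 60)
      t_cur <- t_cur + n + gap_s
      # advance the reference point roughly along the migration axis
      lon0 <- ll$lon[n] + 0.01 * sin(cfg$migration_heading * rad)
      lat0 <- ll$lat[n] + 0.01 * cos(cfg$migration_heading * rad)
      alt0 <- max(80, alt[n] + stats::runif(1, -50, 50))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "sim_config") <- cfg
  class(out) <- unique(c("labeled_track", "track", class(out)))
  out
}

#' Simulate a soaring-decision dataset with known coefficients
#'
#' Draws standardized weather covariates and a binary soaring response from a
#' logistic model with a per-bird normal random intercept:
#' `logit P(soaring) = b0 + b1*tailwind + b2*sidewind + b3*delta_T +
#' b4*tailwind*delta_T + u_bird`.
#'
#' @param config A [sim_config()]; uses `soaring_logit`, `re_sd`, `n_birds`
#'   and `seed`.
#' @param n_points Number of rows; at least 50 (smaller tables are not
#'   sensibly fittable).
#' @return A tibble with `bird_id`, `tailwind`, `sidewind`, `delta_T` (all on
#'   the standardized scale) and `soaring` in `{0, 1}`.
#' @export
simulate_soaring_dataset <- function(config, n_points) {
  stopifnot(inherits(config, "sim_config"))
  if (n_points < 50) stop("n_points must be at least 50 for a fittable dataset")
  set.seed(config$seed)
  b <- config$soaring_logit
  re <- stats::rnorm(config$n_birds, 0, config$re_sd)
  bird <- sample.int(config$n_birds, n_points, replace = TRUE)
  tw <- stats::rnorm(n_points)
  sw <- stats::rnorm(n_points)
  dT <- stats::rnorm(n_points)
  lp <- b[1] + b[2] * tw + b[3] * sw + b[4] * dT + b[5] * tw * dT + re[bird]
  tibble::tibble(
    bird_id = sprintf("bird%02d", bird),
    tailwind = tw, sidewind = sw, delta_T = dT,
    soaring = stats::rbinom(n_points, 1, stats::plogis(lp))
  )
}

#' Simulate a resting-versus-departure decision dataset
#'
#' Each bird waits by the coast and departs on the first day a Bernoulli
#' draw with logistic probability in that day's wind support (plus a
#' per-bird random intercept) succeeds; days after the departure are not
#' observed, so every simulated crossing has exactly one departure day.
#' Records are hourly within the 6:00-13:00 decision window.
#'
#' @param config A [sim_config()]; uses `departure_logit`, `re_sd`,
#'   `n_birds` and `seed`.
#' @param n_days Maximum number of coastal waiting days per bird.
#' @return A tibble with `bird_id`, `day`, `hour` (6-13), `wind_support`,
#'   `sidewind`, `cloud_cover`, `precipitation` and `departed` in `{0, 1}`
#'   (uniform within a bird-day).
#' @export
simulate_departure_dataset <- function(config, n_days) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  b <- config$departure_logit
  hours <- 6:13
  rows <- list()
  for (bird in seq_len(config$n_birds)) {
    re <- stats::rnorm(1, 0, config$re_sd)
    for (d in seq_len(n_days)) {
      ws_day <- stats::rnorm(1)
      departs <- stats::rbinom(1, 1, stats::plogis(b[1] + b[2] * ws_day + re))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        bird_id = sprintf("bird%02d", bird),
        day = d, hour = hours,
        wind_support = ws_day + stats::rnorm(length(hours), 0, 0.1),
        sidewind = abs(stats::rnorm(length(hours))),
        cloud_cover = stats::runif(length(hours)),
        precipitation = 0,
        departed = departs
      )
      if (departs == 1) break
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a sea-crossing scenario with a known transit
#'
#' Builds a strait between two rectangular land masses and a bird that flies
#' straight across it at constant speed, so that the over-water fix span has
#' a known length and the crossing metrics are exact by construction.
#' Optionally prepends coastal resting days (hourly fixes near the departure
#' shore within the decision window) before the crossing day.
#'
#' @param length_km Over-water span between the first and last over-water
#'   fix, km.
#' @param speed_kmh Constant ground speed, km/h.
#' @param lat Transit latitude, degrees.
#' @param fix_interval_s Sampling interval of the transit fixes, seconds.
#' @param n_rest_days Number of coastal resting days before the crossing.
#' @param seed RNG seed for the small positional jitter of resting fixes.
#' @return A list with `track` (a `track` tibble, one bird), `mask` (a
#'   [land_sea_mask()]) and `sea_lon` (the longitudes of the two coasts).
#' @export
simulate_sea_crossing <- function(length_km = 189, speed_kmh = 58,
                                  lat = 43.5, fix_interval_s = 10,
                                  n_rest_days = 0, seed = 1L) {
  set.seed(seed)
  deg_km <- haversine_m(13, lat, 14, lat) / 1000 # km per degree lon at lat
  coast_e <- 15
  coast_w <- coast_e - length_km / deg_km
  mask <- land_sea_mask(list(
    cbind(c(coast_e, coast_e + 3, coast_e + 3, coast_e),
          c(lat - 3, lat - 3, lat + 3, lat + 3)),
    cbind(c(coast_w - 3, coast_w, coast_w, coast_w - 3),
          c(lat - 3, lat - 3, lat + 3, lat + 3))
  ))
  step_km <- speed_kmh * fix_interval_s / 3600
  dlon_step <- step_km / deg_km
  # fixes from just inside the eastern land mass to just inside the western;
  # the first/last over-water fixes sit a hair off each coast
  eps <- dlon_step / 2
  lon_start <- coast_e + 2 * dlon_step
  lon_end <- coast_w - 2 * dlon_step
  lons <- seq(lon_start - eps, lon_end, by = -dlon_step)
  n <- length(lons)
  day0 <- as.POSIXct("2020-10-05 00:00:00", tz = "UTC")
  t_depart <- day0 + 8 * 3600 # 08:00 UTC (10:00 local at +2)
  transit <- tibble::tibble(
    bird_id = "bird01",
    timestamp = t_depart + (seq_len(n) - 1) * fix_interval_s,
    lon = lons, lat = lat,
    altitude_msl = 150 + stats::rnorm(n, 0, 2),
    ground_speed = speed_kmh
  )
  rest <- NULL
  if (n_rest_days > 0) {
    rest_rows <- lapply(seq_len(n_rest_days), function(d) {
      hours <- 3:12 # UTC; 5:00-14:00 at the +2 h local default
      tibble::tibble(
        bird_id = "bird01",
        timestamp = day0 - (n_rest_days - d + 1) * 86400 + hours * 3600,
        lon = coast_e + 0.02 + stats::runif(length(hours), 0, 0.005),
        lat = lat + stats::runif(length(hours), -0.01, 0.01),
        altitude_msl = 50 + stats::rnorm(length(hours), 0, 2),
        ground_speed = 5
      )
    })
    rest <- dplyr::bind_rows(rest_rows)
  }
  track <- new_track(dplyr::bind_rows(rest, transit))
  list(track = track, mask = mask, sea_lon = c(coast_w, coast_e))
}

#' Build a synthetic weather grid from constants or field functions
#'
#' @param times POSIXct hourly steps.
#' @param lons,lats Grid axes.
#' @param ... Named field values: a scalar (uniform field) or a
#'   `function(lon, lat, time_index)` evaluated on the grid. Unspecified
#'   fields default to calm wind, mild temperatures, no cloud or rain.
#' @return A `weather_grid`.
#' @export
simulate_weather_grid <- function(times, lons, lats, ...) {
  spec <- list(...)
  defaults <- list(
    u_wind_1000 = 2, v_wind_1000 = -2, t_air_1000 = 18,
    u_wind_925 = 3, v_wind_925 = -3, t_air_925 = 14,
    t_surface = 19, cloud_cover = 0.2, precipitation = 0
  )
  for (nm in names(spec)) defaults[[nm]] <- spec[[nm]]
  dims <- c(length(lons), length(lats), length(times))
  grid_idx <- expand.grid(i = seq_along(lons), j = seq_along(lats),
                          k = seq_along(times))
  fields <- lapply(defaults, function(val) {
    arr <- array(NA_real_, dim = dims)
    if (is.function(val)) {
      arr[as.matrix(grid_idx)] <- val(lons[grid_idx$i], lats[grid_idx$j], grid_idx$k)
    } else {
      arr[] <- val
    }
    arr
  })
  weather_grid(times, lons, lats, fields)
}
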