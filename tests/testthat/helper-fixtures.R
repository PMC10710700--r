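# Shared fixtures built in code: no data files.

MODES <- c("flapping", "gliding", "spiral", "staircase", "s_shape")

# A pattern mix putting all mass on one mode.
mode_mix <- function(mode) {
  stats::setNames(as.numeric(MODES == mode), MODES)
}

# A config whose bursts are all of one mode.
mode_config <- function(mode, seed = 1, n_birds = 1, n_bursts = 4,
                        burst_s = 300, ...) {
  sim_config(seed = seed, n_birds = n_birds, n_bursts = n_bursts,
             burst_s = burst_s, pattern_mix = mode_mix(mode), ...)
}

noiseless <- function() {
  list(gps_m = 0, acc_passive_mg = 40, acc_flap_mg = 300,
       mag_mgauss = 30, alt_m = 0)
}

# Perfect circle of n points, radius r metres, centred at (lon0, lat0).
circle_segment <- function(r, n = 20, lon0 = 13, lat0 = 44, closed = TRUE,
                           sigma = 0) {
  m_per_deg <- pi * 6371008.8 / 180
  th <- seq(0, 2 * pi, length.out = n + 1)
  if (!closed) th <- th[-(n + 1)] else th <- th[1:(n + 1)]
  x <- r * cos(th) + stats::rnorm(length(th), 0, sigma)
  y <- r * sin(th) + stats::rnorm(length(th), 0, sigma)
  tibble::tibble(
    lon = lon0 + x / (m_per_deg * cos(lat0 * pi / 180)),
    lat = lat0 + y / m_per_deg
  )
}

# Minimal track tibble from vectors.
make_track <- function(n = 20, bird_id = "b1",
                       t0 = as.POSIXct("2020-10-01 08:00:00", tz = "UTC"),
                       lon = 13 + (seq_len(n) - 1) * 1e-4,
                       lat = rep(44, n),
                       alt = rep(200, n), speed = rep(30, n),
                       acc_z = rep(1100, n), mag_x = rep(100, n),
                       dt = 1) {
  tibble::tibble(
    bird_id = bird_id,
    timestamp = t0 + (seq_len(n) - 1) * dt,
    lon = lon, lat = lat, altitude_msl = alt, ground_speed = speed,
    acc_z = acc_z, mag_x = mag_x
  )
}

# One-field uniform weather grid covering a lon/lat/time box.
test_grid <- function(lons = seq(11, 16, 0.25), lats = seq(40, 47, 0.25),
                      t0 = as.POSIXct("2020-10-01 00:00:00", tz = "UTC"),
                      hours = 0:144, ...) {
  simulate_weather_grid(t0 + hours * 3600, lons, lats, ...)
}

# Per-burst agreement between generator truth and classifier output.
burst_agreement <- function(lt, col_truth, col_est, result) {
  truth <- dplyr::distinct(lt, .data$burst_id,
                           truth = .data[[col_truth]])
  est <- dplyr::distinct(result$fixes, .data$burst_id,
                         est = .data[[col_est]])
  m <- dplyr::inner_join(truth, est, by = "burst_id")
  m
}
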