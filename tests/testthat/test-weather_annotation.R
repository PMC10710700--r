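# Wind decomposition, the thermal proxy, ISA altitude and grid
# interpolation.

test_that("wind decomposition handles aligned and opposed flow", {
  w <- wind_components(5, 0, 90) # easterly flow, flying east
  expect_equal(w$tailwind, 5)
  expect_equal(w$sidewind, 0, tolerance = 1e-12)
  w <- wind_components(0, 8, 180) # northward flow, flying south
  expect_equal(w$tailwind, -8)
  expect_equal(w$sidewind, 0, tolerance = 1e-12)
})

test_that("wind decomposition matches a brute-force vector projection", {
  # independent oracle: rotate into the travel frame
  brute <- function(u, v, az) {
    t_hat <- c(sin(az * pi / 180), cos(az * pi / 180))
    n_hat <- c(t_hat[2], -t_hat[1])
    c(tail = sum(c(u, v) * t_hat), side = abs(sum(c(u, v) * n_hat)))
  }
  ref <- brute(3, -4, 135)
  w <- wind_components(3, -4, 135)
  expect_equal(w$tailwind, ref[["tail"]], tolerance = 1e-9)
  expect_equal(w$sidewind, ref[["side"]], tolerance = 1e-9)
})

test_that("tailwind and sidewind satisfy the Pythagorean identity", {
  set.seed(61)
  u <- stats::rnorm(2000, 0, 6)
  v <- stats::rnorm(2000, 0, 6)
  az <- stats::runif(2000, 0, 360)
  w <- wind_components(u, v, az)
  expect_true(all(w$sidewind >= 0))
  expect_lt(max(abs(w$tailwind^2 + w$sidewind^2 - (u^2 + v^2))), 1e-9)
})

test_that("the thermal proxy is a signed surface-air difference", {
  expect_equal(delta_T(21.0, 19.9), 1.1)
  expect_equal(delta_T(15, 15), 0)
  expect_equal(delta_T(15, 20), -5)
  expect_equal(delta_T(20, 15), -delta_T(15, 20))
})

test_that("ISA altitude matches the standard atmosphere", {
  expect_equal(isa_altitude_m(1013.25), 0)
  expect_equal(round(isa_altitude_m(925), -1), 760)
  p <- seq(700, 1013, by = 1)
  expect_true(all(diff(isa_altitude_m(p)) < 0))
})

test_that("uniform fields annotate as the constant everywhere", {
  g <- test_grid(u_wind_1000 = 4, v_wind_1000 = -3, t_surface = 21,
                 t_air_1000 = 19.9)
  tr <- make_track(n = 10, lon = seq(13, 13.01, length.out = 10))
  ann <- annotate_track(tr, g, level = "1000")
  expect_true(all(abs(ann$u - 4) < 1e-9))
  expect_true(all(abs(ann$v + 3) < 1e-9))
  expect_true(all(abs(ann$delta_T - 1.1) < 1e-9))
})

test_that("a fix on a node at a whole hour reads the node value", {
  fld <- function(lon, lat, k) 100 * lon + lat + k
  g <- test_grid(u_wind_1000 = fld, v_wind_1000 = 0)
  tr <- make_track(n = 1, lon = 13.25, lat = 44.5,
                   t0 = as.POSIXct("2020-10-01 05:00:00", tz = "UTC"))
  ann <- annotate_track(tr, g, level = "1000")
  expect_equal(ann$u, fld(13.25, 44.5, 6), tolerance = 1e-9) # hour index 6
})

test_that("bilinear interpolation at a cell centre averages the nodes", {
  fld <- function(lon, lat, k) 10 * lon # linear in lon only
  g <- test_grid(u_wind_1000 = fld, v_wind_1000 = 0)
  tr <- make_track(n = 1, lon = 13.125, lat = 44.125,
                   t0 = as.POSIXct("2020-10-01 05:00:00", tz = "UTC"))
  ann <- annotate_track(tr, g, level = "1000")
  expect_equal(ann$u, mean(c(10 * 13, 10 * 13.25)), tolerance = 1e-9)
})

test_that("bilinear wind values stay inside the surrounding node range", {
  set.seed(62)
  fld <- function(lon, lat, k) sin(lon) * cos(lat) + 0.1 * k
  g <- test_grid(u_wind_1000 = fld, v_wind_1000 = 0)
  tr <- make_track(n = 50, lon = stats::runif(50, 12, 15),
                   lat = stats::runif(50, 41, 46),
                   t0 = as.POSIXct("2020-10-02 00:00:00", tz = "UTC"),
                   dt = 600)
  ann <- annotate_track(tr, g, level = "1000")
  for (i in seq_len(5)) {
    lo_lon <- max(g$lons[g$lons <= tr$lon[i]]); hi_lon <- min(g$lons[g$lons >= tr$lon[i]])
    lo_lat <- max(g$lats[g$lats <= tr$lat[i]]); hi_lat <- min(g$lats[g$lats >= tr$lat[i]])
    ks <- which(abs(as.numeric(g$times) - as.numeric(tr$timestamp[i])) <= 3600)
    vals <- c()
    for (lon in c(lo_lon, hi_lon)) for (lat in c(lo_lat, hi_lat)) for (k in ks) {
      vals <- c(vals, fld(lon, lat, k))
    }
    expect_gte(ann$u[i], min(vals) - 1e-9)
    expect_lte(ann$u[i], max(vals) + 1e-9)
  }
})

test_that("fixes outside the grid are reported", {
  g <- test_grid()
  tr <- make_track(n = 2, lon = c(13, 30))
  expect_error(annotate_track(tr, g), "outside the weather grid")
})

test_that("the pressure-level rule follows altitude and land", {
  g <- test_grid(u_wind_1000 = 1, u_wind_925 = 9, v_wind_1000 = 0,
                 v_wind_925 = 0)
  low <- make_track(n = 5, alt = rep(120, 5), bird_id = "low")
  high <- make_track(n = 5, alt = rep(800, 5), bird_id = "high")
  tr <- dplyr::bind_rows(high, low)
  ann <- annotate_track(tr, g, level = "auto")
  expect_equal(unique(ann$pressure_level[ann$bird_id == "low"]), "1000")
  expect_equal(unique(ann$pressure_level[ann$bird_id == "high"]), "925")
  expect_true(all(abs(ann$u[ann$bird_id == "high"] - 9) < 1e-9))
  ann2 <- annotate_track(tr, g, level = "auto",
                         level_override = c(low = "925"))
  expect_equal(unique(ann2$pressure_level[ann2$bird_id == "low"]), "925")
})

test_that("hourly averaging collapses fixes and keeps the midpoint position", {
  g <- test_grid(u_wind_1000 = function(lon, lat, k) lon * 10, v_wind_1000 = 0)
  tr <- make_track(n = 3, lon = c(13.0, 13.1, 13.2), dt = 600)
  ann <- annotate_track(tr, g, level = "1000")
  h <- hourly_average(ann)
  expect_equal(nrow(h), 1)
  expect_equal(h$u, mean(ann$u))
  expect_equal(h$lon, 13.1) # temporal midpoint fix
  one <- hourly_average(ann[1, ])
  expect_equal(one$u, ann$u[1])
  const <- annotate_track(make_track(n = 4, dt = 300),
                          test_grid(u_wind_1000 = 7, v_wind_1000 = 0),
                          level = "1000")
  expect_equal(hourly_average(const)$u, 7, tolerance = 1e-9)
})
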