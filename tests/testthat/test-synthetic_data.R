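# The ground-truth generator: determinism, per-mode sensor and geometry
# signatures, and the logistic decision datasets.

test_that("identical seeds reproduce tracks exactly", {
  a <- simulate_flight(sim_config(seed = 99, n_birds = 2, n_bursts = 2,
                                  burst_s = 60))
  b <- simulate_flight(sim_config(seed = 99, n_birds = 2, n_bursts = 2,
                                  burst_s = 60))
  expect_identical(a$true_mode, b$true_mode)
  expect_identical(a$burst_id, b$burst_id)
  expect_equal(a$lon, b$lon, tolerance = 1e-9)
  expect_equal(a$acc_z, b$acc_z, tolerance = 1e-9)
  c_ <- simulate_flight(sim_config(seed = 100, n_birds = 2, n_bursts = 2,
                                   burst_s = 60))
  expect_false(identical(a$lon, c_$lon))
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(pattern_mix = c(flapping = 0.5, gliding = 0.4)),
               "sum to 1")
  expect_error(sim_config(burst_s = 10), "at least 11")
  expect_error(sim_config(noise = list(gps_m = -1, acc_passive_mg = 40,
                                       acc_flap_mg = 300, mag_mgauss = 30,
                                       alt_m = 0)),
               "non-negative")
})

test_that("spiral bursts in calm air turn in circles under 10 m diameter", {
  lt <- simulate_flight(mode_config("spiral", seed = 21, n_bursts = 6,
                                    wind_u = 0, wind_v = 0,
                                    noise = noiseless()))
  for (idx in split(seq_len(nrow(lt)), lt$burst_id)) {
    turns <- detect_full_turns(lt[idx, ])
    expect_gt(nrow(turns), 5)
    expect_true(all(turns$diameter_m < 10))
  }
})

test_that("flapping bursts oscillate beyond the passive-band width", {
  lt <- simulate_flight(mode_config("flapping", seed = 22, n_bursts = 6))
  ptp <- tapply(lt$acc_z, lt$burst_id, function(z) max(z) - min(z))
  expect_true(all(ptp > 600))
})

test_that("s-shape bursts never accumulate a full 360-degree turn", {
  lt <- simulate_flight(mode_config("s_shape", seed = 23, n_bursts = 8))
  for (idx in split(seq_len(nrow(lt)), lt$burst_id)) {
    expect_equal(nrow(detect_full_turns(lt[idx, ])), 0)
  }
})

test_that("altitude profiles match the mode: climbs soar, glides sink", {
  for (mode in c("spiral", "staircase")) {
    lt <- simulate_flight(mode_config(mode, seed = 24, n_bursts = 4,
                                      noise = noiseless()))
    rng <- tapply(lt$altitude_msl, lt$burst_id, function(a) max(a) - min(a))
    expect_true(all(rng > 0))
  }
  lt <- simulate_flight(mode_config("gliding", seed = 25, n_bursts = 4,
                                    noise = noiseless()))
  slope <- tapply(seq_len(nrow(lt)), lt$burst_id, function(idx) {
    stats::coef(stats::lm(lt$altitude_msl[idx] ~ seq_along(idx)))[2]
  })
  expect_true(all(slope < 0))
})

test_that("ground speed reflects airspeed plus wind", {
  cfg <- mode_config("gliding", seed = 26, n_bursts = 3,
                     wind_u = 5, wind_v = 0)
  lt <- simulate_flight(cfg)
  spd_ms <- lt$ground_speed / 3.6
  expect_true(all(spd_ms > cfg$airspeed$gliding[1] - 5.5))
  expect_true(all(spd_ms < cfg$airspeed$gliding[2] + 5.5))
})

test_that("null soaring coefficients give a balanced response", {
  cfg <- sim_config(seed = 31, n_birds = 10, re_sd = 0,
                    soaring_logit = c(0, 0, 0, 0, 0))
  d <- simulate_soaring_dataset(cfg, 10000)
  expect_equal(mean(d$soaring), 0.5, tolerance = 0.015 / 0.5)
  expect_true(abs(mean(d$soaring) - 0.5) < 0.015)
})

test_that("a dominant tailwind effect saturates soaring probability", {
  cfg <- sim_config(seed = 32, n_birds = 5, re_sd = 0,
                    soaring_logit = c(0, 10, 0, 0, 0))
  d <- simulate_soaring_dataset(cfg, 5000)
  expect_gt(mean(d$soaring[d$tailwind > 0.5]), 0.99)
  expect_lt(mean(d$soaring[d$tailwind < -0.5]), 0.01)
})

test_that("tiny decision tables are refused", {
  expect_error(simulate_soaring_dataset(sim_config(), 49), "at least 50")
})

test_that("each simulated crossing has at most one departure day", {
  cfg <- sim_config(seed = 33, n_birds = 10)
  d <- simulate_departure_dataset(cfg, n_days = 5)
  per_day <- dplyr::distinct(d, .data$bird_id, .data$day, .data$departed)
  dep_days <- sum(per_day$departed)
  expect_lte(dep_days, 10)
  # departed flag is uniform within a bird-day
  expect_equal(nrow(per_day), nrow(dplyr::distinct(d, .data$bird_id, .data$day)))
  # no bird has observations after its departure day
  last <- d |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::summarise(ok = all(.data$day[.data$departed == 1] == max(.data$day)),
                     .groups = "drop")
  expect_true(all(last$ok))
})

test_that("positive wind coefficient makes departure days windier", {
  cfg <- sim_config(seed = 34, n_birds = 40,
                    departure_logit = c(-1.5, 1.2))
  d <- simulate_departure_dataset(cfg, n_days = 8)
  expect_gt(mean(d$wind_support[d$departed == 1]),
            mean(d$wind_support[d$departed == 0]))
})

test_that("simulated transit matches its constructed metrics", {
  sc <- simulate_sea_crossing(length_km = 120, speed_kmh = 50, seed = 5)
  ev <- detect_crossings(sc$track, sc$mask)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$route_length_km, 120, tolerance = 1 / 120)
  expect_equal(ev$mean_speed_kmh, 50, tolerance = 0.5 / 50)
})
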