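# Behaviour sorting: roost filter, burst segmentation, the accelerometer
# active/passive split and the magnetometer soaring/gliding split, plus the
# end-to-end per-track classifier.

#' Remove roosting fixes
#'
#' Drops fixes with recorded ground speed below `min_speed`; the boundary
#' value is kept (speeds *lower than* the threshold are omitted).
#'
#' @param track A `track` tibble with a `ground_speed` column (km/h).
#' @param min_speed Speed threshold in km/h (default 1).
#' @return The filtered track.
#' @export
filter_roosting <- function(track, min_speed = 1) {
  if (!"ground_speed" %in% names(track)) {
    stop("track has no ground_speed column; cannot filter roosting fixes")
  }
  track[!is.na(track$ground_speed) & track$ground_speed >= min_speed, ]
}

#' Segment a track into 1 Hz bursts
#'
#' Finds maximal runs of consecutive fixes exactly 1 s apart (per bird) and
#' drops runs shorter than `min_len` fixes; segments must have more than 10
#' points to be usable.
#'
#' @param track A `track` tibble.
#' @param min_len Minimum burst length in fixes (default 11).
#' @return The track restricted to retained bursts, with a `burst_seq`
#'   integer column identifying each burst.
#' @export
segment_bursts <- function(track, min_len = 11) {
  if (nrow(track) == 0) {
    track$burst_seq <- integer(0)
    return(track)
  }
  dt <- c(Inf, diff(as.numeric(track$timestamp)))
  new_bird <- c(TRUE, track$bird_id[-1] != track$bird_id[-nrow(track)])
  brk <- new_bird | dt != 1
  seq_id <- cumsum(brk)
  len <- stats::ave(seq_id, seq_id, FUN = length)
  out <- track[len >= min_len, , drop = FALSE]
  out$burst_seq <- match(seq_id[len >= min_len], unique(seq_id[len >= min_len]))
  out
}

# Rolling peak-to-peak over windows of `window` samples.
.rolling_ptp <- function(x, window) {
  n <- length(x)
  if (n <= window) return(max(x) - min(x))
  k <- n - window + 1L
  vapply(seq_len(k), function(i) {
    w <- x[i:(i + window - 1L)]
    max(w) - min(w)
  }, numeric(1))
}

#' Classify a burst as active (flapping) or passive flight
#'
#' Passive flight (gliding or soaring) keeps the accelerometer z-axis smooth
#' inside the 800-1400 milli-g band; flapping produces strong oscillation.
#' A burst is passive iff at least `band_frac` of its `acc_z` samples fall
#' inside `passive_band` and the median peak-to-peak amplitude over
#' `window_s`-second rolling windows stays below `smooth_ptp`.
#'
#' @param burst A data frame of one burst with an `acc_z` column (milli-g).
#' @param passive_band Two-element band in milli-g (default `c(800, 1400)`).
#' @param smooth_ptp Peak-to-peak smoothness threshold in milli-g
#'   (default 300).
#' @param band_frac Minimum in-band sample fraction (default 0.9).
#' @param window_s Rolling-window length in seconds (default 10).
#' @return `"active"` or `"passive"`.
#' @export
classify_activity <- function(burst, passive_band = c(800, 1400),
                              smooth_ptp = 300, band_frac = 0.9,
                              window_s = 10) {
  if (!"acc_z" %in% names(burst) || all(is.na(burst$acc_z))) {
    stop("burst has no accelerometer z-axis data; cannot classify activity")
  }
  z <- burst$acc_z[!is.na(burst$acc_z)]
  frac <- mean(z >= passive_band[1] & z <= passive_band[2])
  ptp <- stats::median(.rolling_ptp(z, window_s))
  if (frac >= band_frac && ptp < smooth_ptp) "passive" else "active"
}

# Periodogram of a detrended series; returns freq (cycles/sample) and power,
# DC excluded.
.periodogram <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  x <- stats::residuals(stats::lm(x ~ t))
  p <- Mod(stats::fft(x))^2 / n
  nf <- floor(n / 2)
  list(freq = (1:nf) / n, power = p[2:(nf + 1)])
}

#' Classify a passive burst as soaring or gliding
#'
#' Thermal soaring shows periodic magnetometer x-axis oscillation (the bird's
#' heading rotates through the Earth's field); gliding keeps the x-axis
#' smooth. A burst is soaring iff the dominant non-zero-frequency peak of
#' the detrended `mag_x` periodogram (measured over a 3-bin neighbourhood to
#' absorb spectral leakage) carries at least `osc_threshold` of the total
#' power and the detrended signal crosses zero at least `min_crossings_60s`
#' times per 60 s.
#'
#' @param burst A data frame of one passive burst with a `mag_x` column
#'   (milliGauss).
#' @param osc_threshold Minimum dominant-peak power fraction (default 0.3).
#' @param min_crossings_60s Minimum zero-crossing rate (default 2 per 60 s).
#' @return `"soaring"` or `"gliding"`.
#' @export
classify_passive <- function(burst, osc_threshold = 0.3,
                             min_crossings_60s = 2) {
  if (!"mag_x" %in% names(burst) || all(is.na(burst$mag_x))) {
    stop("burst has no magnetometer x-axis data; cannot classify passive flight")
  }
  m <- burst$mag_x[!is.na(burst$mag_x)]
  n <- length(m)
  pg <- .periodogram(m)
  tot <- sum(pg$power)
  if (tot <= 0) return("gliding")
  k <- which.max(pg$power)
  nb <- pg$power[max(1, k - 1):min(length(pg$power), k + 1)]
  peak_frac <- sum(nb) / tot
  detr <- stats::residuals(stats::lm(m ~ seq_len(n)))
  s <- sign(detr)
  s <- s[s != 0]
  crossings <- sum(s[-1] != s[-length(s)])
  rate <- crossings / (n / 60)
  if (peak_frac >= osc_threshold && rate >= min_crossings_60s) "soaring" else "gliding"
}

#' Climb rate of a segment
#'
#' The difference between the segment's maximal and minimal altitude above
#' sea level divided by the elapsed time between their occurrences; positive
#' when the maximum occurs after the minimum.
#'
#' @param segment A data frame with `altitude_msl` and `timestamp` columns.
#' @return Climb rate in m/s (0 for a constant-altitude segment).
#' @export
climb_rate <- function(segment) {
  if (nrow(segment) < 2) stop("climb rate needs at least 2 fixes")
  i_max <- which.max(segment$altitude_msl)
  i_min <- which.min(segment$altitude_msl)
  dz <- segment$altitude_msl[i_max] - segment$altitude_msl[i_min]
  dt <- as.numeric(segment$timestamp[i_max]) - as.numeric(segment$timestamp[i_min])
  if (dt == 0) return(0)
  dz / abs(dt) * sign(dt)
}

#' Classify every burst of a track
#'
#' The full sorting pipeline: roost filter, burst segmentation, the
#' accelerometer active/passive split, the magnetometer soaring/gliding
#' split, and soaring-pattern geometry. Every retained burst receives
#' exactly one behaviour (flapping, gliding or soaring) and soaring bursts
#' one pattern (spiral, staircase or s-shape).
#'
#' @param track A `track` tibble with sensor columns.
#' @param min_speed Roost-filter threshold, km/h.
#' @param min_len Minimum burst length in fixes.
#' @param passive_band,smooth_ptp,band_frac,window_s Passed to
#'   [classify_activity()].
#' @param osc_threshold Passed to [classify_passive()].
#' @return A list with `fixes` (per-fix tibble with `segment_id`, `behavior`,
#'   `pattern`) and `segments` (one row per burst: `segment_id`, `bird_id`,
#'   `behavior`, `pattern`, `n_fixes`, `climb_rate`, `mean_altitude`,
#'   `n_turns`, `median_diameter_m`).
#' @export
classify_track <- function(track, min_speed = 1, min_len = 11,
                           passive_band = c(800, 1400), smooth_ptp = 300,
                           band_frac = 0.9, window_s = 10,
                           osc_threshold = 0.3) {
  flt <- filter_roosting(track, min_speed)
  seg <- segment_bursts(flt, min_len)
  if (nrow(seg) == 0) {
    return(list(
      fixes = seg,
      segments = tibble::tibble(
        segment_id = character(), bird_id = character(),
        behavior = character(), pattern = character(),
        n_fixes = integer(), climb_rate = numeric(),
        mean_altitude = numeric(), n_turns = integer(),
        median_diameter_m = numeric()
      )
    ))
  }
  parts <- split(seq_len(nrow(seg)), seg$burst_seq)
  seg$segment_id <- NA_character_
  seg$behavior <- NA_character_
  seg$pattern <- NA_character_
  seg_rows <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    idx <- parts[[i]]
    burst <- seg[idx, ]
    sid <- sprintf("%s_s%03d", burst$bird_id[1], i)
    act <- classify_activity(burst, passive_band, smooth_ptp, band_frac, window_s)
    if (act == "active") {
      behavior <- "flapping"
      pattern <- "none"
      n_turns <- NA_integer_
      med_d <- NA_real_
    } else {
      behavior <- classify_passive(burst, osc_threshold)
      if (behavior == "soaring") {
        pat <- classify_pattern(burst)
        pattern <- pat$pattern
        n_turns <- pat$n_turns
        med_d <- pat$median_diameter_m
      } else {
        pattern <- "none"
        n_turns <- NA_integer_
        med_d <- NA_real_
      }
    }
    seg$segment_id[idx] <- sid
    seg$behavior[idx] <- behavior
    seg$pattern[idx] <- pattern
    seg_rows[[i]] <- tibble::tibble(
      segment_id = sid, bird_id = burst$bird_id[1],
      behavior = behavior, pattern = pattern,
      n_fixes = length(idx),
      climb_rate = climb_rate(burst),
      mean_altitude = mean(burst$altitude_msl),
      n_turns = n_turns, median_diameter_m = med_d
    )
  }
  list(fixes = tibble::as_tibble(seg), segments = dplyr::bind_rows(seg_rows))
}
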