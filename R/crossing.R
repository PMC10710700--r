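# Sea-crossing detection, crossing metrics and construction of the
# resting-versus-departure decision dataset.

#' Detect sea crossings
#'
#' A crossing is the migration period between the first and last fix above
#' the water body: maximal runs of consecutive over-water fixes whose summed
#' over-water route exceeds `min_km` (to exclude near-shore loops) become
#' events.
#'
#' @param track A `track` tibble (one or more birds).
#' @param mask A [land_sea_mask()].
#' @param min_km Minimum over-water route length in km for a run to count as
#'   a crossing (default 20).
#' @return A tibble with one row per crossing: `bird_id`, `departure_time`,
#'   `arrival_time`, `duration_h`, `route_length_km`, `mean_speed_kmh`,
#'   `year`, and the fix index range `start`/`end` within the bird's rows.
#'   `mean_speed_kmh * duration_h` equals `route_length_km` by construction.
#' @export
detect_crossings <- function(track, mask, min_km = 20) {
  out <- list()
  for (bird in unique(track$bird_id)) {
    tr <- track[track$bird_id == bird, ]
    over <- !is_land(mask, tr$lon, tr$lat)
    if (!any(over)) next
    r <- rle(over)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i1 <- starts[j]; i2 <- ends[j]
      if (i2 - i1 < 1) next
      legs <- haversine_m(tr$lon[i1:(i2 - 1)], tr$lat[i1:(i2 - 1)],
                          tr$lon[(i1 + 1):i2], tr$lat[(i1 + 1):i2])
      len_km <- sum(legs) / 1000
      if (len_km < min_km) next
      dur_h <- as.numeric(difftime(tr$timestamp[i2], tr$timestamp[i1], units = "hours"))
      out[[length(out) + 1L]] <- tibble::tibble(
        bird_id = bird,
        departure_time = tr$timestamp[i1],
        arrival_time = tr$timestamp[i2],
        duration_h = dur_h,
        route_length_km = len_km,
        mean_speed_kmh = len_km / dur_h,
        year = as.integer(format(tr$timestamp[i1], "%Y")),
        start = i1, end = i2
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      bird_id = character(), departure_time = as.POSIXct(character(), tz = "UTC"),
      arrival_time = as.POSIXct(character(), tz = "UTC"), duration_h = numeric(),
      route_length_km = numeric(), mean_speed_kmh = numeric(),
      year = integer(), start = integer(), end = integer()
    ))
  }
  dplyr::bind_rows(out)
}

#' Build the resting-versus-departure decision dataset
#'
#' For every detected crossing, walks back over the coastal days the bird
#' spent by the departure shore and assembles hourly-averaged weather records
#' in the local decision window (6:00-13:00 by default): resting days are
#' flagged `departed = 0`; the crossing day contributes records from the
#' window start until the bird's distance from the nearest shore first
#' exceeds `offshore_km` (default 10 km), flagged `departed = 1`. Days on
#' which the bird ventured offshore but within the threshold and returned
#' remain resting days. Crossings preceded by fewer than `min_rest_days`
#' coastal days are skipped.
#'
#' Timestamps are UTC; the decision window is interpreted in local time via
#' `utc_offset_h` (default +2 h, Central European Summer Time).
#'
#' @param annotated An annotated `track` tibble ([annotate_track()] output,
#'   or any track carrying the weather covariate columns to average).
#' @param mask A [land_sea_mask()].
#' @param window Two-element local-hour window (default `c(6, 13)`).
#' @param offshore_km Departure threshold distance from shore, km.
#' @param utc_offset_h Local-time offset from UTC in hours.
#' @param min_rest_days Minimum number of coastal resting days for the
#'   crossing to enter the dataset (default 2).
#' @param min_crossing_km Passed to [detect_crossings()].
#' @param cols Weather columns to carry (those present are averaged).
#' @return A tibble of hourly records: `bird_id`, `date` (local), `hour`
#'   (local), averaged covariates, and `departed`.
#' @export
build_departure_dataset <- function(annotated, mask, window = c(6, 13),
                                    offshore_km = 10, utc_offset_h = 2,
                                    min_rest_days = 2, min_crossing_km = 20,
                                    cols = c("tailwind", "sidewind",
                                             "cloud_cover", "precipitation",
                                             "delta_T", "t_air", "t_surface",
                                             "u", "v", "wind_support")) {
  cols <- intersect(cols, names(annotated))
  events <- detect_crossings(annotated, mask, min_km = min_crossing_km)
  if (nrow(events) == 0) {
    warning("no coastal staging found: track has no qualifying crossing")
    return(tibble::tibble(bird_id = character(), date = as.Date(character()),
                          hour = integer(), departed = integer()))
  }
  local_ts <- annotated$timestamp + utc_offset_h * 3600
  loc_date <- as.Date(local_ts, tz = "UTC")
  loc_hour <- as.integer(format(local_ts, "%H", tz = "UTC"))

  hourly_rows <- function(idx, departed) {
    sub <- annotated[idx, , drop = FALSE]
    sub_hour <- loc_hour[idx]
    sub_date <- loc_date[idx]
    sub |>
      dplyr::mutate(.hour = sub_hour, .date = sub_date) |>
      dplyr::group_by(.data$bird_id, .data$.date, .data$.hour) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean), .groups = "drop") |>
      dplyr::rename(date = ".date", hour = ".hour") |>
      dplyr::mutate(departed = departed)
  }

  out <- list()
  for (e in seq_len(nrow(events))) {
    bird <- events$bird_id[e]
    bird_rows <- which(annotated$bird_id == bird)
    dep_row <- bird_rows[events$start[e]]
    cross_date <- loc_date[dep_row]

    # resting days: consecutive prior days with fixes in the decision window
    rest_dates <- as.Date(character())
    d <- cross_date - 1
    repeat {
      day_idx <- bird_rows[loc_date[bird_rows] == d &
                             loc_hour[bird_rows] >= window[1] &
                             loc_hour[bird_rows] <= window[2]]
      if (length(day_idx) == 0) break
      rest_dates <- c(rest_dates, d)
      d <- d - 1
    }
    if (length(rest_dates) < min_rest_days) next

    for (rd in as.list(sort(rest_dates))) {
      idx <- bird_rows[loc_date[bird_rows] == rd &
                         loc_hour[bird_rows] >= window[1] &
                         loc_hour[bird_rows] <= window[2]]
      out[[length(out) + 1L]] <- hourly_rows(idx, departed = 0L)
    }

    # crossing day: from window start until first fix beyond offshore_km
    day_idx <- bird_rows[loc_date[bird_rows] == cross_date &
                           loc_hour[bird_rows] >= window[1]]
    if (length(day_idx)) {
      dist_km <- shore_distance_m(mask, annotated$lon[day_idx],
                                  annotated$lat[day_idx]) / 1000
      past <- which(dist_km > offshore_km)
      stop_at <- if (length(past)) past[1] else length(day_idx)
      idx <- day_idx[seq_len(stop_at)]
      out[[length(out) + 1L]] <- hourly_rows(idx, departed = 1L)
    }
  }
  if (length(out) == 0) {
    warning("no coastal staging found before any crossing")
    return(tibble::tibble(bird_id = character(), date = as.Date(character()),
                          hour = integer(), departed = integer()))
  }
  dplyr::bind_rows(out)
}
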