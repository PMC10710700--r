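# Readers and writers: tracking tables, weather grids, land/sea masks,
# segment output. Everything downstream works on the canonical track tibble.

.MOVEBANK_COLS <- c(
  timestamp = "timestamp",
  lon = "location-long",
  lat = "location-lat",
  altitude_msl = "height-above-msl",
  ground_speed = "ground-speed"
)
.MOVEBANK_ID_COLS <- c("individual-local-identifier", "tag-local-identifier")
.MOVEBANK_SENSOR_COLS <- c(acc_z = "acceleration-raw-z", mag_x = "magnetic-field-raw-x")

.SIMPLE_COLS <- c(
  bird_id = "bird_id", timestamp = "timestamp", lon = "lon", lat = "lat",
  altitude_msl = "alt", ground_speed = "speed"
)
.SIMPLE_SENSOR_COLS <- c(acc_z = "acc_z", mag_x = "mag_x")

new_track <- function(df) {
  class(df) <- unique(c("track", class(df)))
  df
}

validate_track <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("bird_id", "timestamp", "lon", "lat", "altitude_msl", "ground_speed")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("track is missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$lat < -90 | df$lat > 90, na.rm = TRUE)) stop("latitude outside [-90, 90]")
  if (any(df$lon <= -180 | df$lon > 180, na.rm = TRUE)) stop("longitude outside (-180, 180]")
  if (any(!is.finite(df$altitude_msl))) stop("non-finite altitude")
  bad <- df |>
    dplyr::group_by(.data$bird_id) |>
    dplyr::summarise(ok = all(diff(as.numeric(.data$timestamp)) > 0), .groups = "drop")
  if (any(!bad$ok)) {
    stop("timestamps not strictly increasing for bird(s): ",
         paste(bad$bird_id[!bad$ok], collapse = ", "))
  }
  invisible(df)
}

#' Read a tracking table
#'
#' Reads GPS/sensor fixes from CSV in either the Movebank dialect
#' (`timestamp`, `location-long`, `location-lat`, `height-above-msl`,
#' `ground-speed`, an individual or tag identifier, and optionally
#' `acceleration-raw-z` / `magnetic-field-raw-x`) or the package's simple
#' canonical dialect (`bird_id,timestamp,lon,lat,alt,speed,acc_z,mag_x`).
#'
#' Rows with missing coordinates are dropped with a message; fixes are
#' returned sorted by bird and time. Unknown extra columns are preserved.
#' Timestamps are parsed as UTC.
#'
#' @param path Path to a CSV file.
#' @param dialect `"movebank"` or `"simple"`.
#' @return A `track` tibble with columns `bird_id`, `timestamp` (POSIXct,
#'   UTC), `lon`, `lat`, `altitude_msl` (m), `ground_speed` (km/h) and, when
#'   present in the file, `acc_z` (milli-g) and `mag_x` (milliGauss).
#' @export
read_track <- function(path, dialect = c("movebank", "simple")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  if (dialect == "movebank") {
    cols <- .MOVEBANK_COLS
    sensor <- .MOVEBANK_SENSOR_COLS
    id_col <- intersect(.MOVEBANK_ID_COLS, names(raw))
    if (length(id_col) == 0) {
      stop("format error: missing required column \"",
           .MOVEBANK_ID_COLS[1], "\" (or \"", .MOVEBANK_ID_COLS[2], "\")")
    }
    cols <- c(bird_id = id_col[1], cols)
  } else {
    cols <- .SIMPLE_COLS
    sensor <- .SIMPLE_SENSOR_COLS
  }

  miss <- setdiff(unname(cols), names(raw))
  if (length(miss)) {
    stop("format error: missing required column \"", miss[1], "\"")
  }

  out <- raw
  keep_sensor <- sensor[unname(sensor) %in% names(raw)]
  sel <- c(cols, keep_sensor)
  extra <- setdiff(names(raw), unname(sel))
  out <- out[, c(unname(sel), extra)]
  names(out)[seq_along(sel)] <- names(sel)

  if (!inherits(out$timestamp, "POSIXct")) {
    raw_ts <- as.character(out$timestamp)
    ts <- as.POSIXct(rep(NA_real_, length(raw_ts)), origin = "1970-01-01", tz = "UTC")
    for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                  "%Y/%m/%d %H:%M:%OS")) {
      hole <- is.na(ts)
      if (!any(hole)) break
      ts[hole] <- as.POSIXct(strptime(raw_ts[hole], fmt, tz = "UTC"))
    }
    bad <- which(is.na(ts) & !is.na(raw_ts))
    if (length(bad)) {
      stop("unparseable timestamp at data row ", bad[1],
           ": \"", raw_ts[bad[1]], "\"")
    }
    out$timestamp <- ts
  } else {
    attr(out$timestamp, "tzone") <- "UTC"
  }

  n_bad <- sum(is.na(out$lon) | is.na(out$lat))
  if (n_bad > 0) {
    message("dropping ", n_bad, " row(s) with missing coordinates")
    out <- out[!(is.na(out$lon) | is.na(out$lat)), ]
  }
  out <- dplyr::arrange(out, .data$bird_id, .data$timestamp)
  out <- dplyr::distinct(out, .data$bird_id, .data$timestamp, .keep_all = TRUE)
  validate_track(out)
  new_track(tibble::as_tibble(out))
}

#' Write a track in the simple canonical dialect
#'
#' @param track A `track` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  out <- as.data.frame(track)
  ren <- c(alt = "altitude_msl", speed = "ground_speed")
  for (i in seq_along(ren)) {
    names(out)[names(out) == ren[i]] <- names(ren)[i]
  }
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write labelled segments to CSV (and optionally GeoJSON)
#'
#' One row per fix carrying `segment_id`, `behavior` and `pattern`, plus the
#' fix coordinates and timestamp, so the labelling round-trips.
#'
#' @param segments A tibble of labelled fixes: the per-fix output of
#'   [classify_track()] (columns `bird_id`, `timestamp`, `lon`, `lat`,
#'   `altitude_msl`, `segment_id`, `behavior`, `pattern`).
#' @param path Output CSV path.
#' @param geojson_path Optional path; when given, one GeoJSON `LineString`
#'   feature per segment is written there (RFC 7946).
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, geojson_path = NULL) {
  need <- c("bird_id", "timestamp", "lon", "lat", "segment_id", "behavior", "pattern")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segments missing column(s): ", paste(miss, collapse = ", "))
  out <- as.data.frame(segments)
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  if (!is.null(geojson_path)) {
    feats <- segments |>
      dplyr::group_by(.data$segment_id) |>
      dplyr::group_map(function(g, key) {
        list(
          type = "Feature",
          properties = list(
            segment_id = key$segment_id,
            bird_id = g$bird_id[1],
            behavior = g$behavior[1],
            pattern = g$pattern[1]
          ),
          geometry = list(
            type = "LineString",
            coordinates = lapply(seq_len(nrow(g)), function(i) c(g$lon[i], g$lat[i]))
          )
        )
      })
    fc <- list(type = "FeatureCollection", features = feats)
    jsonlite::write_json(fc, geojson_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read labelled segments written by [write_segments()]
#'
#' @param path CSV path.
#' @return A tibble of labelled fixes.
#' @export
read_segments <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$timestamp <- as.POSIXct(out$timestamp, tz = "UTC")
  tibble::as_tibble(out)
}

# ---- weather grid ----------------------------------------------------------

.GRID_VARS <- c(
  "u_wind_1000", "v_wind_1000", "t_air_1000",
  "u_wind_925", "v_wind_925", "t_air_925",
  "t_surface", "cloud_cover", "precipitation"
)

#' Construct a weather grid
#'
#' A rectilinear hourly weather grid at 0.25-degree (or any regular) spacing
#' holding wind components and air temperature at the 1000 mb and 925 mb
#' pressure levels plus surface temperature, total cloud cover and
#' precipitation. Axes are sorted ascending on construction and the field
#' arrays permuted to match.
#'
#' @param times POSIXct vector of hourly time steps (UTC).
#' @param lons,lats Numeric grid axes in decimal degrees.
#' @param fields Named list of numeric arrays, each with dimensions
#'   `c(length(lons), length(lats), length(times))`. Recognised names:
#'   `u_wind_1000`, `v_wind_1000`, `t_air_1000`, `u_wind_925`, `v_wind_925`,
#'   `t_air_925` (wind m/s, temperature degrees C), `t_surface` (degrees C),
#'   `cloud_cover` (fraction in `[0, 1]`), `precipitation` (m/h).
#' @return A `weather_grid` object.
#' @export
weather_grid <- function(times, lons, lats, fields) {
  stopifnot(inherits(times, "POSIXct"), is.numeric(lons), is.numeric(lats))
  if (!is.list(fields) || is.null(names(fields))) stop("fields must be a named list")
  unknown <- setdiff(names(fields), .GRID_VARS)
  if (length(unknown)) stop("unknown field(s): ", paste(unknown, collapse = ", "))
  dims <- c(length(lons), length(lats), length(times))
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (!is.array(f) || !identical(dim(f), as.integer(dims))) {
      stop("field ", nm, " must be an array with dim (lon, lat, time) = (",
           paste(dims, collapse = ", "), ")")
    }
  }
  ot <- order(as.numeric(times)); olo <- order(lons); ola <- order(lats)
  fields <- lapply(fields, function(f) f[olo, ola, ot, drop = FALSE])
  g <- list(times = times[ot], lons = lons[olo], lats = lats[ola], fields = fields)
  class(g) <- "weather_grid"
  validate_weather_grid(g)
  g
}

validate_weather_grid <- function(g) {
  if (anyDuplicated(g$lons) || anyDuplicated(g$lats)) stop("duplicate grid axis values")
  wind <- intersect(names(g$fields), grep("^[uv]_wind", .GRID_VARS, value = TRUE))
  for (nm in wind) {
    if (any(!is.finite(g$fields[[nm]]))) stop("non-finite values in ", nm)
  }
  if ("cloud_cover" %in% names(g$fields)) {
    cc <- g$fields$cloud_cover
    if (any(cc < 0 | cc > 1, na.rm = TRUE)) {
      stop("cloud_cover outside [0, 1]")
    }
  }
  invisible(g)
}

#' @export
print.weather_grid <- function(x, ...) {
  cat("<weather_grid> ",
      length(x$lons), " x ", length(x$lats), " cells, ",
      length(x$times), " hourly steps\n", sep = "")
  cat("  lon [", min(x$lons), ", ", max(x$lons), "], lat [",
      min(x$lats), ", ", max(x$lats), "]\n", sep = "")
  cat("  fields: ", paste(names(x$fields), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a weather grid from long-format CSV
#'
#' Expects columns `time`, `lon`, `lat`, `variable`, `value` with one row per
#' grid node, variable and hour; the node set must form a complete
#' rectilinear grid. Temperatures may be supplied in Kelvin (`kelvin = TRUE`
#' converts to degrees C on read). NetCDF input is not supported by this
#' reader; convert to the long CSV form first.
#'
#' @param path CSV path.
#' @param kelvin Logical; are the `t_*` variables in Kelvin?
#' @return A `weather_grid`.
#' @export
read_weather_grid <- function(path, kelvin = FALSE) {
  if (grepl("\\.nc$", path, ignore.case = TRUE)) {
    stop("NetCDF input is not supported by this reader; ",
         "export the grid to long-format CSV (time,lon,lat,variable,value)")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time", "lon", "lat", "variable", "value")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("format error: missing required column \"", miss[1], "\"")
  times <- sort(unique(as.POSIXct(raw$time, tz = "UTC")))
  lons <- sort(unique(raw$lon))
  lats <- sort(unique(raw$lat))
  raw$time <- as.POSIXct(raw$time, tz = "UTC")
  fields <- list()
  for (nm in unique(raw$variable)) {
    sub <- raw[raw$variable == nm, ]
    if (nrow(sub) != length(times) * length(lons) * length(lats)) {
      stop("format error: variable ", nm, " does not cover a full rectilinear grid")
    }
    arr <- array(NA_real_, dim = c(length(lons), length(lats), length(times)))
    i <- match(sub$lon, lons)
    j <- match(sub$lat, lats)
    k <- match(as.numeric(sub$time), as.numeric(times))
    arr[cbind(i, j, k)] <- sub$value
    if (anyNA(arr)) stop("format error: variable ", nm, " has duplicated or missing nodes")
    if (kelvin && grepl("^t_", nm)) arr <- arr - 273.15
    fields[[nm]] <- arr
  }
  weather_grid(times, lons, lats, fields)
}

#' Write a weather grid to long-format CSV
#'
#' @param grid A `weather_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather_grid <- function(grid, path) {
  rows <- lapply(names(grid$fields), function(nm) {
    f <- grid$fields[[nm]]
    idx <- expand.grid(
      i = seq_along(grid$lons), j = seq_along(grid$lats), k = seq_along(grid$times)
    )
    tibble::tibble(
      time = format(grid$times[idx$k], "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      lon = grid$lons[idx$i], lat = grid$lats[idx$j],
      variable = nm, value = f[as.matrix(idx)]
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}

# ---- land/sea mask ---------------------------------------------------------

#' Construct a land/sea mask from polygons
#'
#' @param polygons A list of two-column matrices (lon, lat), each a closed or
#'   implicitly closed land polygon ring in WGS84.
#' @return A `land_sea_mask` object.
#' @export
land_sea_mask <- function(polygons) {
  if (!is.list(polygons) || length(polygons) == 0) stop("polygons must be a non-empty list")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2) stop("each polygon must be a 2-column (lon, lat) matrix")
    storage.mode(p) <- "double"
    # drop an explicitly repeated closing vertex
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (nrow(p) < 3) stop("polygon with fewer than 3 vertices")
    p
  })
  m <- list(polygons = polygons)
  class(m) <- "land_sea_mask"
  m
}

#' @export
print.land_sea_mask <- function(x, ...) {
  cat("<land_sea_mask> ", length(x$polygons), " land polygon(s)\n", sep = "")
  invisible(x)
}

#' Read a land/sea mask from GeoJSON
#'
#' Accepts `Polygon` and `MultiPolygon` geometries (outer rings only; holes
#' are ignored) from a `FeatureCollection`, single `Feature` or bare
#' geometry.
#'
#' @param path GeoJSON path.
#' @return A `land_sea_mask`.
#' @export
read_landsea_mask <- function(path) {
  gj <- jsonlite::read_json(path)
  geoms <- switch(gj$type,
    FeatureCollection = lapply(gj$features, function(f) f$geometry),
    Feature = list(gj$geometry),
    list(gj)
  )
  rings <- list()
  for (g in geoms) {
    if (g$type == "Polygon") {
      rings[[length(rings) + 1L]] <- g$coordinates[[1]]
    } else if (g$type == "MultiPolygon") {
      for (poly in g$coordinates) rings[[length(rings) + 1L]] <- poly[[1]]
    } else {
      stop("unsupported geometry type: ", g$type)
    }
  }
  polygons <- lapply(rings, function(r) {
    do.call(rbind, lapply(r, function(xy) c(xy[[1]], xy[[2]])))
  })
  land_sea_mask(polygons)
}

#' Test whether points are over land
#'
#' @param mask A `land_sea_mask`.
#' @param lon,lat Numeric coordinate vectors.
#' @return Logical vector, `TRUE` for points inside any land polygon.
#' @export
is_land <- function(mask, lon, lat) {
  stopifnot(inherits(mask, "land_sea_mask"))
  pts <- cbind(lon, lat)
  inside <- rep(FALSE, nrow(pts))
  for (p in mask$polygons) {
    bnd <- rbind(p, p[1, ])
    inside <- inside | mgcv::in.out(bnd, pts)
  }
  inside
}

# Densified boundary vertices for shore-distance queries, cached on the mask.
shore_points <- function(mask, step_m = 1000) {
  cached <- attr(mask, "shore_points")
  if (!is.null(cached) && isTRUE(attr(cached, "step_m") == step_m)) return(cached)
  pts <- lapply(mask$polygons, function(p) {
    ring <- rbind(p, p[1, ])
    segs <- lapply(seq_len(nrow(ring) - 1), function(i) {
      a <- ring[i, ]; b <- ring[i + 1, ]
      d <- haversine_m(a[1], a[2], b[1], b[2])
      k <- max(1L, ceiling(d / step_m))
      t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
      cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    })
    do.call(rbind, segs)
  })
  out <- do.call(rbind, pts)
  attr(out, "step_m") <- step_m
  out
}

#' Great-circle distance to the nearest shore
#'
#' Distance from each point to the nearest point on any land-polygon
#' boundary, approximated by densifying the boundary at roughly `step_m`
#' spacing.
#'
#' @param mask A `land_sea_mask`.
#' @param lon,lat Numeric coordinate vectors.
#' @param step_m Boundary densification step in metres.
#' @return Distances in metres.
#' @export
shore_distance_m <- function(mask, lon, lat, step_m = 1000) {
  sp <- shore_points(mask, step_m)
  vapply(seq_along(lon), function(i) {
    min(haversine_m(lon[i], lat[i], sp[, 1], sp[, 2]))
  }, numeric(1))
}
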