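# Weather annotation: wind support / side wind decomposition, the
# surface-air temperature difference used as a thermal proxy, pressure-level
# altitude, and grid interpolation onto fixes.

#' Decompose wind into support and side components
#'
#' Projects the wind vector onto the direction of travel. Following the
#' meteorological convention, `u` and `v` are the eastward and northward
#' components of the direction the air moves *toward* (ERA5 convention), so
#' the compass azimuth of the flow is `atan2(u, v)`. Wind support (tailwind)
#' is `|w| * cos(alpha)` where `alpha` is the angle between flow and travel:
#' positive values support the movement, negative values oppose it
#' (headwind). Side wind is returned as a magnitude, `|w| * |sin(alpha)|`.
#'
#' @param u,v Wind components in m/s (toward-east, toward-north). Vectorised.
#' @param travel_azimuth_deg Direction of travel, compass degrees
#'   (0 = north, clockwise).
#' @return A list with numeric vectors `tailwind` (signed, m/s) and
#'   `sidewind` (non-negative, m/s). `tailwind^2 + sidewind^2 = u^2 + v^2`.
#' @export
#' @examples
#' wind_components(5, 0, 90)  # pure easterly flow, flying east: tailwind 5
wind_components <- function(u, v, travel_azimuth_deg) {
  theta <- travel_azimuth_deg * pi / 180
  tailwind <- u * sin(theta) + v * cos(theta)
  sidewind <- abs(u * cos(theta) - v * sin(theta))
  list(tailwind = tailwind, sidewind = sidewind)
}

#' Surface-air temperature difference
#'
#' The thermal-uplift proxy: surface temperature minus air temperature at
#' flight altitude. Positive values indicate a surface warmer than the air
#' aloft (convective uplift); negative values indicate sinking air.
#'
#' @param t_surface,t_air Temperatures in degrees C. Vectorised.
#' @return `t_surface - t_air`, degrees C.
#' @export
delta_T <- function(t_surface, t_air) {
  t_surface - t_air
}

#' Pressure-level altitude in the International Standard Atmosphere
#'
#' @param pressure_hpa Pressure in hPa (mb). Vectorised.
#' @return Geometric altitude in metres:
#'   `h = (T0/L) * (1 - (p/p0)^(R*L/(g*M)))` with `p0 = 1013.25` hPa,
#'   `T0 = 288.15` K, `L = 0.0065` K/m.
#' @export
#' @examples
#' isa_altitude_m(925) # about 760 m
isa_altitude_m <- function(pressure_hpa) {
  p0 <- 1013.25
  T0 <- 288.15
  L <- 0.0065
  R <- 8.31446
  g <- 9.80665
  M <- 0.0289644
  (T0 / L) * (1 - (pressure_hpa / p0)^(R * L / (g * M)))
}

# Bilinear interpolation of one grid field at (lon, lat) for time index k.
# Clamps to the grid edge cell; caller has checked bounds.
.bilinear <- function(field, lons, lats, lon, lat, k) {
  i <- findInterval(lon, lons, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(lons) - 1L)
  j <- findInterval(lat, lats, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), length(lats) - 1L)
  tx <- (lon - lons[i]) / (lons[i + 1] - lons[i])
  ty <- (lat - lats[j]) / (lats[j + 1] - lats[j])
  f00 <- field[cbind(i, j, k)]
  f10 <- field[cbind(i + 1L, j, k)]
  f01 <- field[cbind(i, j + 1L, k)]
  f11 <- field[cbind(i + 1L, j + 1L, k)]
  f00 * (1 - tx) * (1 - ty) + f10 * tx * (1 - ty) +
    f01 * (1 - tx) * ty + f11 * tx * ty
}

.nearest_idx <- function(axis, x) {
  vapply(x, function(xi) which.min(abs(axis - xi)), integer(1))
}

#' Bearing of a sea crossing
#'
#' Initial great-circle bearing between a bird's first and last over-water
#' fix; the travel azimuth the wind decomposition uses for sea crossings.
#'
#' @param track A `track` tibble (one bird).
#' @param mask A `land_sea_mask`.
#' @return Bearing in degrees `[0, 360)`, or `NA` if fewer than two
#'   over-water fixes exist.
#' @export
crossing_azimuth <- function(track, mask) {
  over <- !is_land(mask, track$lon, track$lat)
  idx <- which(over)
  if (length(idx) < 2) return(NA_real_)
  i1 <- idx[1]; i2 <- idx[length(idx)]
  azimuth_deg(track$lon[i1], track$lat[i1], track$lon[i2], track$lat[i2])
}

#' Annotate a track with gridded weather
#'
#' Attaches weather to every fix and derives wind support, side wind and the
#' surface-air temperature difference. Wind components are interpolated
#' bilinearly in space at the two bracketing hours and then linearly in time;
#' temperature, cloud cover and precipitation use the nearest grid node and
#' nearest hour. The pressure level per fix is chosen by `level`: `"auto"`
#' uses 925 mb for over-land fixes (when a mask is supplied) or for birds
#' whose mean flight altitude exceeds `high_altitude_m`, and 1000 mb
#' otherwise; `"1000"` or `"925"` force a level; `level_override` forces a
#' level for named birds (mirroring per-bird extraction at 925 mb for a bird
#' that crossed high).
#'
#' @param track A `track` tibble.
#' @param grid A `weather_grid` covering the track in space and time.
#' @param mask Optional `land_sea_mask` for the over-land part of the level
#'   rule.
#' @param level `"auto"`, `"1000"` or `"925"`.
#' @param level_override Optional named character vector, e.g.
#'   `c(bird7 = "925")`.
#' @param high_altitude_m Mean-altitude threshold for the 925 mb level in the
#'   auto rule (default 400 m).
#' @param travel_azimuth `NULL` to use the consecutive-fix bearing per fix, a
#'   single number for a fixed azimuth (e.g. from [crossing_azimuth()]), or a
#'   vector with one azimuth per fix.
#' @return The track with added columns `u`, `v`, `t_air`, `t_surface`,
#'   `cloud_cover`, `precipitation`, `pressure_level`, `travel_azimuth`,
#'   `tailwind`, `sidewind`, `delta_T`.
#' @export
annotate_track <- function(track, grid, mask = NULL,
                           level = c("auto", "1000", "925"),
                           level_override = NULL,
                           high_altitude_m = 400,
                           travel_azimuth = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(grid, "weather_grid"))
  t_num <- as.numeric(track$timestamp)
  g_num <- as.numeric(grid$times)
  oob <- track$lon < min(grid$lons) | track$lon > max(grid$lons) |
    track$lat < min(grid$lats) | track$lat > max(grid$lats) |
    t_num < min(g_num) | t_num > max(g_num)
  if (any(oob)) {
    stop("fix(es) outside the weather grid bounds: row(s) ",
         paste(utils::head(which(oob), 5), collapse = ", "),
         if (sum(oob) > 5) " ..." else "")
  }

  # pressure level per fix
  if (level == "auto") {
    mean_alt <- stats::ave(track$altitude_msl, track$bird_id, FUN = mean)
    lev <- ifelse(mean_alt > high_altitude_m, "925", "1000")
    if (!is.null(mask)) {
      lev[is_land(mask, track$lon, track$lat)] <- "925"
    }
  } else {
    lev <- rep(level, nrow(track))
  }
  if (!is.null(level_override)) {
    hit <- track$bird_id %in% names(level_override)
    lev[hit] <- unname(level_override[as.character(track$bird_id[hit])])
  }

  # time brackets for linear interpolation of wind
  k0 <- findInterval(t_num, g_num, rightmost.closed = TRUE)
  k0 <- pmin(pmax(k0, 1L), length(g_num) - 1L)
  wt <- (t_num - g_num[k0]) / (g_num[k0 + 1] - g_num[k0])
  kn <- ifelse(abs(t_num - g_num[k0]) <= abs(g_num[k0 + 1] - t_num), k0, k0 + 1L)

  interp_wind <- function(var_base) {
    out <- numeric(nrow(track))
    for (lv in unique(lev)) {
      nm <- paste0(var_base, "_", lv)
      if (is.null(grid$fields[[nm]])) stop("grid is missing field ", nm)
      sel <- lev == lv
      a <- .bilinear(grid$fields[[nm]], grid$lons, grid$lats,
                     track$lon[sel], track$lat[sel], k0[sel])
      b <- .bilinear(grid$fields[[nm]], grid$lons, grid$lats,
                     track$lon[sel], track$lat[sel], k0[sel] + 1L)
      out[sel] <- a * (1 - wt[sel]) + b * wt[sel]
    }
    out
  }
  u <- interp_wind("u_wind")
  v <- interp_wind("v_wind")

  ii <- .nearest_idx(grid$lons, track$lon)
  jj <- .nearest_idx(grid$lats, track$lat)
  nearest <- function(nm) {
    if (is.null(grid$fields[[nm]])) return(rep(NA_real_, nrow(track)))
    grid$fields[[nm]][cbind(ii, jj, kn)]
  }
  t_air <- numeric(nrow(track))
  for (lv in unique(lev)) {
    sel <- lev == lv
    t_air[sel] <- nearest(paste0("t_air_", lv))[sel]
  }
  t_surface <- nearest("t_surface")
  cloud <- nearest("cloud_cover")
  precip <- nearest("precipitation")

  # travel azimuth
  if (is.null(travel_azimuth)) {
    az <- rep(NA_real_, nrow(track))
    for (idx in split(seq_len(nrow(track)), track$bird_id)) {
      az[idx] <- fix_headings(track$lon[idx], track$lat[idx])
    }
  } else if (length(travel_azimuth) == 1) {
    az <- rep(travel_azimuth, nrow(track))
  } else {
    stopifnot(length(travel_azimuth) == nrow(track))
    az <- travel_azimuth
  }

  wc <- wind_components(u, v, az)
  out <- track
  out$u <- u
  out$v <- v
  out$t_air <- t_air
  out$t_surface <- t_surface
  out$cloud_cover <- cloud
  out$precipitation <- precip
  out$pressure_level <- lev
  out$travel_azimuth <- az
  out$tailwind <- wc$tailwind
  out$sidewind <- wc$sidewind
  out$delta_T <- delta_T(t_surface, t_air)
  out
}

#' Average annotated weather per bird-hour
#'
#' When more than one fix falls in the same clock hour, the weather variables
#' are averaged and the temporally middle fix supplies the representative
#' position and timestamp.
#'
#' @param annotated An annotated track (output of [annotate_track()]).
#' @param cols Weather columns to average.
#' @return One row per bird-hour.
#' @export
hourly_average <- function(annotated,
                           cols = c("u", "v", "t_air", "t_surface",
                                    "cloud_cover", "precipitation",
                                    "tailwind", "sidewind", "delta_T")) {
  cols <- intersect(cols, names(annotated))
  annotated |>
    dplyr::mutate(.hour = format(.data$timestamp, "%Y-%m-%d %H", tz = "UTC")) |>
    dplyr::group_by(.data$bird_id, .data$.hour) |>
    dplyr::summarise(
      timestamp = .data$timestamp[ceiling(dplyr::n() / 2)],
      lon = .data$lon[ceiling(dplyr::n() / 2)],
      lat = .data$lat[ceiling(dplyr::n() / 2)],
      dplyr::across(dplyr::all_of(cols), mean),
      n_fixes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(-".hour")
}
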