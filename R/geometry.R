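# Geodesic helpers, turn detection and soaring-pattern geometry.

# Mean Earth radius (IUGG), metres.
.EARTH_R <- 6371008.8

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#'   Vectorised; usual recycling rules apply.
#' @return Distance(s) in metres.
#' @export
#' @examples
#' haversine_m(0, 0, 0, 1) # one degree of latitude, ~111195 m
haversine_m <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = .EARTH_R))
}

#' Initial great-circle bearing
#'
#' Bearing from the first point towards the second on the sphere, measured
#' clockwise from geographic north:
#' `atan2(sin(dlon) cos(lat2), cos(lat1) sin(lat2) - sin(lat1) cos(lat2) cos(dlon))`.
#'
#' @inheritParams haversine_m
#' @return Bearing(s) in degrees in `[0, 360)`.
#' @export
azimuth_deg <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlon <- (lon2 - lon1) * r
  y <- sin(dlon) * cos(lat2 * r)
  x <- cos(lat1 * r) * sin(lat2 * r) - sin(lat1 * r) * cos(lat2 * r) * cos(dlon)
  (atan2(y, x) / r) %% 360
}

# Wrap an angle difference to (-180, 180].
wrap180 <- function(x) {
  out <- (x + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

# Equirectangular local tangent-plane projection about a reference point.
# Adequate for burst-scale geometry (a few km): distortion << 1%.
local_xy <- function(lon, lat, lon0 = mean(lon), lat0 = mean(lat)) {
  m_per_deg <- pi * .EARTH_R / 180
  list(
    x = (lon - lon0) * m_per_deg * cos(lat0 * pi / 180),
    y = (lat - lat0) * m_per_deg,
    lon0 = lon0, lat0 = lat0
  )
}

# Inverse of local_xy().
local_lonlat <- function(x, y, lon0, lat0) {
  m_per_deg <- pi * .EARTH_R / 180
  list(
    lon = lon0 + x / (m_per_deg * cos(lat0 * pi / 180)),
    lat = lat0 + y / m_per_deg
  )
}

# Algebraic (Kasa) least-squares circle fit. Solves the linear system for
# centre and radius; errors on (near-)collinear input.
fit_circle_kasa <- function(x, y) {
  if (length(x) < 3) stop("circle fit needs at least 3 points")
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  dec <- qr(A)
  if (dec$rank < 3) stop("degenerate circle fit: points are collinear")
  sol <- qr.coef(dec, b)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) stop("degenerate circle fit")
  list(cx = unname(sol[1]), cy = unname(sol[2]), r = sqrt(unname(r2)))
}

# Per-fix travel headings from consecutive positions; length n, last value
# repeats the previous one so every fix has a heading.
fix_headings <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(rep(NA_real_, n))
  h <- azimuth_deg(lon[-n], lat[-n], lon[-1], lat[-1])
  c(h, h[n - 1])
}

#' Detect full turns in a flight segment
#'
#' Scans the cumulative signed heading change between consecutive fixes and
#' emits one turn each time it crosses 360 degrees in either direction. After
#' a full turn the accumulator is reduced by 360 so that residual heading
#' change carries into the next turn.
#'
#' @param segment A data frame with `lon` and `lat` columns (one fix per row,
#'   time-ordered).
#' @return A tibble with one row per full turn: `start`, `end` (row indices
#'   into `segment`), `heading_change` (signed degrees, +/-360) and
#'   `diameter_m` (least-squares circle diameter of the turn's fixes, `NA`
#'   when the fit is degenerate).
#' @seealso [turn_diameter_m()], [classify_pattern()]
#' @export
detect_full_turns <- function(segment) {
  empty <- tibble::tibble(
    start = integer(), end = integer(),
    heading_change = numeric(), diameter_m = numeric()
  )
  n <- nrow(segment)
  if (n < 3) return(empty)
  h <- azimuth_deg(
    segment$lon[-n], segment$lat[-n],
    segment$lon[-1], segment$lat[-1]
  )
  dh <- wrap180(diff(h)) # dh[i]: heading change at fix i+1
  keep <- is.finite(dh)
  cum <- 0
  start_fix <- 1L
  out <- list()
  for (i in seq_along(dh)) {
    if (!keep[i]) next
    cum <- cum + dh[i]
    if (abs(cum) >= 360) {
      end_fix <- i + 2L # fix completing the heading change
      d <- tryCatch(
        turn_diameter_m(list(start = start_fix, end = end_fix), segment),
        error = function(e) NA_real_
      )
      out[[length(out) + 1L]] <- tibble::tibble(
        start = start_fix, end = end_fix,
        heading_change = 360 * sign(cum), diameter_m = d
      )
      cum <- cum - 360 * sign(cum)
      start_fix <- end_fix
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Turn diameter from a least-squares circle fit
#'
#' Fits a circle (Kasa algebraic fit) to the fixes of one turn in the local
#' tangent plane and returns its diameter. Because a circling bird drifts
#' with the wind, the start-to-end displacement of a full turn equals the
#' drift accumulated over the turn; a linear ramp matching that displacement
#' is removed before fitting (`drift_compensate = TRUE`) so the diameter
#' measures the turn itself, not the turn plus drift. For a closed,
#' non-drifting turn the compensation is a no-op.
#'
#' The algebraic fit's radius is inflated by measurement noise
#' (`E[r_hat^2] ~ r^2 + 2 sigma^2`); the returned diameter subtracts twice
#' the residual mean square in `r^2` space, which removes the bias to within
#' a few percent down to radii comparable with the GPS noise. For noiseless
#' input the correction vanishes.
#'
#' @param turn A list or one-row data frame with `start` and `end` row indices.
#' @param segment The data frame of fixes the indices refer to (`lon`, `lat`).
#' @param drift_compensate Remove the linear start-to-end drift before
#'   fitting (default `TRUE`).
#' @param bias_correct Apply the noise-bias correction (default `TRUE`).
#' @return Diameter in metres.
#' @export
turn_diameter_m <- function(turn, segment, drift_compensate = TRUE,
                            bias_correct = TRUE) {
  idx <- seq(turn$start[[1]], turn$end[[1]])
  xy <- local_xy(segment$lon[idx], segment$lat[idx])
  x <- xy$x
  y <- xy$y
  if (drift_compensate && length(x) > 2) {
    t <- (seq_along(x) - 1) / (length(x) - 1)
    x <- x - t * (x[length(x)] - x[1])
    y <- y - t * (y[length(y)] - y[1])
  }
  fit <- fit_circle_kasa(x, y)
  r <- fit$r
  if (bias_correct && length(x) > 3) {
    d <- sqrt((x - fit$cx)^2 + (y - fit$cy)^2)
    s2 <- mean((d - r)^2) * length(x) / (length(x) - 3)
    r <- sqrt(max(r^2 - 2 * s2, (r / 2)^2))
  }
  2 * r
}

#' Classify the soaring pattern of a segment
#'
#' Implements the three-way soaring-pattern taxonomy: segments without any
#' full turn are s-shape; otherwise each full turn is typed by its fitted
#' diameter (spiral below 10 m, staircase at or above) and the segment takes
#' the more frequent turn type, ties going to staircase.
#'
#' @param segment A data frame of fixes (`lon`, `lat`) for one soaring
#'   segment.
#' @param spiral_max_diameter_m Diameter threshold separating spiral from
#'   staircase turns (default 10 m).
#' @return A list with `pattern` (one of `"spiral"`, `"staircase"`,
#'   `"s_shape"`), `n_turns` and `median_diameter_m` (`NA` when no turns).
#' @export
classify_pattern <- function(segment, spiral_max_diameter_m = 10) {
  turns <- detect_full_turns(segment)
  turns <- turns[is.finite(turns$diameter_m), , drop = FALSE]
  if (nrow(turns) == 0) {
    return(list(pattern = "s_shape", n_turns = 0L, median_diameter_m = NA_real_))
  }
  is_spiral <- turns$diameter_m < spiral_max_diameter_m
  pattern <- if (sum(is_spiral) > sum(!is_spiral)) "spiral" else "staircase"
  list(
    pattern = pattern,
    n_turns = nrow(turns),
    median_diameter_m = stats::median(turns$diameter_m)
  )
}
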