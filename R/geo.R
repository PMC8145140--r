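# WGS84 ellipsoid and transverse Mercator series (UTM).
# Forward/inverse use the standard 4th-order Krueger expansions in the
# third flattening; within a UTM zone the pair is mutually consistent to
# well below a millimeter, which is what the round-trip contract needs.

.wgs84 <- local({
  a <- 6378137
  f <- 1 / 298.257223563
  n <- f / (2 - f)
  list(
    a = a, f = f, n = n,
    e = sqrt(f * (2 - f)),
    big_a = a / (1 + n) * (1 + n^2 / 4 + n^4 / 64),
    alpha = c(
      n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180,
      13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440,
      61 * n^3 / 240 - 103 * n^4 / 140,
      49561 * n^4 / 161280
    ),
    beta = c(
      n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360,
      n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440,
      17 * n^3 / 480 - 37 * n^4 / 840,
      4397 * n^4 / 161280
    ),
    k0 = 0.9996, fe = 500000, fn_south = 1e7
  )
})

#' UTM projection of geographic coordinates
#'
#' `latlon_to_utm()` projects WGS84 longitude/latitude to Universal
#' Transverse Mercator easting/northing in meters; `utm_to_latlon()` is the
#' inverse. The zone defaults to the zone of the first point.
#'
#' @param lat,lon Geographic coordinates in decimal degrees
#'   (latitude in `[-90, 90]`, longitude in `[-180, 180]`).
#' @param x,y Easting and northing in meters.
#' @param zone UTM zone number (1-60).
#' @param south Logical; `TRUE` for the southern-hemisphere northing
#'   convention (10,000 km false northing).
#' @return A tibble: `x`, `y` (plus `zone`, `south`) for the forward
#'   direction; `lat`, `lon` for the inverse.
#' @examples
#' p <- latlon_to_utm(40.85, 14.27)          # zone 33, Naples area
#' utm_to_latlon(p$x, p$y, p$zone[1], p$south[1])
#' @export
latlon_to_utm <- function(lat, lon, zone = NULL, south = NULL) {
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    abort("latitude must be in [-90, 90] and longitude in [-180, 180].",
          class = "hotspotr_input_error")
  }
  zone <- zone %||% utm_zone(lon[1])
  south <- south %||% (lat[1] < 0)
  g <- .wgs84
  lon0 <- (zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180 - lon0
  t <- sinh(atanh(sin(phi)) - g$e * atanh(g$e * sin(phi)))
  xi_p <- atan2(t, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(t^2 + cos(lam)^2))
  xi <- xi_p
  eta <- eta_p
  for (j in 1:4) {
    xi <- xi + g$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + g$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  tibble(
    x = g$fe + g$k0 * g$big_a * eta,
    y = g$k0 * g$big_a * xi + if (south) g$fn_south else 0,
    zone = zone, south = south
  )
}

#' @rdname latlon_to_utm
#' @export
utm_to_latlon <- function(x, y, zone, south = FALSE) {
  g <- .wgs84
  lon0 <- (zone * 6 - 183) * pi / 180
  xi <- (y - if (south) g$fn_south else 0) / (g$k0 * g$big_a)
  eta <- (x - g$fe) / (g$k0 * g$big_a)
  xi_p <- xi
  eta_p <- eta
  for (j in 1:4) {
    xi_p <- xi_p - g$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - g$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  tau <- sin(xi_p) / sqrt(sinh(eta_p)^2 + cos(xi_p)^2)
  lam <- atan2(sinh(eta_p), cos(xi_p))
  psi <- asinh(tau)
  phi <- atan(tau)
  for (i in 1:8) { # invert the conformal latitude by fixed point
    phi <- asin(tanh(psi + g$e * atanh(g$e * sin(phi))))
  }
  tibble(lat = phi * 180 / pi, lon = (lam + lon0) * 180 / pi)
}

utm_zone <- function(lon) {
  as.integer(pmin(60, pmax(1, floor((lon + 180) / 6) + 1)))
}

#' Read spatial events from a CSV file
#'
#' Reads one event per row with WGS84 decimal-degree coordinates. The file
#' must have latitude and longitude columns (`lat`/`latitude`,
#' `lon`/`lng`/`longitude`); an `event_id`/`id` column is used when present
#' and created otherwise. Rows with unparseable or out-of-range coordinates
#' are dropped with a warning; the dropped rows (with a reason) are
#' attached as attribute `"rejected"`.
#'
#' @param path Path to the CSV file.
#' @return Tibble with columns `event_id`, `lat`, `lon`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "hotspotr_input_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  names(raw) <- tolower(names(raw))
  lat_col <- intersect(c("lat", "latitude"), names(raw))[1]
  lon_col <- intersect(c("lon", "lng", "long", "longitude"), names(raw))[1]
  if (is.na(lat_col) || is.na(lon_col)) {
    abort("CSV must have latitude and longitude columns.",
          class = "hotspotr_format_error")
  }
  if (nrow(raw) == 0) {
    abort("no event rows in file.", class = "hotspotr_input_error")
  }
  id_col <- intersect(c("event_id", "id"), names(raw))[1]
  ev <- tibble(
    event_id = if (!is.na(id_col)) raw[[id_col]] else
      as.character(seq_len(nrow(raw))),
    lat = suppressWarnings(as.numeric(raw[[lat_col]])),
    lon = suppressWarnings(as.numeric(raw[[lon_col]])),
    row = seq_len(nrow(raw))
  )
  bad <- ev |>
    dplyr::mutate(reason = dplyr::case_when(
      is.na(.data$lat) | is.na(.data$lon) ~ "unparseable coordinate",
      abs(.data$lat) > 90 ~ "latitude out of [-90, 90]",
      abs(.data$lon) > 180 ~ "longitude out of [-180, 180]",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$reason))
  ok <- dplyr::anti_join(ev, bad, by = "row") |>
    dplyr::select(!"row")
  if (nrow(ok) == 0) {
    abort("no valid event rows in file.", class = "hotspotr_input_error")
  }
  if (nrow(bad) > 0) {
    warn(sprintf("dropped %d invalid row(s); see attr(, \"rejected\").",
                 nrow(bad)))
    attr(ok, "rejected") <- dplyr::select(bad, "row", "event_id", "reason")
  }
  ok
}

#' Project events to planar UTM coordinates
#'
#' Converts latitude/longitude events to easting/northing in meters, the
#' coordinate system clustering runs in (the prototype dissimilarity is
#' Euclidean, so raw degrees are not usable). The UTM zone of the centroid
#' is used unless given, and projection metadata is attached so hotspot
#' centers and GeoJSON circles can be mapped back to geographic
#' coordinates.
#'
#' @param events Data frame with `lat` and `lon` columns (for example from
#'   [read_events()]).
#' @param zone,south Optional UTM zone override (see [latlon_to_utm()]).
#' @return `events` with planar `x`, `y` columns (meters) appended and a
#'   `"projection"` attribute (`zone`, `south`).
#' @examples
#' ev <- tibble::tibble(lat = c(40.85, 40.86), lon = c(14.25, 14.27))
#' project_events(ev)
#' @export
project_events <- function(events, zone = NULL, south = NULL) {
  if (!is.data.frame(events) || !all(c("lat", "lon") %in% names(events))) {
    abort("`events` must have `lat` and `lon` columns.",
          class = "hotspotr_input_error")
  }
  zone <- zone %||% utm_zone(mean(events$lon))
  if (zone < 1 || zone > 60) {
    abort("UTM zone must be in 1..60.", class = "hotspotr_config_error")
  }
  south <- south %||% (mean(events$lat) < 0)
  pr <- latlon_to_utm(events$lat, events$lon, zone = zone, south = south)
  out <- dplyr::mutate(events, x = pr$x, y = pr$y)
  attr(out, "projection") <- list(zone = zone, south = south)
  out
}

#' Write hotspot circles as a GeoJSON FeatureCollection
#'
#' Each hotspot becomes a Polygon feature approximating its circle with
#' `n_segments` vertices, carrying `id`, `radius_m`, `area_km2`,
#' `entropy`, `reliability` and (when present) `class` properties. When the
#' report carries projection metadata the ring vertices are inverse
#' projected to WGS84 longitude/latitude (GeoJSON's coordinate order);
#' otherwise the planar coordinates are written as-is.
#'
#' @param report A [hotspot_reliability()] report (or any data frame with
#'   `hotspot`, `x`, `y`, `radius_m`, `area_km2`, `entropy`,
#'   `reliability`).
#' @param path Output file path.
#' @param n_segments Number of vertices per circle (`>= 8`).
#' @return The path, invisibly.
#' @export
write_hotspots_geojson <- function(report, path, n_segments = 64) {
  if (!is.data.frame(report) || nrow(report) == 0) {
    abort("`report` must be a non-empty data frame.",
          class = "hotspotr_input_error")
  }
  if (n_segments < 8) {
    abort("`n_segments` must be >= 8.", class = "hotspotr_input_error")
  }
  proj <- attr(report, "projection", exact = TRUE)
  theta <- seq(0, 2 * pi, length.out = n_segments + 1)[-(n_segments + 1)]
  features <- purrr::pmap(as_tibble(report), function(...) {
    row <- list(...)
    vx <- row$x + row$radius_m * cos(theta)
    vy <- row$y + row$radius_m * sin(theta)
    ring <- if (!is.null(proj)) {
      ll <- utm_to_latlon(vx, vy, zone = proj$zone, south = proj$south)
      cbind(ll$lon, ll$lat)
    } else {
      cbind(vx, vy)
    }
    ring <- rbind(ring, ring[1, , drop = FALSE]) # close the ring
    props <- list(
      id = row$hotspot,
      radius_m = row$radius_m,
      area_km2 = row$area_km2,
      entropy = row$entropy,
      reliability = row$reliability
    )
    if (!is.null(row$reliability_class)) {
      props$class <- as.character(row$reliability_class)
    }
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(apply(ring, 1, identity,
                                               simplify = FALSE))),
      properties = props
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = 10
  )
  invisible(path)
}
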