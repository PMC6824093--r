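#' Generate a synthetic receiver network
#'
#' Coastal stations are spaced evenly (with small jitter) along the coastline
#' arc of `geometry`; offshore stations are placed inside the bight, i.e.
#' between the arc and its centre, emulating islands and offshore research
#' platforms. Every station gets the presumed 10 km detection radius used
#' for the real network unless overridden.
#'
#' @param n_coastal,n_offshore Non-negative station counts.
#' @param geometry A [coast_geometry()].
#' @param detection_radius_km Detection radius assigned to every station.
#' @param active_from,active_to Activity window (UTC `POSIXct`).
#' @param seed Integer seed; same seed and config give an identical table.
#' @return Tibble with columns `station_id`, `lat`, `lon`,
#'   `detection_radius_km`, `active_from`, `active_to`, `offshore_flag`.
#' @export
generate_network <- function(n_coastal, n_offshore,
                             geometry = coast_geometry(),
                             detection_radius_km = 10,
                             active_from = as.POSIXct("2017-09-01", tz = "UTC"),
                             active_to = as.POSIXct("2018-12-31", tz = "UTC"),
                             seed) {
  stopifnot(n_coastal >= 0, n_offshore >= 0)
  if (!inherits(geometry, "coast_geometry"))
    abort("`geometry` must be a coast_geometry().",
          class = "coastflight_config_error")
  if (detection_radius_km <= 0)
    abort("`detection_radius_km` must be positive.",
          class = "coastflight_config_error")
  withr::with_seed(seed, {
    coastal <- if (n_coastal > 0) {
      phi <- seq(geometry$arc_deg[1], geometry$arc_deg[2],
                 length.out = n_coastal)
      phi <- phi + rnorm(n_coastal, 0, 0.4)
      coast_point(geometry, phi) |>
        mutate(station_id = sprintf("C%02d", seq_len(n_coastal)),
               offshore_flag = FALSE)
    } else NULL
    offshore <- if (n_offshore > 0) {
      phi <- runif(n_offshore, geometry$arc_deg[1] + 15,
                   geometry$arc_deg[2] - 15)
      frac <- runif(n_offshore, 0.35, 0.7)
      coast_point(geometry, phi, radius_frac = frac) |>
        mutate(station_id = sprintf("O%02d", seq_len(n_offshore)),
               offshore_flag = TRUE)
    } else NULL
    out <- dplyr::bind_rows(coastal, offshore)
    if (nrow(out) == 0)
      return(tibble(station_id = character(), lat = numeric(),
                    lon = numeric(), detection_radius_km = numeric(),
                    active_from = as.POSIXct(character(), tz = "UTC"),
                    active_to = as.POSIXct(character(), tz = "UTC"),
                    offshore_flag = logical()))
    out |>
      mutate(detection_radius_km = detection_radius_km,
             active_from = active_from, active_to = active_to) |>
      select("station_id", "lat", "lon", "detection_radius_km",
             "active_from", "active_to", "offshore_flag")
  })
}

#' Write / read a receiver network as CSV
#'
#' @param network Station tibble as returned by [generate_network()].
#' @param path File path.
#' @return `read_network()` returns the station tibble; `write_network()`
#'   returns `path` invisibly.
#' @export
write_network <- function(network, path) {
  utils::write.csv(network, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    mutate(across(c("active_from", "active_to"),
                  ~ as.POSIXct(.x, tz = "UTC")))
}

#' Write a receiver network as GeoJSON points
#'
#' @inheritParams write_network
#' @export
write_network_geojson <- function(network, path) {
  features <- purrr::pmap(network, function(station_id, lat, lon,
                                            detection_radius_km, active_from,
                                            active_to, offshore_flag, ...) {
    list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(lon, lat)),
      properties = list(station_id = station_id,
                        detection_radius_km = detection_radius_km,
                        active_from = format(active_from, "%Y-%m-%dT%H:%M:%SZ"),
                        active_to = format(active_to, "%Y-%m-%dT%H:%M:%SZ"),
                        offshore_flag = offshore_flag)
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
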