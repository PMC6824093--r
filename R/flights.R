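#' Route-classification rule
#'
#' A flight is offshore iff it starts at a latitude above `lat_threshold`
#' and ends at a longitude below `lon_threshold`, or includes a detection at
#' any of the `offshore_station_ids` (islands / offshore platforms). All
#' other flights are alongshore. Defaults are the study thresholds.
#'
#' @param lat_threshold Start-latitude threshold (decimal degrees N).
#' @param lon_threshold End-longitude threshold (decimal degrees E).
#' @param offshore_station_ids Character vector of offshore station ids.
#' @return A list of class `route_rule`.
#' @export
route_rule <- function(lat_threshold = 54.135, lon_threshold = 8.08,
                       offshore_station_ids = character()) {
  if (!is.finite(lat_threshold) || !is.finite(lon_threshold))
    abort("thresholds must be finite.", class = "coastflight_config_error")
  structure(list(lat_threshold = lat_threshold,
                 lon_threshold = lon_threshold,
                 offshore_station_ids = as.character(offshore_station_ids)),
            class = "route_rule")
}

#' Read / write a route rule as YAML
#' @param rule A [route_rule()].
#' @param path File path.
#' @export
write_route_rule <- function(rule, path) {
  yaml::write_yaml(unclass(rule), path)
  invisible(path)
}

#' @rdname write_route_rule
#' @export
read_route_rule <- function(path) {
  x <- yaml::read_yaml(path)
  route_rule(x$lat_threshold, x$lon_threshold,
             as.character(x$offshore_station_ids %||% character()))
}

#' Segment filtered detection runs into continuous flights
#'
#' Per bird, consecutive runs are chained while every inter-detection gap is
#' below `max_gap_h`. A chain touching at least two distinct stations is
#' accepted as a flight iff the great-circle displacement between its first
#' and last station is at least `min_span_km` OR it touches at least
#' `min_stations` distinct stations. Single-station chains are stopover
#' movements, never flights.
#'
#' @param kept_runs Filtered run tibble (needs `tag_id`, `station_id`, `ts`).
#' @param network Station tibble giving station coordinates.
#' @param max_gap_h Maximum inter-detection gap within a chain (hours).
#' @param min_span_km Displacement criterion (km).
#' @param min_stations Station-count criterion.
#' @return Flight tibble: `flight_id`, `bird_id`, `start_station`,
#'   `end_station`, `start_lat`, `start_lon`, `start_time`, `end_lat`,
#'   `end_lon`, `end_time`, `n_stations`, `n_runs`, `span_km`,
#'   `station_seq` and a `detections` list-column of the chained runs.
#' @export
segment_flights <- function(kept_runs, network, max_gap_h = 7,
                            min_span_km = 35, min_stations = 3) {
  empty <- tibble(flight_id = character(), bird_id = character(),
                  start_station = character(), end_station = character(),
                  start_lat = numeric(), start_lon = numeric(),
                  start_time = as.POSIXct(character(), tz = "UTC"),
                  end_lat = numeric(), end_lon = numeric(),
                  end_time = as.POSIXct(character(), tz = "UTC"),
                  n_stations = integer(), n_runs = integer(),
                  span_km = numeric(), station_seq = character(),
                  detections = list())
  if (nrow(kept_runs) == 0) return(empty)
  unknown <- setdiff(kept_runs$station_id, network$station_id)
  if (length(unknown))
    abort(paste0("run(s) at unknown station(s): ",
                 paste(unknown, collapse = ", ")),
          class = "coastflight_station_error")
  runs <- kept_runs |>
    left_join(network |> select("station_id", "lat", "lon"),
              by = "station_id") |>
    arrange(.data$tag_id, .data$ts)

  flights <- runs |>
    group_by(.data$tag_id) |>
    group_modify(function(g, key) {
      gaps <- diff(as.numeric(g$ts)) / 3600
      chain <- cumsum(c(0, gaps >= max_gap_h))
      g$chain <- chain
      g |>
        group_by(.data$chain) |>
        group_modify(function(ch, k2) {
          stations <- unique(ch$station_id)
          if (length(stations) < 2) return(tibble())
          span <- great_circle_km(ch$lat[1], ch$lon[1],
                                  ch$lat[nrow(ch)], ch$lon[nrow(ch)])
          if (!(span >= min_span_km || length(stations) >= min_stations))
            return(tibble())
          tibble(
            start_station = ch$station_id[1],
            end_station = ch$station_id[nrow(ch)],
            start_lat = ch$lat[1], start_lon = ch$lon[1],
            start_time = ch$ts[1],
            end_lat = ch$lat[nrow(ch)], end_lon = ch$lon[nrow(ch)],
            end_time = ch$ts[nrow(ch)],
            n_stations = length(stations), n_runs = nrow(ch),
            span_km = span,
            station_seq = paste(ch$station_id, collapse = ">"),
            detections = list(ch |> ungroup())
          )
        }) |>
        ungroup() |>
        select(-dplyr::any_of("chain"))
    }) |>
    ungroup() |>
    rename(bird_id = "tag_id")
  if (nrow(flights) == 0) return(empty)
  flights |>
    arrange(.data$start_time, .data$bird_id) |>
    mutate(flight_id = sprintf("F%04d", dplyr::row_number())) |>
    select(dplyr::all_of(setdiff(names(empty), "detections")), "detections")
}

#' Keep only each bird's first flight
#'
#' Earliest `start_time` per bird; ties are broken towards the flight with
#' more stations, then by lexicographically smallest station sequence.
#'
#' @param flights Flight tibble from [segment_flights()].
#' @return One-row-per-bird flight tibble.
#' @export
first_flights <- function(flights) {
  if (nrow(flights) == 0) return(flights)
  flights |>
    group_by(.data$bird_id) |>
    arrange(.data$start_time, dplyr::desc(.data$n_stations),
            .data$station_seq, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    arrange(.data$start_time, .data$bird_id)
}

#' Classify flights as offshore or alongshore
#'
#' @param flights Flight tibble.
#' @param rule A [route_rule()].
#' @return The flight tibble with a `route` column
#'   (`"offshore"`/`"alongshore"`).
#' @export
classify_route <- function(flights, rule = route_rule()) {
  stopifnot(inherits(rule, "route_rule"))
  if (nrow(flights) == 0) return(flights |> mutate(route = character()))
  touches_offshore <- purrr::map_lgl(flights$detections, function(d) {
    any(d$station_id %in% rule$offshore_station_ids)
  })
  flights |>
    mutate(route = ifelse(
      (.data$start_lat > rule$lat_threshold &
         .data$end_lon < rule$lon_threshold) | touches_offshore,
      "offshore", "alongshore"))
}

#' Stopover duration and flight onset relative to sunset
#'
#' Minimum stopover duration is the UTC calendar-date difference between tag
#' deployment and flight start; onset is the signed difference (hours)
#' between the flight start time and sunset of the start date at the start
#' coordinates.
#'
#' @param flights Flight tibble (first flights).
#' @param deployments Deployment tibble (needs `bird_id`, `deploy_date`).
#' @return The flight tibble with `min_stopover_days` and
#'   `onset_rel_sunset_h` columns.
#' @export
stopover_metrics <- function(flights, deployments) {
  if (nrow(flights) == 0)
    return(flights |> mutate(min_stopover_days = integer(),
                             onset_rel_sunset_h = numeric()))
  out <- flights |>
    left_join(deployments |> select("bird_id", "deploy_date"),
              by = "bird_id") |>
    mutate(min_stopover_days =
             as.integer(as.Date(.data$start_time) - .data$deploy_date))
  if (any(is.na(out$min_stopover_days)))
    abort("flight bird(s) missing from the deployment table.",
          class = "coastflight_join_error")
  if (any(out$min_stopover_days < 0))
    abort(paste0("flight before deployment for bird(s): ",
                 paste(out$bird_id[out$min_stopover_days < 0],
                       collapse = ", ")),
          class = "coastflight_order_error")
  out |>
    mutate(onset_rel_sunset_h = as.numeric(difftime(
      .data$start_time,
      sunset_utc(as.Date(.data$start_time), .data$start_lat,
                 .data$start_lon),
      units = "hours")))
}

#' Write flights as GeoJSON LineStrings
#'
#' @param flights Flight tibble.
#' @param path File path.
#' @export
write_flights_geojson <- function(flights, path) {
  features <- purrr::map(seq_len(nrow(flights)), function(i) {
    d <- flights$detections[[i]]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = purrr::map2(d$lon, d$lat, c)),
         properties = list(flight_id = flights$flight_id[i],
                           bird_id = flights$bird_id[i],
                           route = flights$route[i] %||% NA,
                           span_km = flights$span_km[i],
                           n_stations = flights$n_stations[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Map-style plot of flights over the receiver network
#'
#' @param flights Classified flight tibble.
#' @param network Station tibble.
#' @return A ggplot object.
#' @export
plot_flights <- function(flights, network) {
  paths <- flights |>
    mutate(.fid = .data$flight_id) |>
    select(".fid", "detections",
           dplyr::any_of("route")) |>
    tidyr::unnest("detections")
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = network,
                        ggplot2::aes(x = .data$lon, y = .data$lat,
                                     shape = .data$offshore_flag),
                        size = 2, colour = "grey40") +
    ggplot2::geom_path(data = paths,
                       ggplot2::aes(x = .data$lon, y = .data$lat,
                                    group = .data$.fid,
                                    colour = if ("route" %in% names(paths))
                                      .data$route else NULL),
                       alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 17),
                                name = "offshore station") +
    ggplot2::labs(x = "longitude (°E)", y = "latitude (°N)",
                  colour = "route") +
    ggplot2::coord_quickmap() +
    ggplot2::theme_minimal()
  p
}
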