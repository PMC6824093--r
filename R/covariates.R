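#' Z-transform covariates on species level
#'
#' Standardizes each requested column to mean 0 / sd 1 within each species,
#' adding `<column>_z` columns. The per-species means and sds are stored in
#' the `"z_params"` attribute so the identical transform can be re-applied
#' (e.g. to prediction grids) with [apply_z()].
#'
#' @param table Tibble with a `species` column.
#' @param columns Character vector of numeric columns to transform.
#' @return `table` with added `_z` columns and a `"z_params"` attribute.
#' @export
z_by_species <- function(table, columns) {
  stopifnot("species" %in% names(table))
  params <- table |>
    group_by(.data$species) |>
    summarise(across(dplyr::all_of(columns),
                     list(mean = ~ mean(.x), sd = ~ sd(.x)),
                     .names = "{.col}.{.fn}"),
              .n = dplyr::n(), .groups = "drop")
  for (sp in params$species) {
    row <- params[params$species == sp, ]
    if (row$.n < 2)
      abort(paste0("species '", sp, "' has fewer than 2 rows."),
            class = "coastflight_z_error")
    for (col in columns) {
      s <- row[[paste0(col, ".sd")]]
      if (!is.finite(s) || s == 0)
        abort(paste0("zero variance in column '", col, "' for species '",
                     sp, "'."),
              class = "coastflight_z_error")
    }
  }
  zp <- params |>
    select(-".n") |>
    tidyr::pivot_longer(-"species", names_to = c("column", "stat"),
                        names_sep = "\\.", values_to = "value") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  apply_z(table, zp)
}

#' @rdname z_by_species
#' @param z_params A `"z_params"` attribute tibble (`species`, `column`,
#'   `mean`, `sd`) from a previous [z_by_species()] call.
#' @export
apply_z <- function(table, z_params) {
  out <- table
  for (col in unique(z_params$column)) {
    pp <- z_params[z_params$column == col, ]
    m <- unname(setNames(pp$mean, pp$species)[out$species])
    s <- unname(setNames(pp$sd, pp$species)[out$species])
    out[[paste0(col, "_z")]] <- (out[[col]] - m) / s
  }
  attr(out, "z_params") <- z_params
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column `j`
#' on all other columns. Exact collinearity is reported as `Inf` with a
#' warning rather than an error.
#'
#' @param design Data frame of numeric columns (more rows than columns).
#' @return Tibble with `column` and `vif`.
#' @export
vif_screen <- function(design) {
  design <- as.data.frame(design)
  num <- vapply(design, is.numeric, logical(1))
  if (!all(num))
    abort("all columns must be numeric.", class = "coastflight_config_error")
  if (nrow(design) <= ncol(design))
    abort("need more rows than columns.", class = "coastflight_config_error")
  vifs <- vapply(seq_along(design), function(j) {
    y <- design[[j]]
    X <- design[-j]
    fit <- suppressWarnings(lm(y ~ ., data = X))
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(is.infinite(vifs)))
    warn(paste0("exact collinearity: ",
                paste(names(design)[is.infinite(vifs)], collapse = ", ")))
  tibble(column = names(design), vif = vifs)
}

#' Build the bird-day departure covariate table
#'
#' For every bird and every stopover day from the night after deployment to
#' its flight night (or to `end_date` for censored birds), evaluates sunset
#' weather at the bird's stopover location (its deployment coordinates — the
#' only reliable position before the first flight) and z-transforms the
#' numeric covariates on species level.
#'
#' @param deployments Deployment tibble (`bird_id`, `species`,
#'   `deploy_date`, `lat`, `lon`).
#' @param flights First-flight tibble (`bird_id`, `start_time`); birds
#'   absent from it are treated as censored.
#' @param weather A [weather_field()].
#' @param end_date Last stopover date for censored birds; defaults to the
#'   last date whose sunset the field covers.
#' @param z Apply the species-level z-transform (default). Use `FALSE` to
#'   obtain raw covariates, e.g. to pool several seasons before a single
#'   [z_by_species()] call.
#' @return Tibble keyed by (`bird_id`, `date`) with `day` (days since
#'   deployment), raw weather covariates, `julian_day`, `year`, `event`
#'   flag, and species-level `_z` columns (attribute `"z_params"`).
#' @export
departure_covariates <- function(deployments, flights, weather,
                                 end_date = NULL, z = TRUE) {
  stopifnot(inherits(weather, "weather_field"))
  if (is.null(end_date)) end_date <- as.Date(max(weather$time)) - 1
  fl <- flights |>
    transmute(bird_id = .data$bird_id,
              flight_date = as.Date(.data$start_time))
  birds <- deployments |>
    select("bird_id", "species", "deploy_date", "lat", "lon") |>
    left_join(fl, by = "bird_id") |>
    mutate(last_date = dplyr::coalesce(.data$flight_date,
                                       as.Date(end_date)))
  rows <- birds |>
    mutate(date = purrr::map2(.data$deploy_date + 1, .data$last_date,
                              ~ seq(.x, max(.x, .y), by = "day"))) |>
    tidyr::unnest("date") |>
    filter(.data$date <= .data$last_date) |>
    mutate(day = as.integer(.data$date - .data$deploy_date),
           sunset = sunset_utc(.data$date, .data$lat, .data$lon),
           event = as.integer(!is.na(.data$flight_date) &
                                .data$date == .data$flight_date))
  wx <- interpolate_at(weather, rows$lat, rows$lon, rows$sunset)
  rows <- dplyr::bind_cols(rows, wx |> select(dplyr::all_of(WEATHER_VARS))) |>
    mutate(julian_day = lubridate::yday(.data$date),
           year = factor(lubridate::year(.data$date)))
  if (!z) return(rows)
  z_by_species(rows, c(WEATHER_VARS, "julian_day"))
}

#' Build the per-bird route covariate table
#'
#' One row per first flight: sunset weather at the flight start point,
#' 24-hour changes in pressure and temperature (sunset value minus the value
#' 24 h earlier at the same point), minimum stopover duration and flight
#' onset relative to sunset, all z-transformed on species level, plus the
#' binary route response (`route01`: 1 = offshore).
#'
#' @param flights Classified first-flight tibble with `route`,
#'   `min_stopover_days` and `onset_rel_sunset_h` (see [classify_route()],
#'   [stopover_metrics()]).
#' @param deployments Deployment tibble supplying `species`.
#' @param weather A [weather_field()].
#' @param z Apply the species-level z-transform (default); `FALSE` returns
#'   raw covariates for multi-season pooling.
#' @return Route-row tibble with raw and `_z` covariates.
#' @export
route_covariates <- function(flights, deployments, weather, z = TRUE) {
  stopifnot(inherits(weather, "weather_field"))
  rows <- flights |>
    left_join(deployments |> select("bird_id", "species"), by = "bird_id") |>
    mutate(start_date = as.Date(.data$start_time),
           sunset = sunset_utc(.data$start_date, .data$start_lat,
                               .data$start_lon))
  wx <- interpolate_at(weather, rows$start_lat, rows$start_lon, rows$sunset)
  wx24 <- interpolate_at(weather, rows$start_lat, rows$start_lon,
                         rows$sunset - 86400)
  rows <- rows |>
    mutate(u_wind = wx$u_wind, v_wind = wx$v_wind,
           rel_humidity = wx$rel_humidity,
           total_cloud = wx$total_cloud,
           d_pressure_24h = wx$air_pressure - wx24$air_pressure,
           d_temp_24h = wx$air_temp - wx24$air_temp,
           year = factor(lubridate::year(.data$start_date)),
           route01 = as.integer(.data$route == "offshore"))
  if (!z) return(rows)
  z_by_species(rows, c("u_wind", "v_wind", "rel_humidity", "total_cloud",
                       "d_pressure_24h", "d_temp_24h",
                       "min_stopover_days", "onset_rel_sunset_h"))
}
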