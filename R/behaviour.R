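#' Behavioural parameters of the bird simulator
#'
#' Defaults mirror the fitted effect sizes of the study system: nightly
#' departure hazard increasing under southward (negative v) winds and clear
#' skies, and offshore routing favoured by westward (negative u) winds and
#' longer stopovers.
#'
#' @param baseline_daily_hazard Nightly departure probability when all
#'   covariates sit at their mean, in (0, 1). The default 0.030 yields a
#'   realized mean stopover near the observed 16 days once the nightly
#'   variance of the weather effects (which raises the average hazard above
#'   the baseline) is accounted for.
#' @param beta_v_wind,beta_cloud Log-hazard coefficients on the z-scored
#'   northward wind and total cloud cover at sunset.
#' @param route_intercept,beta_u_wind,beta_stopover Logit coefficients of
#'   the offshore-route choice on z-scored eastward wind and stopover days.
#' @param species_effects Named list (one entry per species) of length-3
#'   numeric log-hazard offsets for the three stopover periods (days <= 10,
#'   10 < days <= 21, > 21). `NULL` means no species differences.
#' @param min_stopover_days Minimum nights a bird stays before it can depart.
#' @param ground_speed_ms Constant flight ground speed (m/s).
#' @param onset_mean_h,onset_sd_h Normal mean/sd of flight onset after sunset
#'   (hours).
#' @param strata_cuts Day cuts defining the three stopover periods.
#' @return A list of class `behaviour_params`.
#' @export
behaviour_params <- function(baseline_daily_hazard = 0.030,
                             beta_v_wind = -1.03,
                             beta_cloud = -0.54,
                             route_intercept = -0.57,
                             beta_u_wind = -1.21,
                             beta_stopover = 0.90,
                             species_effects = NULL,
                             min_stopover_days = 2,
                             ground_speed_ms = 15,
                             onset_mean_h = 1.5,
                             onset_sd_h = 0.75,
                             strata_cuts = c(10, 21)) {
  if (baseline_daily_hazard <= 0 || baseline_daily_hazard >= 1)
    abort("`baseline_daily_hazard` must lie in (0, 1).",
          class = "coastflight_config_error")
  if (min_stopover_days < 0)
    abort("`min_stopover_days` must be >= 0.",
          class = "coastflight_config_error")
  structure(list(baseline_daily_hazard = baseline_daily_hazard,
                 beta_v_wind = beta_v_wind, beta_cloud = beta_cloud,
                 route_intercept = route_intercept,
                 beta_u_wind = beta_u_wind, beta_stopover = beta_stopover,
                 species_effects = species_effects,
                 min_stopover_days = min_stopover_days,
                 ground_speed_ms = ground_speed_ms,
                 onset_mean_h = onset_mean_h, onset_sd_h = onset_sd_h,
                 strata_cuts = strata_cuts),
            class = "behaviour_params")
}

#' Generate a synthetic tag-deployment table
#'
#' Birds are tagged at a handful of sites on the northern section of the
#' coastline arc, on dates drawn uniformly from the catching window, with
#' species drawn from `species_probs`.
#'
#' @param n_birds Number of tagged birds.
#' @param geometry A [coast_geometry()].
#' @param date_range Length-2 `Date` catching window.
#' @param n_sites Number of distinct catching sites.
#' @param species_probs Named probability vector over species.
#' @param seed Integer seed.
#' @return Tibble with `bird_id`, `species`, `deploy_date`, `deploy_ts`,
#'   `lat`, `lon`, `coast_phi` (the site's angle on the coastline arc).
#' @export
generate_deployments <- function(n_birds,
                                 geometry = coast_geometry(),
                                 date_range = as.Date(c("2017-09-28",
                                                        "2017-10-24")),
                                 n_sites = 7,
                                 species_probs = c(blackbird = 0.32,
                                                   redwing = 0.32,
                                                   song_thrush = 0.36),
                                 seed) {
  stopifnot(n_birds >= 0, n_sites >= 1)
  withr::with_seed(seed, {
    phi <- seq(geometry$deploy_deg[1], geometry$deploy_deg[2],
               length.out = n_sites)
    sites <- coast_point(geometry, phi) |>
      mutate(site = seq_len(n_sites), coast_phi = phi)
    idx <- sample.int(n_sites, n_birds, replace = TRUE)
    dates <- as.Date(sample(seq(date_range[1], date_range[2], by = "day"),
                            n_birds, replace = TRUE))
    tibble(
      bird_id = sprintf("B%04d", seq_len(n_birds)),
      species = sample(names(species_probs), n_birds, replace = TRUE,
                       prob = species_probs),
      deploy_date = dates,
      deploy_ts = as.POSIXct(paste(dates, "11:00:00"), tz = "UTC"),
      lat = sites$lat[idx], lon = sites$lon[idx],
      coast_phi = sites$coast_phi[idx]
    )
  })
}

.stratum_of <- function(days, cuts) {
  1L + findInterval(days, cuts + 0.5)
}

.species_offset <- function(species, stratum, species_effects) {
  if (is.null(species_effects)) return(rep(0, length(species)))
  purrr::map2_dbl(species, stratum, function(s, k) {
    off <- species_effects[[s]]
    if (is.null(off)) 0 else off[[k]]
  })
}

#' Simulate weather-dependent departures, routes and tracks
#'
#' Each night from `min_stopover_days` after deployment, a bird departs with
#' probability `1 - exp(-H0 * exp(eta))`, where `H0` is the cumulative
#' baseline hazard per night implied by `baseline_daily_hazard` and `eta`
#' combines z-scored sunset weather at the bird's stopover location with the
#' species/period offset. On the departure night the route is drawn from
#' `logit P(offshore) = route_intercept + beta_u_wind * z(u) +
#' beta_stopover * z(stopover days)`, and a constant-speed track is laid
#' along the coastline arc (alongshore) or straight across the bight
#' (offshore). Weather z-scores use the season-long per-species mean/sd of
#' the simulated sunset weather, mirroring the analysis-side transform.
#'
#' @param deployments Deployment tibble from [generate_deployments()] (needs
#'   `bird_id`, `species`, `deploy_date`, `lat`, `lon`, `coast_phi`).
#' @param weather A [weather_field()] covering all deployment sites and the
#'   full stopover window.
#' @param params A [behaviour_params()].
#' @param geometry The [coast_geometry()] used for tracks.
#' @param seed Integer seed.
#' @param z_params Optional standardization constants for the behavioural
#'   model: a tibble (`species`, `column`, `mean`, `sd`) covering `u_wind`,
#'   `v_wind` and `total_cloud`, e.g. pooled over several simulated seasons.
#'   Defaults to the season-long per-species moments of this call's sunset
#'   weather.
#' @return Tibble (one row per bird): `bird_id`, `species`,
#'   `true_departure_date` (`NA` if censored), `true_route`
#'   (`"alongshore"`/`"offshore"`/`NA`), `onset_ts`, `stopover_days`,
#'   `censored`, and a `track` list-column of (`lat`, `lon`, `ts`) tibbles.
#'   The per-bird-night decision table (with raw and z-scored covariates and
#'   the realised hazard) is attached as attribute `"nightly"`.
#' @export
simulate_birds <- function(deployments, weather, params = behaviour_params(),
                           geometry = coast_geometry(), seed,
                           z_params = NULL) {
  stopifnot(inherits(weather, "weather_field"))
  if (nrow(deployments) == 0) {
    out <- tibble(bird_id = character(), species = character(),
                  true_departure_date = as.Date(character()),
                  true_route = character(),
                  onset_ts = as.POSIXct(character(), tz = "UTC"),
                  stopover_days = integer(), censored = logical(),
                  track = list())
    attr(out, "nightly") <- tibble()
    return(out)
  }
  # last date whose sunset and 12-18 UTC block the field fully covers
  last_date <- as.Date(max(weather$time)) - 1
  first_date <- min(deployments$deploy_date)
  if (last_date <= first_date)
    abort("weather field does not cover the stopover window.",
          class = "coastflight_config_error")
  nights <- seq(first_date, last_date, by = "day")

  site_nights <- deployments |>
    distinct(.data$lat, .data$lon) |>
    tidyr::crossing(date = nights) |>
    mutate(sunset = sunset_utc(.data$date, .data$lat, .data$lon))
  wx <- interpolate_at(weather, site_nights$lat, site_nights$lon,
                       site_nights$sunset)
  site_nights <- dplyr::bind_cols(
    site_nights,
    wx |> select(dplyr::all_of(WEATHER_VARS))
  )

  nightly <- deployments |>
    select("bird_id", "species", "deploy_date", "lat", "lon") |>
    tidyr::crossing(date = nights) |>
    filter(.data$date >= .data$deploy_date) |>
    left_join(site_nights, by = c("lat", "lon", "date")) |>
    mutate(days = as.integer(.data$date - .data$deploy_date),
           eligible = .data$days >= params$min_stopover_days,
           stratum = .stratum_of(.data$days, params$strata_cuts)) |>
    arrange(.data$bird_id, .data$date)
  nightly <- nightly |>
    group_by(.data$species) |>
    mutate(z_v_wind = as.numeric(scale(.data$v_wind)),
           z_u_wind = as.numeric(scale(.data$u_wind)),
           z_cloud = as.numeric(scale(.data$total_cloud))) |>
    ungroup()
  if (!is.null(z_params)) {
    # externally supplied standardization overrides the season-long default
    zl <- apply_z(nightly, z_params)
    zcols <- c(v_wind = "z_v_wind", u_wind = "z_u_wind",
               total_cloud = "z_cloud")
    for (v in intersect(unique(z_params$column), names(zcols)))
      nightly[[zcols[[v]]]] <- zl[[paste0(v, "_z")]]
  }

  H0 <- -log(1 - params$baseline_daily_hazard)
  withr::with_seed(seed, {
    nightly <- nightly |>
      mutate(
        eta = params$beta_v_wind * .data$z_v_wind +
          params$beta_cloud * .data$z_cloud +
          .species_offset(.data$species, .data$stratum,
                          params$species_effects),
        hazard = ifelse(.data$eligible, 1 - exp(-H0 * exp(.data$eta)), 0),
        draw = runif(dplyr::n()),
        departs = .data$draw < .data$hazard
      )

    birds <- nightly |>
      group_by(.data$bird_id, .data$species, .data$deploy_date,
               .data$lat, .data$lon) |>
      summarise(
        true_departure_date = if (any(.data$departs))
          min(.data$date[.data$departs]) else as.Date(NA),
        .groups = "drop"
      ) |>
      mutate(censored = is.na(.data$true_departure_date),
             stopover_days = ifelse(.data$censored, NA_integer_,
                                    as.integer(.data$true_departure_date -
                                                 .data$deploy_date)))

    dep_night <- nightly |>
      select("bird_id", "date", "z_u_wind", "u_wind", "sunset")
    birds <- birds |>
      left_join(dep_night, by = c("bird_id",
                                  "true_departure_date" = "date"))

    # route choice: z(stopover) over departed birds of the same species
    birds <- birds |>
      group_by(.data$species) |>
      mutate(z_stop = {
        s <- .data$stopover_days
        if (sum(!is.na(s)) >= 2 && sd(s, na.rm = TRUE) > 0)
          (s - mean(s, na.rm = TRUE)) / sd(s, na.rm = TRUE)
        else ifelse(is.na(s), NA_real_, 0)
      }) |>
      ungroup() |>
      mutate(
        route_logit = params$route_intercept +
          params$beta_u_wind * .data$z_u_wind +
          params$beta_stopover * .data$z_stop,
        p_offshore = stats::plogis(.data$route_logit),
        route_draw = runif(dplyr::n()),
        true_route = dplyr::case_when(
          .data$censored ~ NA_character_,
          .data$route_draw < .data$p_offshore ~ "offshore",
          TRUE ~ "alongshore"
        ),
        onset_ts = .data$sunset +
          round(rnorm(dplyr::n(), params$onset_mean_h,
                      params$onset_sd_h) * 3600)
      )

    phi_by_bird <- deployments |>
      select("bird_id", "coast_phi")
    birds <- birds |> left_join(phi_by_bird, by = "bird_id")
    birds$track <- purrr::pmap(
      list(birds$censored, birds$true_route, birds$lat, birds$lon,
           birds$coast_phi, as.list(birds$onset_ts)),
      function(cens, route, lat0, lon0, phi0, t0) {
        if (cens) return(NULL)
        .make_track(route, lat0, lon0, phi0, t0, geometry,
                    params$ground_speed_ms)
      })
  })

  out <- birds |>
    select("bird_id", "species", dplyr::all_of(c("deploy_date")),
           "true_departure_date", "true_route", "onset_ts",
           "stopover_days", "censored", "track") |>
    arrange(.data$bird_id)
  attr(out, "nightly") <- nightly
  out
}

# constant-speed straight/arc track sampled every step_km
.make_track <- function(route, lat0, lon0, phi0, t0, geometry, speed_ms,
                        step_km = 1.8) {
  if (identical(route, "alongshore")) {
    # coast-following birds leave network coverage at the bight's corner
    dest_phi <- geometry$alongshore_end_deg %||% geometry$arc_deg[1]
    arc_len <- geometry$radius_km * (phi0 - dest_phi) * pi / 180
    npt <- max(2L, ceiling(arc_len / step_km) + 1L)
    phi <- seq(phi0, dest_phi, length.out = npt)
    pts <- coast_point(geometry, phi)
    # cumulative great-circle distance along the sampled path
    d <- cumsum(c(0, great_circle_km(pts$lat[-npt], pts$lon[-npt],
                                     pts$lat[-1], pts$lon[-1])))
  } else {
    dest <- coast_point(geometry, geometry$arc_deg[1])
    total <- great_circle_km(lat0, lon0, dest$lat, dest$lon)
    npt <- max(2L, ceiling(total / step_km) + 1L)
    f <- seq(0, 1, length.out = npt)
    pts <- tibble(lat = lat0 + f * (dest$lat - lat0),
                  lon = lon0 + f * (dest$lon - lon0))
    d <- f * total
  }
  tibble(lat = pts$lat, lon = pts$lon,
         ts = t0 + d * 1000 / speed_ms)
}
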