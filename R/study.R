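#' Default bounding box of the synthetic study region
#'
#' Covers the default [coast_geometry()] arc (tagging coast, bight interior
#' and far coast) with a margin for weather interpolation.
#'
#' @return Named numeric vector `c(lat_min, lat_max, lon_min, lon_max)`.
#' @export
study_bbox <- function() {
  c(lat_min = 53.3, lat_max = 55.9, lon_min = 6.3, lon_max = 9.8)
}

#' Simulate a two-season departure study with known ground truth
#'
#' Emulates the full study design: birds tagged in two autumn catching
#' windows (one per year), each season with its own autocorrelated weather
#' field, departures driven by the behavioural model, and the analysis-ready
#' counting-process table assembled through the package's own covariate
#' pipeline. One species-level standardization — pooled over both seasons'
#' bird-nights — drives both the behavioural model and the returned
#' covariates, so fitted coefficients are directly comparable to the
#' generating ones.
#'
#' @param n_birds Total birds over both seasons (split evenly).
#' @param params A [behaviour_params()].
#' @param seed Integer seed (all internal seeds derive from it).
#' @param geometry A [coast_geometry()].
#' @param bbox Weather bounding box, as [study_bbox()].
#' @param z_columns Covariates standardized for the returned rows.
#' @return List with `rows` (counting-process tibble, z-scored), `truth`
#'   (per-bird truth with season's `nightly` tables bound as attribute),
#'   `deployments`, and `z_params`.
#' @export
simulate_departure_study <- function(n_birds = 300,
                                     params = behaviour_params(),
                                     seed,
                                     geometry = coast_geometry(),
                                     bbox = study_bbox(),
                                     z_columns = c("v_wind", "total_cloud",
                                                   "u_wind")) {
  n1 <- ceiling(n_birds / 2)
  n2 <- n_birds - n1
  dep1 <- generate_deployments(n1, geometry,
                               date_range = as.Date(c("2017-09-28",
                                                      "2017-10-24")),
                               seed = seed)
  dep2 <- generate_deployments(n2, geometry,
                               date_range = as.Date(c("2018-10-03",
                                                      "2018-10-17")),
                               seed = seed + 1L)
  dep2$bird_id <- sub("^B", "C", dep2$bird_id)
  wx1 <- generate_weather(bbox, as.POSIXct(c("2017-09-28", "2017-11-30"),
                                           tz = "UTC"), seed = seed + 2L)
  wx2 <- generate_weather(bbox, as.POSIXct(c("2018-10-03", "2018-12-05"),
                                           tz = "UTC"), seed = seed + 3L)

  # pass 1 exposes each season's nightly sunset weather; their pooled
  # per-species moments define the single shared z-transform
  t1 <- simulate_birds(dep1, wx1, params, geometry, seed = seed + 4L)
  t2 <- simulate_birds(dep2, wx2, params, geometry, seed = seed + 5L)
  nightly <- dplyr::bind_rows(attr(t1, "nightly"), attr(t2, "nightly"))
  zp <- nightly |>
    group_by(.data$species) |>
    summarise(across(dplyr::all_of(z_columns),
                     list(mean = ~ mean(.x), sd = ~ sd(.x)),
                     .names = "{.col}.{.fn}"),
              .groups = "drop") |>
    tidyr::pivot_longer(-"species", names_to = c("column", "stat"),
                        names_sep = "\\.", values_to = "value") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")

  tr1 <- simulate_birds(dep1, wx1, params, geometry, seed = seed + 4L,
                        z_params = zp)
  tr2 <- simulate_birds(dep2, wx2, params, geometry, seed = seed + 5L,
                        z_params = zp)
  fl1 <- tr1 |> filter(!.data$censored) |>
    transmute(bird_id = .data$bird_id, start_time = .data$onset_ts)
  fl2 <- tr2 |> filter(!.data$censored) |>
    transmute(bird_id = .data$bird_id, start_time = .data$onset_ts)
  raw <- dplyr::bind_rows(
    departure_covariates(dep1, fl1, wx1, z = FALSE),
    departure_covariates(dep2, fl2, wx2, z = FALSE))
  rows <- expand_counting_process(apply_z(raw, zp))

  truth <- dplyr::bind_rows(tr1, tr2)
  attr(truth, "nightly") <- dplyr::bind_rows(attr(tr1, "nightly"),
                                             attr(tr2, "nightly"))
  list(rows = rows, truth = truth,
       deployments = dplyr::bind_rows(dep1, dep2), z_params = zp)
}

#' Simulate a single-season route-choice study
#'
#' One autumn cohort; for every departed bird the returned row carries the
#' binary route, the z-scored eastward wind of its departure night and its
#' z-scored stopover duration — the exact covariates the behavioural model
#' drew the route from, so the logistic fit measures pure GLM recovery.
#'
#' @inheritParams simulate_departure_study
#' @return Tibble of route rows (`bird_id`, `species`, `route01`,
#'   `u_wind_z`, `min_stopover_days_z`) with the truth tibble as attribute
#'   `"truth"`.
#' @export
simulate_route_study <- function(n_birds = 500,
                                 params = behaviour_params(),
                                 seed,
                                 geometry = coast_geometry(),
                                 bbox = study_bbox()) {
  dep <- generate_deployments(n_birds, geometry, seed = seed)
  wx <- generate_weather(bbox, as.POSIXct(c("2017-09-28", "2017-12-10"),
                                          tz = "UTC"), seed = seed + 1L)
  tr <- simulate_birds(dep, wx, params, geometry, seed = seed + 2L)
  nightly <- attr(tr, "nightly")
  dep_night <- nightly |>
    select("bird_id", "date", "z_u_wind")
  rows <- tr |>
    filter(!.data$censored) |>
    left_join(dep_night, by = c("bird_id",
                                "true_departure_date" = "date")) |>
    group_by(.data$species) |>
    mutate(min_stopover_days_z =
             (.data$stopover_days - mean(.data$stopover_days)) /
             sd(.data$stopover_days)) |>
    ungroup() |>
    transmute(bird_id = .data$bird_id, species = .data$species,
              route01 = as.integer(.data$true_route == "offshore"),
              u_wind_z = .data$z_u_wind,
              min_stopover_days_z = .data$min_stopover_days_z)
  attr(rows, "truth") <- tr
  rows
}
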