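WEATHER_VARS <- c("u_wind", "v_wind", "rel_humidity", "air_pressure",
                  "air_temp", "precip_rate", "total_cloud")
# precip and cloud are carried as 6-h block means, the rest as instantaneous
BLOCK_VARS <- c("precip_rate", "total_cloud")
INSTANT_VARS <- setdiff(WEATHER_VARS, BLOCK_VARS)

#' Gridded weather field container
#'
#' Regular lat x lon x time grid holding the seven analysis variables:
#' u/v wind (m/s, eastward/northward positive), relative humidity (%),
#' air pressure (hPa), air temperature (deg C), precipitation rate (mm/h) and
#' total cloud cover (%).
#'
#' @param lat,lon Strictly increasing coordinate vectors (decimal degrees).
#' @param time Strictly increasing `POSIXct` (UTC) time steps.
#' @param vars Named list of numeric arrays, each `length(lat) x length(lon)
#'   x length(time)`, covering all seven variables.
#' @return An object of class `weather_field`.
#' @export
weather_field <- function(lat, lon, time, vars) {
  stopifnot(is.numeric(lat), is.numeric(lon), inherits(time, "POSIXct"))
  if (length(time) < 1 || any(diff(as.numeric(time)) <= 0))
    abort("`time` must be strictly increasing.", class = "coastflight_config_error")
  if (any(diff(lat) <= 0) || any(diff(lon) <= 0))
    abort("`lat` and `lon` must be strictly increasing.",
          class = "coastflight_config_error")
  missing_vars <- setdiff(WEATHER_VARS, names(vars))
  if (length(missing_vars))
    abort(paste0("missing weather variables: ",
                 paste(missing_vars, collapse = ", ")),
          class = "coastflight_config_error")
  dims <- c(length(lat), length(lon), length(time))
  for (v in WEATHER_VARS) {
    if (!identical(dim(vars[[v]]), as.integer(dims)))
      abort(paste0("variable `", v, "` has wrong dimensions."),
            class = "coastflight_config_error")
  }
  structure(list(lat = lat, lon = lon, time = time,
                 vars = vars[WEATHER_VARS]),
            class = "weather_field")
}

#' @export
print.weather_field <- function(x, ...) {
  cat("<weather_field> ", length(x$lat), " x ", length(x$lon), " x ",
      length(x$time), " (lat x lon x time)\n", sep = "")
  cat("  lat ", min(x$lat), "..", max(x$lat),
      "  lon ", min(x$lon), "..", max(x$lon), "\n", sep = "")
  cat("  time ", format(min(x$time)), " .. ", format(max(x$time)),
      " UTC\n", sep = "")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.weather_field <- function(x, ...) {
  grid <- tidyr::expand_grid(time = x$time, lon = x$lon, lat = x$lat)
  # expand_grid varies the last column fastest == array's first dim (lat)
  vals <- purrr::map(x$vars, ~ as.vector(.x))
  dplyr::bind_cols(grid[, c("lat", "lon", "time")], tibble::as_tibble(vals))
}

#' Default parameters of the synthetic weather generator
#'
#' Long-run means and standard deviations per variable plus a common temporal
#' autocorrelation. Defaults emulate late-autumn conditions over a temperate
#' coastal sea: prevailing winds with a positive eastward and slightly
#' negative northward component, high humidity and broken cloud.
#'
#' @param mean,sd Named numeric vectors over the seven weather variables.
#' @param autocorrelation Lag-1 temporal correlation of every variable,
#'   in `[0, 1)`.
#' @param n_lat,n_lon Grid resolution used by [generate_weather()].
#' @return A list of class `weather_params`.
#' @export
weather_params <- function(
    mean = c(u_wind = 2.5, v_wind = -0.5, rel_humidity = 78,
             air_pressure = 1010, air_temp = 9, precip_rate = 0.05,
             total_cloud = 60),
    sd = c(u_wind = 3.5, v_wind = 3.5, rel_humidity = 12,
           air_pressure = 9, air_temp = 4, precip_rate = 0.08,
           total_cloud = 30),
    autocorrelation = 0.7,
    n_lat = 5, n_lon = 5) {
  if (autocorrelation < 0 || autocorrelation >= 1)
    abort("`autocorrelation` must lie in [0, 1).",
          class = "coastflight_config_error")
  structure(list(mean = mean[WEATHER_VARS], sd = sd[WEATHER_VARS],
                 autocorrelation = autocorrelation,
                 n_lat = n_lat, n_lon = n_lon),
            class = "weather_params")
}

#' Generate a synthetic autocorrelated weather field
#'
#' Each variable is a stationary AR(1) process in time whose innovations are
#' spread over a small set of smooth spatial modes (constant, lat gradient,
#' lon gradient, saddle), so fields are smooth in space and have lag-1
#' temporal correlation equal to `params$autocorrelation` at every grid
#' point. Humidity and cloud are clipped to `[0, 100]` and precipitation to
#' non-negative values after simulation.
#'
#' @param bbox Named numeric vector `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param time_range Length-2 `POSIXct` (UTC), inclusive start/end.
#' @param step_hours Time step; must divide 24.
#' @param params A [weather_params()] object.
#' @param seed Integer seed; fixed seed reproduces the field exactly.
#' @return A [weather_field()].
#' @export
generate_weather <- function(bbox, time_range, step_hours = 6,
                             params = weather_params(), seed) {
  if (24 %% step_hours != 0)
    abort("`step_hours` must divide 24.", class = "coastflight_config_error")
  time_range <- as.POSIXct(time_range, tz = "UTC")
  if (length(time_range) != 2 || time_range[2] < time_range[1])
    abort("empty time range.", class = "coastflight_config_error")
  time <- seq(time_range[1], time_range[2], by = step_hours * 3600)
  if (length(time) < 2)
    abort("time range shorter than one step.", class = "coastflight_config_error")
  lat <- seq(bbox[["lat_min"]], bbox[["lat_max"]], length.out = params$n_lat)
  lon <- seq(bbox[["lon_min"]], bbox[["lon_max"]], length.out = params$n_lon)

  # spatial modes on scaled coordinates in [-1, 1]
  latn <- if (params$n_lat > 1) seq(-1, 1, length.out = params$n_lat) else 0
  lonn <- if (params$n_lon > 1) seq(-1, 1, length.out = params$n_lon) else 0
  modes <- list(
    outer(rep(1, length(latn)), rep(1, length(lonn))),
    outer(latn, rep(1, length(lonn))),
    outer(rep(1, length(latn)), lonn),
    outer(latn, lonn)
  )
  wts <- c(0.70, 0.14, 0.12, 0.04) # variance shares per mode

  withr::with_seed(seed, {
    rho <- params$autocorrelation
    nt <- length(time)
    vars <- purrr::map(setNames(WEATHER_VARS, WEATHER_VARS), function(v) {
      sdv <- params$sd[[v]]
      arr <- array(params$mean[[v]], dim = c(length(lat), length(lon), nt))
      for (k in seq_along(modes)) {
        sk <- sdv * sqrt(wts[k])
        b <- numeric(nt)
        b[1] <- rnorm(1, 0, sk)
        if (nt > 1) {
          eps <- rnorm(nt - 1, 0, sk * sqrt(1 - rho^2))
          for (t in 2:nt) b[t] <- rho * b[t - 1] + eps[t - 1]
        }
        for (t in seq_len(nt)) arr[, , t] <- arr[, , t] + b[t] * modes[[k]]
      }
      arr
    })
    vars$rel_humidity <- pmin(pmax(vars$rel_humidity, 0), 100)
    vars$total_cloud <- pmin(pmax(vars$total_cloud, 0), 100)
    vars$precip_rate <- pmax(vars$precip_rate, 0)
    weather_field(lat, lon, time, vars)
  })
}

# vectorised index/weight lookup along one grid axis; errors outside the hull
.axis_weights <- function(x, grid, what) {
  if (any(x < min(grid) - 1e-9 | x > max(grid) + 1e-9))
    abort(paste0("query outside the ", what, " range of the weather field ",
                 "(no extrapolation)."),
          class = "coastflight_extrapolation_error")
  if (length(grid) == 1) return(list(i = rep(1L, length(x)), w = rep(0, length(x))))
  i <- findInterval(x, grid, all.inside = TRUE)
  w <- (x - grid[i]) / (grid[i + 1] - grid[i])
  list(i = i, w = pmin(pmax(w, 0), 1))
}

#' Interpolate the weather field to points in space and time
#'
#' Instantaneous variables (wind, humidity, pressure, temperature) are
#' interpolated trilinearly (bilinear in space, linear in time). Block
#' variables (precipitation rate, total cloud) are returned as the 12-18 UTC
#' six-hour block mean of the query's calendar date via [sixhour_block()].
#' Vectorised over `lat`, `lon`, `time`.
#'
#' @param field A [weather_field()].
#' @param lat,lon Query coordinates (decimal degrees), inside the grid hull.
#' @param time Query `POSIXct` (UTC) times, inside the field's time range.
#' @return A tibble with one row per query: `lat`, `lon`, `valid_time` and
#'   the seven weather variables.
#' @export
interpolate_at <- function(field, lat, lon, time) {
  stopifnot(inherits(field, "weather_field"))
  time <- as.POSIXct(time, tz = "UTC")
  k <- vctrs::vec_recycle_common(lat, lon, as.numeric(time))
  lat <- k[[1]]; lon <- k[[2]]; tq <- k[[3]]
  ax <- .axis_weights(lat, field$lat, "latitude")
  ay <- .axis_weights(lon, field$lon, "longitude")
  at <- .axis_weights(tq, as.numeric(field$time), "time")
  inst <- purrr::map(setNames(INSTANT_VARS, INSTANT_VARS), function(v) {
    .trilinear(field$vars[[v]], ax, ay, at,
               length(field$lat), length(field$lon))
  })
  blocks <- purrr::map(setNames(BLOCK_VARS, BLOCK_VARS), function(v) {
    sixhour_block(field, v, as.Date(as.POSIXct(tq, origin = "1970-01-01",
                                               tz = "UTC")), lat, lon)
  })
  tibble(lat = lat, lon = lon,
         valid_time = as.POSIXct(tq, origin = "1970-01-01", tz = "UTC"),
         !!!inst, !!!blocks)
}

.trilinear <- function(arr, ax, ay, at, nlat, nlon) {
  val <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wi <- if (di == 0) 1 - ax$w else ax$w
    wj <- if (dj == 0) 1 - ay$w else ay$w
    wk <- if (dk == 0) 1 - at$w else at$w
    i <- pmin(ax$i + di, nlat)
    j <- pmin(ay$i + dj, nlon)
    tk <- pmin(at$i + dk, dim(arr)[3])
    val <- val + wi * wj * wk * arr[cbind(i, j, tk)]
  }
  val
}

#' Six-hour block mean around local sunset (12-18 UTC)
#'
#' Mean of a block variable over the fixed 12:00-18:00 UTC window of `date`,
#' spatially interpolated to (`lat`, `lon`). The window is fixed in UTC: at
#' this study region's longitudes it brackets local sunset in autumn.
#'
#' @param field A [weather_field()].
#' @param var One of `"precip_rate"`, `"total_cloud"`.
#' @param date `Date` (or coercible); vectorised together with `lat`, `lon`.
#' @param lat,lon Query coordinates.
#' @return Numeric vector of block means.
#' @export
sixhour_block <- function(field, var, date, lat, lon) {
  stopifnot(inherits(field, "weather_field"))
  var <- match.arg(var, BLOCK_VARS)
  date <- as.Date(date)
  k <- vctrs::vec_recycle_common(as.numeric(date), lat, lon)
  dnum <- k[[1]]; lat <- k[[2]]; lon <- k[[3]]
  ax <- .axis_weights(lat, field$lat, "latitude")
  ay <- .axis_weights(lon, field$lon, "longitude")
  tnum <- as.numeric(field$time)
  out <- numeric(length(dnum))
  nlat <- length(field$lat); nlon <- length(field$lon)
  for (d in unique(dnum)) {
    sel_rows <- which(dnum == d)
    t0 <- d * 86400 + 12 * 3600
    t1 <- d * 86400 + 18 * 3600
    frames <- which(tnum >= t0 - 1 & tnum <= t1 + 1)
    if (!length(frames))
      abort(paste0("12-18 UTC block of ", as.Date(d, origin = "1970-01-01"),
                   " not covered by the weather field."),
            class = "coastflight_extrapolation_error")
    acc <- 0
    for (fr in frames) {
      axs <- list(i = ax$i[sel_rows], w = ax$w[sel_rows])
      ays <- list(i = ay$i[sel_rows], w = ay$w[sel_rows])
      att <- list(i = rep(min(fr, dim(field$vars[[var]])[3]), length(sel_rows)),
                  w = rep(0, length(sel_rows)))
      acc <- acc + .trilinear(field$vars[[var]], axs, ays, att, nlat, nlon)
    }
    out[sel_rows] <- acc / length(frames)
  }
  out
}
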