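suppressMessages({
  library(dplyr)
  library(tibble)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- analytic weather fields -------------------------------------------------

# field whose every variable is affine in lat, lon and time:
# value = offset + b*lat + c*lon + d*hours_since_t0  (trilinear-exact)
affine_field <- function(b = 2, c = -1, d = 0.5,
                         lat = seq(53, 56, length.out = 4),
                         lon = seq(6, 10, length.out = 5),
                         time = seq(as.POSIXct("2017-10-01", tz = "UTC"),
                                    by = 3600, length.out = 49)) {
  h <- as.numeric(difftime(time, time[1], units = "hours"))
  one <- function(offset) {
    arr <- array(0, dim = c(length(lat), length(lon), length(time)))
    for (k in seq_along(time))
      arr[, , k] <- offset + outer(b * lat, c * lon, `+`) + d * h[k]
    arr
  }
  vars <- lapply(setNames(as.list(seq(0, 60, by = 10)),
                          c("u_wind", "v_wind", "rel_humidity",
                            "air_pressure", "air_temp", "precip_rate",
                            "total_cloud")), one)
  weather_field(lat, lon, time, vars)
}

# constant-valued field
constant_field <- function(value = 5,
                           time = seq(as.POSIXct("2017-10-01", tz = "UTC"),
                                      by = 6 * 3600, length.out = 9)) {
  lat <- seq(53, 56, length.out = 3)
  lon <- seq(6, 10, length.out = 3)
  arr <- array(value, dim = c(3, 3, length(time)))
  weather_field(lat, lon, time,
                setNames(rep(list(arr), 7),
                         c("u_wind", "v_wind", "rel_humidity", "air_pressure",
                           "air_temp", "precip_rate", "total_cloud")))
}

small_weather <- function(seed = 99) {
  generate_weather(study_bbox(),
                   as.POSIXct(c("2017-09-28", "2017-11-20"), tz = "UTC"),
                   step_hours = 6, seed = seed)
}

# --- receiver networks and runs ----------------------------------------------

# minimal station table at given coordinates
station_table <- function(lat, lon, ids = NULL, offshore = FALSE) {
  n <- length(lat)
  tibble(
    station_id = ids %||% sprintf("S%02d", seq_len(n)),
    lat = lat, lon = lon, detection_radius_km = 10,
    active_from = as.POSIXct("2017-01-01", tz = "UTC"),
    active_to = as.POSIXct("2019-01-01", tz = "UTC"),
    offshore_flag = rep(offshore, length.out = n)
  )
}

# bare run rows (signal features irrelevant for segmentation tests)
run_rows <- function(tag_id, station_id, ts) {
  n <- length(ts)
  tibble(
    run_id = sprintf("%s-R%03d", tag_id[1], seq_len(n)),
    tag_id = rep(tag_id, length.out = n),
    station_id = rep(station_id, length.out = n),
    antenna_id = paste0(rep(station_id, length.out = n), "-A1"),
    ts = as.POSIXct(ts, tz = "UTC"),
    run_len = 5L, burst_slop = 0.02, freq_sd = 0.02, slop = 0.5,
    tag_model = "NTQB2-1"
  )
}

# --- independent oracles -----------------------------------------------------

# brute-force flight segmentation: enumerate maximal chains with all gaps
# < max_gap_h, then apply the acceptance criteria independently
oracle_segments <- function(runs, network, max_gap_h = 7, min_span_km = 35,
                            min_stations = 3) {
  out <- list()
  for (bird in sort(unique(runs$tag_id))) {
    g <- runs[runs$tag_id == bird, ]
    g <- g[order(g$ts), ]
    idx_sets <- list()
    cur <- 1
    for (i in seq_len(nrow(g))[-1]) {
      gap <- as.numeric(difftime(g$ts[i], g$ts[i - 1], units = "hours"))
      if (gap < max_gap_h) cur <- c(cur, i)
      else { idx_sets[[length(idx_sets) + 1]] <- cur; cur <- i }
    }
    idx_sets[[length(idx_sets) + 1]] <- cur
    for (idx in idx_sets) {
      ch <- g[idx, ]
      stations <- unique(ch$station_id)
      if (length(stations) < 2) next
      p1 <- network[network$station_id == ch$station_id[1], ]
      p2 <- network[network$station_id == ch$station_id[nrow(ch)], ]
      span <- great_circle_km(p1$lat, p1$lon, p2$lat, p2$lon)
      if (span >= min_span_km || length(stations) >= min_stations) {
        out[[length(out) + 1]] <- tibble(
          bird_id = bird, start_time = ch$ts[1],
          end_time = ch$ts[nrow(ch)], n_runs = nrow(ch),
          n_stations = length(stations),
          station_seq = paste(ch$station_id, collapse = ">"))
      }
    }
  }
  if (!length(out)) {
    return(tibble(bird_id = character(),
                  start_time = as.POSIXct(character(), tz = "UTC"),
                  end_time = as.POSIXct(character(), tz = "UTC"),
                  n_runs = integer(), n_stations = integer(),
                  station_seq = character()))
  }
  dplyr::bind_rows(out) |> arrange(start_time, bird_id)
}

# random detection stream over a small random network
random_stream <- function(seed) {
  withr::with_seed(seed, {
    net <- station_table(lat = runif(6, 53.5, 55.5),
                         lon = runif(6, 6.5, 9.5))
    n_birds <- sample(1:3, 1)
    runs <- purrr::map(seq_len(n_birds), function(b) {
      n <- sample(2:14, 1)
      t0 <- as.POSIXct("2017-10-10", tz = "UTC") + runif(1, 0, 5) * 86400
      gaps <- runif(n - 1, 0, 12) * 3600   # some gaps straddle 7 h
      run_rows(paste0("B", b),
               sample(net$station_id, n, replace = TRUE),
               t0 + cumsum(c(0, gaps)))
    }) |> dplyr::bind_rows()
    list(runs = runs, network = net)
  })
}

# dense 1-D grid maximization of the Breslow/Efron partial likelihood for a
# single covariate on (start, stop] data — the independent Cox oracle
cox_grid_oracle <- function(rows, x, lo = -2, hi = 2, n_grid = 80001,
                            ties = "breslow") {
  stopifnot(ties %in% c("breslow", "efron"))
  ev_times <- sort(unique(rows$stop[rows$event == 1]))
  grid <- seq(lo, hi, length.out = n_grid)
  ll <- vapply(grid, function(b) {
    total <- 0
    for (t in ev_times) {
      at_risk <- rows$start < t & rows$stop >= t
      dead <- at_risk & rows$stop == t & rows$event == 1
      xr <- x[at_risk]; xd <- x[dead]
      d <- length(xd)
      if (ties == "breslow") {
        total <- total + sum(b * xd) - d * log(sum(exp(b * xr)))
      } else {
        sr <- sum(exp(b * xr)); sd_ <- sum(exp(b * xd))
        total <- total + sum(b * xd) -
          sum(log(sr - (seq_len(d) - 1) / d * sd_))
      }
    }
    total
  }, numeric(1))
  grid[which.max(ll)]
}

# the 3-subject toy dataset with a closed-form partial-likelihood root
cox_toy_rows <- function() {
  tibble(bird_id = c("a", "b", "c"), start = 0, stop = c(1, 2, 3),
         event = 1L, x = c(1, 0, 1))
}

# direct binomial log-likelihood at fitted probabilities (Nagelkerke oracle)
binom_loglik <- function(y, p) sum(y * log(p) + (1 - y) * log(1 - p))
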