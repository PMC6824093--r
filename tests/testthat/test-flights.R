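t0 <- as.POSIXct("2017-10-10 18:00", tz = "UTC")

# two stations 30 km apart (N-S), one 40 km further, one far station
seg_net <- station_table(
  lat = c(54.0, 54.0 + 30 / 111.19, 54.0 + 70 / 111.19, 55.4),
  lon = c(8.0, 8.0, 8.0, 9.4),
  ids = c("N1", "N2", "N3", "N4"))

test_that("chains failing both the 35-km and 3-station criteria are rejected", {
  runs <- run_rows("B1", c("N1", "N2"), t0 + c(0, 3600))
  expect_equal(nrow(segment_flights(runs, seg_net)), 0)
})

test_that("three distinct receivers suffice even under 35 km of displacement", {
  # N1 -> N2 -> back near N1: displacement 0-30 km but 3 stations
  runs <- run_rows("B1", c("N1", "N2", "N3", "N1"),
                   t0 + c(0, 3600, 7200, 10800))
  fl <- segment_flights(runs, seg_net)
  expect_equal(nrow(fl), 1)
  expect_equal(fl$n_stations, 3L)
  # and with exactly 3 stations, 20 km span variant
  runs2 <- run_rows("B2", c("N1", "N2", "N1"), t0 + c(0, 3600, 7200)) |>
    mutate(station_id = c("N1", "N2", "N1"))
  expect_equal(nrow(segment_flights(runs2, seg_net)), 0) # only 2 distinct
})

test_that("a 35-km displacement with two stations is a flight; 8-h gaps cut chains", {
  runs <- run_rows("B1", c("N1", "N3", "N1", "N2"),
                   t0 + c(0, 2 * 3600, 11 * 3600, 12 * 3600))
  fl <- segment_flights(runs, seg_net)
  expect_equal(nrow(fl), 1) # second chain spans 30 km with 2 stations: rejected
  expect_equal(fl$start_station, "N1")
  expect_equal(fl$end_station, "N3")
  expect_gt(fl$span_km, 35)
  expect_equal(fl$n_runs, 2L)
})

test_that("an exactly 7-hour gap splits the chain (strict < rule)", {
  runs <- run_rows("B1", c("N1", "N3", "N3", "N1"),
                   t0 + c(0, 3600, 3600 + 7 * 3600, 3600 + 8 * 3600))
  fl <- segment_flights(runs, seg_net)
  expect_equal(nrow(fl), 2) # both halves span >= 35 km with 2 stations
  expect_equal(fl$n_runs, c(2L, 2L))
})

test_that("runs at unknown stations raise an error", {
  runs <- run_rows("B1", c("N1", "XX"), t0 + c(0, 3600))
  expect_error(segment_flights(runs, seg_net),
               class = "coastflight_station_error")
})

test_that("segmentation equals the brute-force chain oracle on random streams", {
  for (seed in 1:300) {
    s <- random_stream(seed)
    got <- segment_flights(s$runs, s$network) |>
      select(bird_id, start_time, end_time, n_runs, n_stations, station_seq)
    want <- oracle_segments(s$runs, s$network)
    expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
  }
})

test_that("first_flights keeps the earliest flight per bird with stated tie-breaks", {
  fl <- tibble(
    flight_id = c("F1", "F2", "F3", "F4", "F5"),
    bird_id = c("A", "A", "B", "C", "C"),
    start_time = t0 + c(5 * 86400, 0, 0, 0, 0),
    n_stations = c(2L, 2L, 3L, 2L, 4L),
    station_seq = c("a>b", "a>c", "x>y>z", "m>n", "d>e>f>g"),
    detections = vector("list", 5))
  ff <- first_flights(fl)
  expect_equal(nrow(ff), 3)
  expect_equal(ff$flight_id[ff$bird_id == "A"], "F2") # earliest
  expect_equal(ff$flight_id[ff$bird_id == "C"], "F5") # tie -> more stations
  expect_equal(nrow(first_flights(fl[0, ])), 0)
})

test_that("route classification follows the threshold/offshore-station rule", {
  mk_flight <- function(start_lat, end_lon, stations) {
    tibble(flight_id = "F", bird_id = "B", start_lat = start_lat,
           start_lon = 8.8, start_time = t0,
           end_lat = 53.9, end_lon = end_lon,
           detections = list(tibble(station_id = stations)))
  }
  rule <- route_rule(offshore_station_ids = c("HEL1", "FINO1"))
  expect_equal(classify_route(mk_flight(54.50, 7.90, "N1"), rule)$route,
               "offshore")
  expect_equal(classify_route(mk_flight(54.00, 7.90, "N1"), rule)$route,
               "alongshore")
  expect_equal(classify_route(mk_flight(54.00, 9.00, c("N1", "HEL1")),
                              rule)$route, "offshore")
  # exactly at the thresholds: strict comparisons -> alongshore
  expect_equal(classify_route(mk_flight(54.135, 7.90, "N1"), rule)$route,
               "alongshore")
  expect_equal(classify_route(mk_flight(54.50, 8.08, "N1"), rule)$route,
               "alongshore")
})

test_that("classification is exhaustive, disjoint and order-invariant", {
  study <- simulate_departure_study(40, seed = 1001)
  net <- generate_network(18, 4, seed = 1002)
  runs <- simulate_detections(study$truth, net,
                              noise_params(false_positive_rate = 0),
                              seed = 1003)
  fl <- first_flights(segment_flights(runs, net))
  rule <- route_rule(offshore_station_ids =
                       net$station_id[net$offshore_flag])
  cls <- classify_route(fl, rule)
  expect_equal(sum(cls$route == "offshore") +
                 sum(cls$route == "alongshore"), nrow(fl))
  # permuting detections within a flight does not change the class
  withr::with_seed(5, {
    cls2 <- cls
    cls2$detections <- purrr::map(cls$detections,
                                  ~ .x[sample.int(nrow(.x)), ])
  })
  cls2 <- classify_route(cls2 |> select(-route), rule)
  expect_equal(cls2$route, cls$route)
})

test_that("stopover metrics use calendar dates and sunset offsets", {
  depl <- tibble(bird_id = "B", deploy_date = as.Date("2017-10-01"))
  fl <- tibble(flight_id = "F", bird_id = "B",
               start_lat = 54.3, start_lon = 8.6,
               start_time = sunset_utc(as.Date("2017-10-03"), 54.3, 8.6) +
                 2 * 3600,
               detections = vector("list", 1))
  m <- stopover_metrics(fl, depl)
  expect_equal(m$min_stopover_days, 2L)
  expect_equal(m$onset_rel_sunset_h, 2, tolerance = 1e-8)
  bad <- fl |> mutate(start_time = as.POSIXct("2017-09-20", tz = "UTC"))
  expect_error(stopover_metrics(bad, depl),
               class = "coastflight_order_error")
})
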