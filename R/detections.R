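#' Detection-noise parameters
#'
#' Class-specific distributions of the four run-level signal features plus
#' the false-positive injection rate. True detections have long runs, tight
#' burst timing and stable frequency; false positives are short, sloppy and
#' unstable — the separation the run filter exploits.
#'
#' @param false_positive_rate Expected false-positive runs per receiver-hour.
#' @param true_features,fp_features Lists with `run_len_lambda` (Poisson mean
#'   of run length above the class minimum) and `mean`/`sd` pairs for
#'   `burst_slop` (s), `freq_sd` (kHz) and `slop`.
#' @param tag_models Character vector of tag models sampled per run.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(
    false_positive_rate = 0.02,
    true_features = list(run_len_min = 2, run_len_lambda = 6,
                         burst_slop = c(0.02, 0.01),
                         freq_sd = c(0.02, 0.01),
                         slop = c(0.5, 0.2)),
    fp_features = list(run_len_min = 1, run_len_lambda = 0.7,
                       burst_slop = c(0.12, 0.04),
                       freq_sd = c(0.09, 0.03),
                       slop = c(2.0, 0.6)),
    tag_models = c("NTQB2-1", "NTQB2-2")) {
  if (false_positive_rate < 0)
    abort("`false_positive_rate` must be >= 0.",
          class = "coastflight_config_error")
  structure(list(false_positive_rate = false_positive_rate,
                 true_features = true_features, fp_features = fp_features,
                 tag_models = tag_models),
            class = "noise_params")
}

.draw_features <- function(n, feat, tag_models) {
  tibble(
    run_len = feat$run_len_min + rpois(n, feat$run_len_lambda),
    burst_slop = pmax(rnorm(n, feat$burst_slop[1], feat$burst_slop[2]), 0),
    freq_sd = pmax(rnorm(n, feat$freq_sd[1], feat$freq_sd[2]), 0),
    slop = pmax(rnorm(n, feat$slop[1], feat$slop[2]), 0),
    tag_model = sample(tag_models, n, replace = TRUE)
  )
}

#' Simulate detection runs from true tracks plus injected false positives
#'
#' A true run is emitted for every contiguous segment of a bird's track that
#' passes within a station's detection radius while the station is active
#' (timestamped at closest approach). False positives are injected per
#' receiver-hour at `noise$false_positive_rate` over `window`, carrying real
#' tag ids but false-positive signal features. Every run carries its truth
#' label.
#'
#' @param truth Truth tibble from [simulate_birds()] (uses the `track`
#'   list-column and `bird_id`).
#' @param network Station tibble from [generate_network()].
#' @param noise A [noise_params()].
#' @param seed Integer seed.
#' @param window Optional length-2 `POSIXct` for false-positive injection;
#'   defaults to the span of all track timestamps.
#' @return Run tibble: `run_id`, `tag_id`, `station_id`, `antenna_id`, `ts`,
#'   `run_len`, `burst_slop`, `freq_sd`, `slop`, `tag_model`, `truth`.
#' @export
simulate_detections <- function(truth, network, noise = noise_params(), seed,
                                window = NULL) {
  empty <- tibble(run_id = character(), tag_id = character(),
                  station_id = character(), antenna_id = character(),
                  ts = as.POSIXct(character(), tz = "UTC"),
                  run_len = integer(), burst_slop = numeric(),
                  freq_sd = numeric(), slop = numeric(),
                  tag_model = character(), truth = character())
  tracks <- if (nrow(truth)) truth[!purrr::map_lgl(truth$track, is.null), ]
            else truth
  withr::with_seed(seed, {
    hits <- purrr::pmap(
      list(tracks$bird_id, tracks$track),
      function(bird, trk) {
        res <- purrr::pmap(network, function(station_id, lat, lon,
                                             detection_radius_km,
                                             active_from, active_to,
                                             offshore_flag, ...) {
          d <- great_circle_km(trk$lat, trk$lon, lat, lon)
          ok <- d <= detection_radius_km &
            trk$ts >= active_from & trk$ts <= active_to
          if (!any(ok)) return(NULL)
          # contiguous in-range passes
          r <- rle(ok)
          ends <- cumsum(r$lengths)
          starts <- ends - r$lengths + 1
          pass <- which(r$values)
          purrr::map(pass, function(p) {
            idx <- starts[p]:ends[p]
            best <- idx[which.min(d[idx])]
            tibble(tag_id = bird, station_id = station_id,
                   ts = trk$ts[best])
          }) |> dplyr::bind_rows()
        })
        dplyr::bind_rows(res)
      }) |> dplyr::bind_rows()

    if (nrow(hits)) {
      feats <- .draw_features(nrow(hits), noise$true_features,
                              noise$tag_models)
      hits <- dplyr::bind_cols(hits, feats) |>
        mutate(truth = "true",
               antenna_id = paste0(.data$station_id, "-A",
                                   sample.int(4, dplyr::n(), replace = TRUE)))
    }

    if (is.null(window)) {
      all_ts <- purrr::map(tracks$track, "ts")
      window <- if (length(all_ts) && sum(lengths(all_ts)) > 0)
        range(do.call(c, all_ts)) else NULL
    }
    fps <- NULL
    if (!is.null(window) && noise$false_positive_rate > 0 &&
        nrow(network) > 0 && nrow(truth) > 0) {
      fps <- purrr::pmap(network, function(station_id, active_from,
                                           active_to, ...) {
        w0 <- max(window[1], active_from)
        w1 <- min(window[2], active_to)
        hours <- as.numeric(difftime(w1, w0, units = "hours"))
        if (hours <= 0) return(NULL)
        n_fp <- rpois(1, hours * noise$false_positive_rate)
        if (n_fp == 0) return(NULL)
        tibble(tag_id = sample(truth$bird_id, n_fp, replace = TRUE),
               station_id = station_id,
               ts = w0 + runif(n_fp, 0, hours * 3600))
      }) |> dplyr::bind_rows()
      if (!is.null(fps) && nrow(fps)) {
        feats <- .draw_features(nrow(fps), noise$fp_features,
                                noise$tag_models)
        fps <- dplyr::bind_cols(fps, feats) |>
          mutate(truth = "false_positive",
                 antenna_id = paste0(.data$station_id, "-A",
                                     sample.int(4, dplyr::n(),
                                                replace = TRUE)))
      }
    }

    out <- dplyr::bind_rows(hits, fps)
    if (is.null(out) || nrow(out) == 0) return(empty)
    out |>
      arrange(.data$ts, .data$tag_id, .data$station_id) |>
      mutate(run_id = sprintf("R%06d", dplyr::row_number())) |>
      select("run_id", "tag_id", "station_id", "antenna_id", "ts",
             "run_len", "burst_slop", "freq_sd", "slop", "tag_model",
             "truth")
  })
}

#' Read and write run tables in Motus-like CSV form
#'
#' Column mapping: `tag_id` = `motusTagID`/`tagDeployID`, `station_id` =
#' `recvDeployID`, `antenna_id` = `port`, `ts` (POSIX seconds UTC),
#' `run_len` = `runLen`, `burst_slop` = `burstSlop`, `freq_sd` = `freqsd`,
#' `slop` = `slop`, `tag_model` = `tagModel`; the synthetic-only truth label
#' travels as `truthLabel`.
#'
#' @param runs Run tibble as produced by [simulate_detections()].
#' @param path File path.
#' @return `read_runs()` returns the run tibble; `write_runs()` returns
#'   `path` invisibly.
#' @export
write_runs <- function(runs, path) {
  out <- tibble(
    runID = runs$run_id, tagDeployID = runs$tag_id,
    motusTagID = runs$tag_id, recvDeployID = runs$station_id,
    port = runs$antenna_id, ts = as.numeric(runs$ts),
    runLen = runs$run_len, burstSlop = runs$burst_slop,
    freqsd = runs$freq_sd, slop = runs$slop, tagModel = runs$tag_model
  )
  if ("truth" %in% names(runs)) out$truthLabel <- runs$truth
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_runs
#' @export
read_runs <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble(
    run_id = as.character(raw$runID), tag_id = as.character(raw$motusTagID),
    station_id = as.character(raw$recvDeployID),
    antenna_id = as.character(raw$port),
    ts = as.POSIXct(raw$ts, origin = "1970-01-01", tz = "UTC"),
    run_len = raw$runLen, burst_slop = raw$burstSlop,
    freq_sd = raw$freqsd, slop = raw$slop,
    tag_model = as.character(raw$tagModel)
  )
  if ("truthLabel" %in% names(raw)) out$truth <- raw$truthLabel
  out
}
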