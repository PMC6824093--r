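mk_cov <- function(bird_id, days, event_day = NA, species = "redwing",
                   x = NULL) {
  n <- length(days)
  tibble(bird_id = bird_id, species = species,
         date = as.Date("2017-10-01") + days, day = days,
         event = as.integer(!is.na(event_day) & days == event_day),
         x = x %||% rnorm(n))
}

test_that("counting-process expansion builds gapless (start, stop] rows", {
  cov <- mk_cov("A", 1:3, event_day = 3)
  rows <- expand_counting_process(cov)
  expect_equal(rows$start, 0:2)
  expect_equal(rows$stop, 1:3)
  expect_equal(rows$event, c(0L, 0L, 1L))
  # censored bird observed 5 days -> 5 rows, all event 0
  cens <- expand_counting_process(mk_cov("B", 1:5))
  expect_equal(nrow(cens), 5)
  expect_true(all(cens$event == 0))
  # total rows = sum of per-bird days
  both <- expand_counting_process(dplyr::bind_rows(mk_cov("A", 1:3, 3),
                                                   mk_cov("B", 1:5)))
  expect_equal(nrow(both), 8)
  # a missing day raises an error naming the bird
  gap <- mk_cov("C", c(1, 2, 4), event_day = 4)
  expect_error(expand_counting_process(gap), regexp = "C",
               class = "coastflight_gap_error")
})

test_that("stopover-period strata place boundary rows per the (start, stop] rule", {
  cov <- mk_cov("A", 1:25, event_day = 25)
  rows <- expand_counting_process(cov) |> stratify_species_time(c(10, 21))
  expect_equal(rows$stratum[rows$stop == 10], 1L)
  expect_equal(rows$stratum[rows$stop == 11], 2L)
  expect_equal(rows$stratum[rows$stop == 21], 2L)
  expect_equal(rows$stratum[rows$stop == 22], 3L)
  expect_error(stratify_species_time(rows, c(-1, 5)),
               class = "coastflight_config_error")
})

test_that("3 species x 3 periods yield six interaction terms vs the reference", {
  cov <- dplyr::bind_rows(
    mk_cov("A", 1:25, 25, species = "song_thrush"),
    mk_cov("B", 1:25, 25, species = "blackbird"),
    mk_cov("C", 1:25, 25, species = "redwing"))
  rows <- expand_counting_process(cov) |> stratify_species_time(c(10, 21))
  terms <- attr(rows, "species_terms")
  expect_length(terms, 6)
  expect_setequal(terms, c(paste0("sp_blackbird_p", 1:3),
                           paste0("sp_redwing_p", 1:3)))
  expect_true(all(rows$sp_blackbird_p1[rows$species == "song_thrush"] == 0))
  # empty cuts leave the table unchanged
  rows0 <- expand_counting_process(cov)
  expect_identical(stratify_species_time(rows0, numeric(0)), rows0)
})

test_that("the Cox toy dataset reproduces its closed-form and grid-oracle root", {
  rows <- cox_toy_rows()
  fit <- fit_departure_cox(rows, ~x, cluster_by_bird = FALSE,
                           ties = "breslow")
  beta_hat <- tidy(fit)$estimate
  expect_equal(beta_hat, -0.5 * log(2), tolerance = 1e-4 / abs(0.5 * log(2)))
  oracle <- cox_grid_oracle(rows, rows$x, ties = "breslow")
  expect_lt(abs(beta_hat - oracle), 1e-4)
  # no ties here, so the Efron fit must agree too
  fit_e <- fit_departure_cox(rows, ~x, cluster_by_bird = FALSE,
                             ties = "efron")
  expect_equal(tidy(fit_e)$estimate, beta_hat, tolerance = 1e-8)
})

test_that("partial-likelihood maximizer matches the grid oracle on random toys", {
  for (seed in c(2, 3, 4)) {
    withr::with_seed(seed, {
      n <- 12
      rows <- tibble(bird_id = letters[1:n], start = 0,
                     stop = sample(1:8, n, replace = TRUE),
                     event = rbinom(n, 1, 0.8), x = rnorm(n))
    })
    if (sum(rows$event) < 2) next
    for (tie_method in c("breslow", "efron")) {
      fit <- fit_departure_cox(rows, ~x, cluster_by_bird = FALSE,
                               ties = tie_method)
      oracle <- cox_grid_oracle(rows, rows$x, ties = tie_method)
      expect_lt(abs(tidy(fit)$estimate - oracle), 1e-4)
    }
  }
})

test_that("degenerate departure fits raise explicit errors", {
  rows <- cox_toy_rows()
  expect_error(fit_departure_cox(rows |> mutate(x = 1), ~x),
               class = "coastflight_fit_error")
  expect_error(fit_departure_cox(rows |> mutate(event = 0L), ~x),
               class = "coastflight_fit_error")
  # monotone likelihood: the departing bird always has the largest x in
  # its risk set, so the partial likelihood increases without bound
  mono <- tibble(bird_id = letters[1:8], start = 0,
                 stop = c(1, 2, 3, 4, 10, 10, 10, 10),
                 event = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
                 x = c(8, 7, 6, 5, 1, 2, 3, 4))
  expect_error(fit_departure_cox(mono, ~x), class = "coastflight_fit_error")
})

test_that("clustering changes variances only; duplicate clusters keep estimates", {
  study <- simulate_departure_study(80, seed = 1300)
  f_cl <- fit_departure_cox(study$rows, ~ v_wind_z + total_cloud_z, TRUE)
  f_un <- fit_departure_cox(study$rows, ~ v_wind_z + total_cloud_z, FALSE)
  expect_equal(tidy(f_cl)$estimate, tidy(f_un)$estimate, tolerance = 1e-10)
  # duplicating every bird as its own new cluster leaves the estimate unchanged
  # (a Breslow property: its estimating equation simply doubles, whereas
  # Efron's within-tie averaging is not duplication-invariant)
  dup <- study$rows |> mutate(bird_id = paste0(bird_id, "_copy"))
  doubled <- dplyr::bind_rows(study$rows, dup)
  f_b <- fit_departure_cox(study$rows, ~ v_wind_z + total_cloud_z, TRUE,
                           ties = "breslow")
  f_dup <- fit_departure_cox(doubled, ~ v_wind_z + total_cloud_z, TRUE,
                             ties = "breslow")
  expect_equal(tidy(f_dup)$estimate, tidy(f_b)$estimate, tolerance = 1e-8)
})

test_that("AIC satisfies its identity and censored tail rows are inert", {
  study <- simulate_departure_study(60, seed = 1400)
  fit <- fit_departure_cox(study$rows, ~ v_wind_z + total_cloud_z)
  k <- length(coef(fit$coxph))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * k, tolerance = 1e-9)
  # dropping censored-only rows after the last event never changes beta
  last_event <- max(study$rows$stop[study$rows$event == 1])
  trimmed <- study$rows |> filter(!(event == 0 & start >= last_event))
  f_tr <- fit_departure_cox(trimmed, ~ v_wind_z + total_cloud_z)
  expect_equal(tidy(f_tr)$estimate, tidy(fit)$estimate, tolerance = 1e-10)
})

test_that("all-subsets AIC enumerates 2^k models and is deterministic", {
  study <- simulate_departure_study(60, seed = 1500)
  rows <- study$rows
  sel <- select_by_aic(rows, c("v_wind_z", "total_cloud_z", "u_wind_z"))
  expect_equal(nrow(sel$ranking), 2^3 - 1) # empty subset impossible for Cox
  sel2 <- select_by_aic(rows, c("v_wind_z", "total_cloud_z", "u_wind_z"))
  expect_identical(sel$ranking, sel2$ranking)
  expect_equal(sel$ranking$aic[1], min(sel$ranking$aic))
  # with forced terms the empty candidate subset is allowed: 2^k models
  rows2 <- stratify_species_time(rows)
  sel3 <- select_by_aic(rows2, c("v_wind_z", "total_cloud_z"),
                        always_terms = attr(rows2, "species_terms")[1])
  expect_equal(nrow(sel3$ranking), 4)
})

test_that("AIC selection retains a strong simulated effect", {
  keep <- logical(20)
  for (r in seq_len(20)) {
    study <- simulate_departure_study(200, seed = 1600 + r)
    rows <- study$rows |>
      mutate(noise_z = withr::with_seed(1700 + r, rnorm(dplyr::n())))
    sel <- select_by_aic(rows, c("v_wind_z", "noise_z"))
    keep[r] <- grepl("v_wind_z", sel$ranking$formula[1])
  }
  expect_gte(mean(keep), 0.95)
})

test_that("PH test: single-term global and per-term tests agree; power on reversal", {
  study <- simulate_departure_study(120, seed = 1800)
  fit1 <- fit_departure_cox(study$rows, ~v_wind_z)
  ph <- test_ph(fit1)
  expect_equal(nrow(ph), 2)
  expect_equal(unname(ph$chisq[1]), unname(ph$chisq[2]), tolerance = 1e-6)
  one_event <- tibble(bird_id = c("a", "b", "c"), start = 0, stop = 1:3,
                      event = c(1L, 0L, 0L), x = c(0.5, 0, 1))
  expect_error(test_ph(fit_departure_cox(one_event, ~x,
                                         cluster_by_bird = FALSE)),
               class = "coastflight_fit_error")

  # an effect reversing sign across stopover periods violates PH and is
  # detected in the large majority of replicates
  geom <- coast_geometry(); bbox <- study_bbox()
  pb <- behaviour_params(species_effects = list(
    blackbird = c(1.3, -1.3, -1.3)))
  rejections <- logical(60)
  for (r in seq_len(60)) {
    s0 <- 1900 + 13 * r
    dep <- generate_deployments(150, geom, seed = s0)
    wx <- generate_weather(bbox,
                           as.POSIXct(c("2017-09-28", "2017-12-10"),
                                      tz = "UTC"), seed = s0 + 1)
    tr <- simulate_birds(dep, wx, pb, geom, seed = s0 + 2)
    fl <- tr |> filter(!censored) |>
      transmute(bird_id, start_time = onset_ts)
    rows <- expand_counting_process(departure_covariates(dep, fl, wx)) |>
      mutate(sp_blackbird = as.integer(species == "blackbird"))
    fit_r <- fit_departure_cox(rows, ~ v_wind_z + sp_blackbird)
    rejections[r] <- test_ph(fit_r)$p_value[2] < 0.05
  }
  expect_gte(mean(rejections), 0.8)
})

test_that("flight-probability curves are monotone, bounded and mean-anchored", {
  study <- simulate_departure_study(100, seed = 2000)
  fit <- fit_departure_cox(study$rows, ~ v_wind_z + total_cloud_z)
  curve <- predict_flight_probability(fit, "v_wind_z")
  expect_true(all(curve$p_flight >= 0 & curve$p_flight <= 1))
  # beta_v < 0 -> flight probability decreases with v-wind
  expect_lt(tidy(fit)$estimate[1], 0)
  expect_true(all(diff(curve$p_flight) <= 1e-12))
  # null coefficients -> flat baseline event probability across the grid
  null_fit <- fit
  null_fit$coxph$coefficients[] <- 0
  flat <- predict_flight_probability(null_fit, "v_wind_z")
  expect_lt(diff(range(flat$p_flight)), 1e-9)
  expect_warning(predict_flight_probability(fit, "v_wind_z",
                                            grid = c(0, 10)),
                 regexp = "4 sd")
  expect_error(predict_flight_probability(fit, "not_a_term"),
               class = "coastflight_config_error")
})
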