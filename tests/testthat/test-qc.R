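test_that("receiver-hour and tag-level proportions use the <4 cutoff", {
  base_ts <- as.POSIXct("2017-10-10 14:00", tz = "UTC")
  runs <- run_rows("T1", "S01", base_ts + c(0, 600, 1200)) |>
    mutate(run_len = c(2L, 3L, 5L))
  f <- compute_run_features(runs)
  expect_equal(f$prop_short_runs_recv_hour, rep(2 / 3, 3))
  expect_equal(f$runs_per_recv_hour, rep(3L, 3))
  expect_equal(f$prop_short_runs_tag, rep(2 / 3, 3))
})

test_that("singleton runs and the ±25-min context window behave as defined", {
  lone <- run_rows("T9", "S01", as.POSIXct("2017-10-10 14:00", tz = "UTC")) |>
    mutate(run_len = 2L)
  f1 <- compute_run_features(lone)
  expect_equal(f1$prop_short_runs_tag, 1)
  expect_equal(f1$context_runs_25min, 0L)
  expect_equal(f1$context_antennas_25min, 0L)

  two <- run_rows("T2", c("S01", "S02"),
                  as.POSIXct("2017-10-10 14:00", tz = "UTC") + c(0, 20 * 60))
  f2 <- compute_run_features(two)
  expect_equal(f2$context_runs_25min, c(1L, 1L))
  expect_equal(f2$context_antennas_25min, c(1L, 1L))
  # 30 minutes apart: outside the window
  apart <- run_rows("T3", c("S01", "S02"),
                    as.POSIXct("2017-10-10 14:00", tz = "UTC") +
                      c(0, 30 * 60))
  f3 <- compute_run_features(apart)
  expect_equal(f3$context_runs_25min, c(0L, 0L))
})

sep_fixture <- function(seed = 100, n = 400) {
  study <- simulate_departure_study(30, seed = seed)
  net <- generate_network(12, 3, seed = seed + 1)
  runs <- simulate_detections(study$truth, net, noise_params(), seed = seed + 2)
  compute_run_features(runs)
}

test_that("filter model separates separable synthetic classes (AUROC 1)", {
  feats <- sep_fixture()
  mod <- fit_filter_model(feats, feats$truth, seed = 1, network_id = "A")
  expect_equal(glance(mod)$auroc, 1, tolerance = 1e-6)
  # refit determinism
  mod2 <- fit_filter_model(feats, feats$truth, seed = 1, network_id = "A")
  expect_identical(mod$coef, mod2$coef)
  # single-class labels error
  expect_error(fit_filter_model(feats, rep(TRUE, nrow(feats))),
               class = "coastflight_label_error")
})

test_that("labels independent of features give chance-level AUROC", {
  n <- 5000
  withr::with_seed(7, {
    feats <- tibble(
      run_id = sprintf("R%05d", seq_len(n)),
      run_len = 1L + rpois(n, 4), burst_slop = abs(rnorm(n, 0.05, 0.03)),
      freq_sd = abs(rnorm(n, 0.05, 0.03)), slop = abs(rnorm(n, 1, 0.5)),
      runs_per_recv_hour = 1L + rpois(n, 2),
      prop_short_runs_recv_hour = runif(n), prop_short_runs_tag = runif(n),
      context_runs_25min = rpois(n, 1), context_antennas_25min = rpois(n, 1),
      tag_model = sample(c("NTQB2-1", "NTQB2-2"), n, replace = TRUE))
    labels <- runif(n) < 0.4
  })
  # fit on one half, score the held-out half: out-of-sample AUROC is free of
  # the optimism a 10-term fit shows even on pure noise
  train <- seq_len(n) <= n / 2
  mod <- suppressWarnings(fit_filter_model(feats[train, ], labels[train],
                                           seed = 2))
  p_out <- predict_fp_prob(mod, feats[!train, ])
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = labels[!train], predictor = p_out, quiet = TRUE,
    direction = "<", levels = c(FALSE, TRUE))))
  expect_lt(abs(auc - 0.5), 0.03)
})

test_that("threshold filtering is strict and partitions the run set", {
  feats <- sep_fixture(seed = 300)
  study <- simulate_departure_study(30, seed = 300)
  net <- generate_network(12, 3, seed = 301)
  runs <- simulate_detections(study$truth, net, noise_params(), seed = 302)
  mod <- fit_filter_model(compute_run_features(runs), runs$truth, seed = 1)
  flt <- score_and_filter(runs, mod, threshold = 0.8)
  expect_equal(nrow(flt$kept) + nrow(flt$removed), nrow(runs))
  expect_length(intersect(flt$kept$run_id, flt$removed$run_id), 0)
  expect_true(all(flt$kept$fp_prob < 0.8))
  expect_true(all(flt$removed$fp_prob >= 0.8))
  # strictness at an exactly attained threshold value
  thr <- max(flt$scores$fp_prob)
  at_thr <- score_and_filter(runs, mod, threshold = thr)
  expect_false(thr %in% at_thr$kept$fp_prob)
  # bounds
  expect_equal(nrow(score_and_filter(runs, mod, 1.0)$kept), nrow(runs))
  expect_equal(nrow(score_and_filter(runs, mod, 0.0)$kept), 0)
})

test_that("filtering the kept set again removes nothing (idempotence)", {
  study <- simulate_departure_study(30, seed = 400)
  net <- generate_network(12, 3, seed = 401)
  runs <- simulate_detections(study$truth, net, noise_params(), seed = 402)
  mod <- fit_filter_model(compute_run_features(runs), runs$truth, seed = 1)
  once <- score_and_filter(runs, mod, 0.8)
  twice <- score_and_filter(once$kept |> select(-fp_prob), mod, 0.8)
  expect_equal(nrow(twice$removed), 0)
  expect_setequal(twice$kept$run_id, once$kept$run_id)
})

test_that("filtering lowers the false-positive fraction on synthetic data", {
  study <- simulate_departure_study(40, seed = 500)
  net <- generate_network(15, 4, seed = 501)
  runs <- simulate_detections(study$truth, net, noise_params(), seed = 502)
  mod <- fit_filter_model(compute_run_features(runs), runs$truth, seed = 1)
  expect_gte(glance(mod)$auroc, 0.9)
  flt <- score_and_filter(runs, mod, 0.8)
  expect_lt(mean(flt$kept$truth == "false_positive"),
            mean(runs$truth == "false_positive"))
})

test_that("models are parameterized per network and applied separately", {
  study_a <- simulate_departure_study(25, seed = 600)
  study_b <- simulate_departure_study(25, seed = 700)
  net_a <- generate_network(10, 2, seed = 601)
  net_b <- generate_network(14, 5, seed = 701)
  runs_a <- simulate_detections(study_a$truth, net_a,
                                noise_params(false_positive_rate = 0.01),
                                seed = 602)
  runs_b <- simulate_detections(study_b$truth, net_b,
                                noise_params(false_positive_rate = 0.05),
                                seed = 702)
  models <- list(
    A = fit_filter_model(compute_run_features(runs_a), runs_a$truth,
                         seed = 1, network_id = "A"),
    B = fit_filter_model(compute_run_features(runs_b), runs_b$truth,
                         seed = 1, network_id = "B"))
  expect_equal(glance(models$A)$network_id, "A")
  expect_equal(glance(models$B)$network_id, "B")
  expect_false(identical(models$A$coef, models$B$coef))
  kept_a <- score_and_filter(runs_a, models$A, 0.8)$kept
  kept_b <- score_and_filter(runs_b, models$B, 0.8)$kept
  expect_lt(mean(kept_a$truth == "false_positive"),
            mean(runs_a$truth == "false_positive"))
  expect_lt(mean(kept_b$truth == "false_positive"),
            mean(runs_b$truth == "false_positive"))
})

test_that("rule-based score ranks false positives above true runs", {
  feats <- sep_fixture(seed = 800)
  s <- rule_based_score(feats)
  expect_true(all(s >= 0 & s <= 1))
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = feats$truth == "false_positive", predictor = s,
    quiet = TRUE, direction = "<", levels = c(FALSE, TRUE))))
  expect_gt(auc, 0.85)
})

test_that("missing feature values raise an error naming the run", {
  feats <- sep_fixture(seed = 900)
  mod <- fit_filter_model(feats, feats$truth, seed = 1)
  feats$burst_slop[3] <- NA
  expect_error(predict_fp_prob(mod, feats),
               regexp = feats$run_id[3],
               class = "coastflight_feature_error")
})
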