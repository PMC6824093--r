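QC_NUMERIC_FEATURES <- c("run_len", "burst_slop", "freq_sd", "slop",
                         "runs_per_recv_hour", "prop_short_runs_recv_hour",
                         "prop_short_runs_tag", "context_runs_25min",
                         "context_antennas_25min")

#' Compute per-run false-positive screening features
#'
#' For each detection run: its four signal features, the number of runs and
#' the proportion of short runs (length < 4) in its receiver-hour bin
#' (station x UTC wall-clock hour), the proportion of short runs among all
#' runs of its tag, and the number of other runs of the same tag within
#' +/- 25 min of its timestamp together with the number of distinct antennas
#' among those.
#'
#' @param runs Run tibble (needs `run_id`, `tag_id`, `station_id`,
#'   `antenna_id`, `ts`, `run_len`, `burst_slop`, `freq_sd`, `slop`,
#'   `tag_model`).
#' @return Feature tibble, one row per run, keyed by `run_id`; carries the
#'   `truth` column through if present.
#' @export
compute_run_features <- function(runs) {
  if (nrow(runs) == 0) {
    return(runs |> mutate(runs_per_recv_hour = integer(),
                          prop_short_runs_recv_hour = numeric(),
                          prop_short_runs_tag = numeric(),
                          context_runs_25min = integer(),
                          context_antennas_25min = integer()))
  }
  out <- runs |>
    mutate(.hour_bin = lubridate::floor_date(.data$ts, "hour")) |>
    group_by(.data$station_id, .data$.hour_bin) |>
    mutate(runs_per_recv_hour = dplyr::n(),
           prop_short_runs_recv_hour = mean(.data$run_len < 4)) |>
    ungroup() |>
    group_by(.data$tag_id) |>
    mutate(prop_short_runs_tag = mean(.data$run_len < 4)) |>
    ungroup()

  ctx <- out |>
    group_by(.data$tag_id) |>
    group_modify(function(g, key) {
      tsec <- as.numeric(g$ts)
      nruns <- integer(nrow(g)); nant <- integer(nrow(g))
      for (i in seq_len(nrow(g))) {
        idx <- which(abs(tsec - tsec[i]) <= 25 * 60)
        idx <- setdiff(idx, i)
        nruns[i] <- length(idx)
        nant[i] <- length(unique(g$antenna_id[idx]))
      }
      g$context_runs_25min <- nruns
      g$context_antennas_25min <- nant
      g
    }) |>
    ungroup()

  ctx |>
    select(-".hour_bin") |>
    arrange(.data$run_id)
}

#' Fit a false-positive filter model on labelled runs
#'
#' Logistic regression of the false-positive label on the standardized
#' screening features (tag model entering as a categorical term when more
#' than one model is present). Feature means/sds are stored so the model can
#' be applied to new runs of the same network; a zero-variance feature is
#' dropped to an all-zero column with a warning.
#'
#' @param features Feature tibble from [compute_run_features()].
#' @param labels Logical vector (or `"true"`/`"false_positive"` character)
#'   marking false positives, aligned with `features` rows.
#' @param seed Integer seed recorded in the model metadata (the fit itself
#'   is deterministic).
#' @param network_id Identifier of the receiver network the model belongs
#'   to; models are fitted and applied per network.
#' @return An object of class `filter_model`.
#' @export
fit_filter_model <- function(features, labels, seed = 1L,
                             network_id = "default") {
  if (is.character(labels)) labels <- labels == "false_positive"
  stopifnot(length(labels) == nrow(features))
  if (length(unique(labels)) < 2)
    abort("both classes must be present in `labels`.",
          class = "coastflight_label_error")
  X <- features[QC_NUMERIC_FEATURES]
  center <- purrr::map_dbl(X, mean)
  scale_ <- purrr::map_dbl(X, sd)
  degenerate <- !is.finite(scale_) | scale_ == 0
  if (any(degenerate)) {
    warn(paste0("zero-variance feature(s) imputed as 0: ",
                paste(QC_NUMERIC_FEATURES[degenerate], collapse = ", ")))
    center[degenerate] <- 0
    scale_[degenerate] <- 1
    X[degenerate] <- 0
  }
  Z <- purrr::map2(X, seq_along(X), ~ (.x - center[.y]) / scale_[.y]) |>
    tibble::as_tibble()
  tag_levels <- sort(unique(features$tag_model))
  df <- Z
  df$.fp <- as.integer(labels)
  use_tag <- length(tag_levels) > 1
  if (use_tag)
    df$tag_model <- factor(features$tag_model, levels = tag_levels)
  form <- as.formula(paste(".fp ~",
                           paste(c(QC_NUMERIC_FEATURES,
                                   if (use_tag) "tag_model"),
                                 collapse = " + ")))
  fit <- suppressWarnings(glm(form, family = binomial(), data = df))
  cf <- coef(fit)
  cf[is.na(cf)] <- 0  # aliased (exactly collinear) features contribute nothing
  prob <- as.numeric(fit$fitted.values)
  auc <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                        predictor = prob, quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  structure(
    list(coef = cf, center = center, scale = scale_,
         tag_levels = tag_levels, use_tag_model = use_tag,
         meta = list(n = nrow(features), n_fp = sum(labels),
                     seed = as.integer(seed), network_id = network_id,
                     auc = auc)),
    class = "filter_model"
  )
}

#' @export
print.filter_model <- function(x, ...) {
  cat("<filter_model> network ", x$meta$network_id, ": n = ", x$meta$n,
      " runs (", x$meta$n_fp, " false positives), in-sample AUROC = ",
      round(x$meta$auc, 3), "\n", sep = "")
  invisible(x)
}

#' Predicted probability that runs are false positives
#'
#' @param model A [fit_filter_model()] model.
#' @param features Feature tibble from [compute_run_features()].
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_fp_prob <- function(model, features) {
  stopifnot(inherits(model, "filter_model"))
  missing_feats <- setdiff(QC_NUMERIC_FEATURES, names(features))
  if (length(missing_feats))
    abort(paste0("features missing from input: ",
                 paste(missing_feats, collapse = ", ")),
          class = "coastflight_feature_error")
  bad <- !complete.cases(features[QC_NUMERIC_FEATURES])
  if (any(bad))
    abort(paste0("missing feature values for run(s): ",
                 paste(features$run_id[bad], collapse = ", ")),
          class = "coastflight_feature_error")
  eta <- rep(model$coef[["(Intercept)"]], nrow(features))
  for (v in QC_NUMERIC_FEATURES) {
    z <- (features[[v]] - model$center[[v]]) / model$scale[[v]]
    eta <- eta + model$coef[[v]] * z
  }
  if (model$use_tag_model) {
    for (lv in model$tag_levels[-1]) {
      cname <- paste0("tag_model", lv)
      if (cname %in% names(model$coef))
        eta <- eta + model$coef[[cname]] * (features$tag_model == lv)
    }
  }
  # keep probabilities in the open interval so strict-threshold bounds
  # (0 keeps nothing, 1 keeps everything) hold under saturation
  pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
}

#' Score runs and filter at a false-positive probability threshold
#'
#' Features are computed on the supplied run set, scored with the given
#' network's filter model, and the table is partitioned: a run is kept iff
#' its predicted false-positive probability is strictly below `threshold`
#' (default 0.8).
#'
#' @param runs Run tibble.
#' @param model A [fit_filter_model()] model fitted on the same network.
#' @param threshold Probability cutoff; strict comparison (`< threshold`).
#' @return List with `kept` and `removed` run tibbles (each with an
#'   `fp_prob` column) and `scores`, a `(run_id, fp_prob)` tibble.
#' @export
score_and_filter <- function(runs, model, threshold = 0.8) {
  feats <- compute_run_features(runs)
  p <- predict_fp_prob(model, feats)
  scored <- runs |>
    left_join(tibble(run_id = feats$run_id, fp_prob = p), by = "run_id")
  keep <- scored$fp_prob < threshold
  list(kept = scored[keep, , drop = FALSE],
       removed = scored[!keep, , drop = FALSE],
       scores = tibble(run_id = scored$run_id, fp_prob = scored$fp_prob))
}

#' Transparent rule-based false-positive score
#'
#' A fixed-weight logistic score over the raw screening features, for
#' datasets without truth labels. Weights were chosen once from the feature
#' scales of coded NTQB-type tags (burst slop and frequency sd in their
#' native units); the score is a heuristic screen, not a calibrated
#' probability.
#'
#' @param features Feature tibble from [compute_run_features()].
#' @return Numeric score in `[0, 1]`, higher = more false-positive-like.
#' @export
rule_based_score <- function(features) {
  with(features,
       stats::plogis(-3 +
                       2.0 * (run_len < 4) +
                       12 * burst_slop +
                       18 * freq_sd +
                       0.8 * slop +
                       2.0 * prop_short_runs_recv_hour +
                       2.0 * prop_short_runs_tag -
                       0.4 * context_antennas_25min))
}

#' Serialize a filter model to JSON
#'
#' @param model A `filter_model`.
#' @param path File path.
#' @return `read_filter_model()` returns the model; `write_filter_model()`
#'   returns `path` invisibly.
#' @export
write_filter_model <- function(model, path) {
  stopifnot(inherits(model, "filter_model"))
  jsonlite::write_json(
    list(coef = as.list(model$coef), center = as.list(model$center),
         scale = as.list(model$scale), tag_levels = model$tag_levels,
         use_tag_model = model$use_tag_model, meta = model$meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_model
#' @export
read_filter_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coef = unlist(x$coef), center = unlist(x$center),
                 scale = unlist(x$scale),
                 tag_levels = as.character(x$tag_levels),
                 use_tag_model = isTRUE(x$use_tag_model), meta = x$meta),
            class = "filter_model")
}

#' @exportS3Method generics::tidy
tidy.filter_model <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @exportS3Method generics::glance
glance.filter_model <- function(x, ...) {
  tibble(n = x$meta$n, n_false_positive = x$meta$n_fp,
         auroc = x$meta$auc, network_id = x$meta$network_id)
}
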