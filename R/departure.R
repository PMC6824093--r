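#' Expand bird-days into counting-process (start, stop] rows
#'
#' One row per bird-day from deployment until the flight day (inclusive) on
#' the stopover clock: row `k` covers `(k - 1, k]` days since the bird's own
#' deployment and carries the sunset covariates of that night. The flight
#' night gets `event = 1`; censored birds get `event = 0` throughout.
#'
#' @param covariates Bird-day covariate table from [departure_covariates()]
#'   (keyed by `bird_id`, `date`, with `day` and `event`).
#' @return Tibble of rows with `start`, `stop`, `event` plus all covariate
#'   columns, ordered by bird and day; the z-parameter attribute is carried
#'   through.
#' @export
expand_counting_process <- function(covariates) {
  req <- c("bird_id", "date", "day", "event")
  missing_cols <- setdiff(req, names(covariates))
  if (length(missing_cols))
    abort(paste0("covariate table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "coastflight_config_error")
  rows <- covariates |> arrange(.data$bird_id, .data$day)
  # gapless day sequence per bird, nothing after the event
  chk <- rows |>
    group_by(.data$bird_id) |>
    summarise(gapless = identical(as.integer(.data$day),
                                  seq.int(dplyr::first(.data$day),
                                          length.out = dplyr::n())),
              post_event = any(cumsum(dplyr::lag(.data$event,
                                                 default = 0L)) > 0),
              .groups = "drop")
  if (any(!chk$gapless))
    abort(paste0("missing covariate day(s) for bird(s): ",
                 paste(chk$bird_id[!chk$gapless], collapse = ", ")),
          class = "coastflight_gap_error")
  if (any(chk$post_event))
    abort(paste0("rows after the flight day for bird(s): ",
                 paste(chk$bird_id[chk$post_event], collapse = ", ")),
          class = "coastflight_gap_error")
  out <- rows |>
    mutate(start = .data$day - 1L, stop = .data$day) |>
    select("bird_id", "start", "stop", "event", dplyr::everything())
  attr(out, "z_params") <- attr(covariates, "z_params")
  out
}

#' Assign stopover-period strata and species-by-period terms
#'
#' Cuts the stopover clock at `cuts` (default 10 and 21 days): a row with
#' `stop <= cuts[1]` is period 1, `stop <= cuts[2]` period 2, later rows
#' period 3. For every non-reference species and period a 0/1 interaction
#' column `sp_<species>_p<k>` is added, giving stratum-specific species
#' effects against one shared baseline hazard, as in a step-function
#' time-dependent coefficient.
#'
#' @param rows Counting-process rows from [expand_counting_process()].
#' @param cuts Strictly increasing positive day cuts.
#' @param reference Reference species (default `"song_thrush"` if present,
#'   else the alphabetically first).
#' @return `rows` with `stratum` and the interaction columns; the generated
#'   term names are in attribute `"species_terms"`.
#' @export
stratify_species_time <- function(rows, cuts = c(10, 21),
                                  reference = NULL) {
  if (length(cuts) == 0) return(rows)
  if (any(cuts <= 0) || is.unsorted(cuts, strictly = TRUE))
    abort("`cuts` must be strictly increasing and positive.",
          class = "coastflight_config_error")
  out <- rows |>
    mutate(stratum = 1L + findInterval(.data$stop, cuts + 0.5))
  terms <- character()
  if ("species" %in% names(out)) {
    species <- sort(unique(out$species))
    if (is.null(reference))
      reference <- if ("song_thrush" %in% species) "song_thrush"
                   else species[1]
    for (sp in setdiff(species, reference)) {
      for (k in seq_len(length(cuts) + 1)) {
        cn <- paste0("sp_", sp, "_p", k)
        out[[cn]] <- as.integer(out$species == sp & out$stratum == k)
        terms <- c(terms, cn)
      }
    }
  }
  attr(out, "species_terms") <- terms
  attr(out, "z_params") <- attr(rows, "z_params")
  out
}

#' Fit the time-dependent departure Cox model
#'
#' Cox proportional-hazards fit on `(start, stop]` daily intervals; with
#' `cluster_by_bird` the variance is the robust sandwich grouped by bird
#' (the point estimates are unchanged). Ties are handled with the Efron
#' approximation by default: daily intervals make same-night departures
#' common, and with heavy ties Breslow visibly attenuates coefficients
#' (Efron is also what the usual survival software defaults to).
#'
#' @param rows Counting-process rows.
#' @param formula Right-hand side only, e.g. `~ v_wind_z + total_cloud_z`.
#' @param cluster_by_bird Use robust per-bird clustered standard errors.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `departure_fit` wrapping the `coxph` fit.
#' @export
fit_departure_cox <- function(rows, formula, cluster_by_bird = TRUE,
                              ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(rows$event) < 1)
    abort("no events in the data.", class = "coastflight_fit_error")
  tt <- terms(formula)
  term_labels <- attr(tt, "term.labels")
  if (length(term_labels) == 0)
    abort("the departure model needs at least one covariate.",
          class = "coastflight_fit_error")
  const <- vapply(term_labels, function(v) {
    v %in% names(rows) && is.numeric(rows[[v]]) &&
      length(unique(rows[[v]])) < 2
  }, logical(1))
  if (any(const))
    abort(paste0("covariate(s) without contrast: ",
                 paste(term_labels[const], collapse = ", ")),
          class = "coastflight_fit_error")
  f <- as.formula(paste("survival::Surv(start, stop, event) ~",
                        paste(term_labels, collapse = " + "),
                        if (cluster_by_bird) "+ cluster(bird_id)" else ""))
  fit <- withCallingHandlers(
    survival::coxph(f, data = rows, ties = ties,
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("beta may be infinite|did not converge", conditionMessage(w)))
        abort(paste0("monotone likelihood / non-convergence: ",
                     conditionMessage(w)),
              class = "coastflight_fit_error")
      invokeRestart("muffleWarning")
    })
  if (any(is.na(coef(fit))))
    abort(paste0("inestimable coefficient(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "coastflight_fit_error")
  structure(
    list(coxph = fit, rows = rows, formula = formula,
         cluster_by_bird = cluster_by_bird,
         loglik = fit$loglik[2], aic = AIC(fit),
         n = fit$n, n_events = fit$nevent),
    class = "departure_fit")
}

#' @export
print.departure_fit <- function(x, ...) {
  cat("<departure_fit> ", x$n, " bird-day rows, ", x$n_events,
      " departures\n", sep = "")
  print(tidy(x), n = Inf)
  cat("loglik = ", format(x$loglik), ", AIC = ", format(x$aic), "\n",
      sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.departure_fit <- function(x, ...) {
  fit <- x$coxph
  beta <- coef(fit)
  se <- sqrt(diag(fit$naive.var %||% fit$var))
  rse <- sqrt(diag(fit$var))
  z <- beta / rse
  tibble(term = names(beta), estimate = unname(beta),
         exp_estimate = exp(unname(beta)), std_error = unname(se),
         robust_se = unname(rse), statistic = unname(z),
         p_value = unname(2 * pnorm(-abs(z))))
}

#' @exportS3Method generics::glance
glance.departure_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, loglik = x$loglik, aic = x$aic,
         r_squared_nagelkerke = .cox_nagelkerke(x))
}

# Nagelkerke-type R^2 for the Cox fit (per-subject n, as survival's royston
# convention uses events; here the classic Cox-Snell/Nagelkerke on n rows)
.cox_nagelkerke <- function(x) {
  l0 <- x$coxph$loglik[1]; l1 <- x$coxph$loglik[2]
  n <- x$n
  cs <- 1 - exp(2 * (l0 - l1) / n)
  cs / (1 - exp(2 * l0 / n))
}

#' Test the proportional-hazards assumption
#'
#' Scaled Schoenfeld residuals against a transform of event time (identity
#' by default), with the usual per-term score test and global test; also
#' reports the plain correlation between the scaled residuals and the
#' transformed event times.
#'
#' @param fit A [fit_departure_cox()] fit.
#' @param transform `"identity"`, `"km"`, `"rank"` or `"log"`.
#' @return Tibble with `term`, `correlation`, `chisq`, `df`, `p_value`
#'   (last row is the GLOBAL test, with `NA` correlation).
#' @export
test_ph <- function(fit, transform = "identity") {
  stopifnot(inherits(fit, "departure_fit"))
  if (fit$n_events < 2)
    abort("need at least 2 events to test proportional hazards.",
          class = "coastflight_fit_error")
  zph <- survival::cox.zph(fit$coxph, transform = transform,
                           global = TRUE)
  tab <- zph$table
  sch <- zph$y                       # scaled Schoenfeld residuals
  tt <- zph$x                        # transformed event times
  cors <- vapply(colnames(sch), function(cn) {
    if (sd(sch[, cn]) == 0) NA_real_ else cor(tt, sch[, cn])
  }, numeric(1))
  tibble(term = rownames(tab),
         correlation = c(cors[rownames(tab)[-nrow(tab)]], NA_real_),
         chisq = tab[, "chisq"], df = tab[, "df"],
         p_value = tab[, "p"])
}

#' All-subsets AIC model selection for the departure model
#'
#' Enumerates every subset of `candidate_terms` (always on the identical
#' rows), fits each Cox model, and returns the fit with the lowest AIC
#' together with the full ranking. Ties are broken towards fewer terms,
#' then lexicographically on the formula. Subsets with no terms are skipped
#' (a Cox model has no intercept-only form); non-converging candidates are
#' skipped with a message.
#'
#' @param rows Counting-process rows.
#' @param candidate_terms Character vector of candidate covariate names.
#' @param always_terms Terms forced into every candidate model (e.g. the
#'   species-by-period columns).
#' @param cluster_by_bird Passed to [fit_departure_cox()].
#' @return List with `best` (a `departure_fit`) and `ranking` (tibble of
#'   `formula`, `n_terms`, `aic`, `delta_aic`).
#' @export
select_by_aic <- function(rows, candidate_terms, always_terms = character(),
                          cluster_by_bird = TRUE) {
  if (length(candidate_terms) == 0 && length(always_terms) == 0)
    abort("no candidate terms.", class = "coastflight_config_error")
  fitter <- function(terms_k) {
    fit_departure_cox(rows,
                      as.formula(paste("~", paste(terms_k, collapse = " + "))),
                      cluster_by_bird = cluster_by_bird)
  }
  .aic_subset_search(candidate_terms, always_terms, fitter,
                     allow_empty = length(always_terms) > 0)
}

# shared all-subsets machinery (used by departure and routing selection)
.aic_subset_search <- function(candidate_terms, always_terms, fitter,
                               allow_empty) {
  k <- length(candidate_terms)
  if (k > 14)
    abort("more than 14 candidate terms: all-subsets enumeration refused.",
          class = "coastflight_config_error")
  subsets <- purrr::map(0:k, ~ if (.x == 0) list(character(0))
                        else purrr::array_tree(combn(candidate_terms, .x), 2)) |>
    purrr::flatten()
  results <- purrr::map(subsets, function(s) {
    terms_k <- c(always_terms, s)
    if (length(terms_k) == 0 && !allow_empty) return(NULL)
    fit <- tryCatch(fitter(terms_k), error = function(e) {
      message("skipping non-converging candidate {",
              paste(terms_k, collapse = " + "), "}: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(fit)) return(NULL)
    tibble(formula = paste(sort(s), collapse = " + "),
           n_terms = length(s), aic = fit$aic, fit = list(fit))
  })
  ranking <- dplyr::bind_rows(results)
  if (nrow(ranking) == 0)
    abort("no candidate model converged.", class = "coastflight_fit_error")
  ranking <- ranking |>
    arrange(.data$aic, .data$n_terms, .data$formula) |>
    mutate(delta_aic = .data$aic - min(.data$aic)) |>
    distinct(.data$formula, .keep_all = TRUE)
  best <- ranking$fit[[1]]
  list(best = best,
       ranking = ranking |> select("formula", "n_terms", "aic", "delta_aic"))
}

#' Predicted flight probability along a covariate grid
#'
#' Flight probability is `1 - S(t)` from the Breslow baseline, evaluated at
#' the end of the stopover window (`t = max(stop)` by default) with the
#' focal covariate set to each grid value and every other model covariate at
#' its sample mean.
#'
#' @param fit A [fit_departure_cox()] fit.
#' @param focal_term Name of the focal covariate.
#' @param grid Numeric grid of focal covariate values (default: 25 points
#'   over the observed range). Values beyond 4 sd of the training data
#'   trigger a warning.
#' @param at_time Stopover day at which to evaluate `1 - S(t)`.
#' @return Tibble with the grid value and `p_flight`.
#' @export
predict_flight_probability <- function(fit, focal_term, grid = NULL,
                                       at_time = NULL) {
  stopifnot(inherits(fit, "departure_fit"))
  rows <- fit$rows
  model_terms <- attr(terms(fit$formula), "term.labels")
  if (!focal_term %in% model_terms)
    abort(paste0("`", focal_term, "` is not a term of the fitted model."),
          class = "coastflight_config_error")
  xf <- rows[[focal_term]]
  if (is.null(grid)) grid <- seq(min(xf), max(xf), length.out = 25)
  if (any(grid < mean(xf) - 4 * sd(xf) | grid > mean(xf) + 4 * sd(xf)))
    warn("grid extends beyond 4 sd of the training data.")
  if (is.null(at_time)) at_time <- max(rows$stop)
  newdata <- purrr::map(setNames(model_terms, model_terms), function(v) {
    if (is.numeric(rows[[v]])) rep(mean(rows[[v]]), length(grid))
    else rep(names(which.max(table(rows[[v]]))), length(grid))
  }) |> tibble::as_tibble()
  newdata[[focal_term]] <- grid
  sf <- survival::survfit(fit$coxph, newdata = newdata, se.fit = FALSE)
  surv <- summary(sf, times = at_time, extend = TRUE)$surv
  surv <- matrix(surv, ncol = length(grid))[1, ]
  out <- tibble(!!focal_term := grid, p_flight = 1 - surv)
  out
}

#' Flight-probability curve plot
#'
#' @param fit A `departure_fit`.
#' @param focal_term Focal covariate name.
#' @param ... Passed to [predict_flight_probability()].
#' @return A ggplot object.
#' @export
plot_flight_probability <- function(fit, focal_term, ...) {
  curve <- predict_flight_probability(fit, focal_term, ...)
  ggplot2::ggplot(curve,
                  ggplot2::aes(x = .data[[focal_term]],
                               y = .data$p_flight)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = focal_term, y = "P(flight)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Coefficient (forest) plot of a fitted departure model
#'
#' @param object A `departure_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.departure_fit <- function(object, ...) {
  td <- tidy(object) |>
    mutate(lo = .data$estimate - 1.96 * .data$robust_se,
           hi = .data$estimate + 1.96 * .data$robust_se)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo,
                                          xmax = .data$hi)) +
    ggplot2::labs(x = expression(beta~"(log hazard ratio)"), y = NULL) +
    ggplot2::theme_minimal()
}
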