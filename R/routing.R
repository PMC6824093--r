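#' Fit the offshore-vs-alongshore route model
#'
#' Binomial (logistic) GLM of route (1 = offshore) on the supplied terms,
#' fitted by IRLS. Complete separation is detected (diverging coefficients /
#' degenerate fitted probabilities) and raised as an error naming the
#' offending term rather than silently returning huge coefficients.
#'
#' @param rows Route-row tibble (one row per bird) with a `route01` column.
#' @param formula Right-hand side only, e.g. `~ u_wind_z +
#'   min_stopover_days_z`; `~ 1` fits the intercept-only model.
#' @return An object of class `route_fit` wrapping the `glm` fit.
#' @export
fit_route_glm <- function(rows, formula) {
  if (!"route01" %in% names(rows))
    abort("`rows` must contain a `route01` column (1 = offshore).",
          class = "coastflight_config_error")
  if (length(unique(rows$route01)) < 2)
    abort("both route classes must be present.",
          class = "coastflight_separation_error")
  f <- as.formula(paste("route01 ~",
                        paste(deparse(formula[[2]]), collapse = "")))
  fit <- suppressWarnings(glm(f, family = binomial(), data = rows,
                              control = list(maxit = 100)))
  beta <- coef(fit)
  big <- abs(beta) > 15 & names(beta) != "(Intercept)"
  probs <- fit$fitted.values
  degenerate <- all(probs < 1e-8 | probs > 1 - 1e-8)
  if (any(big, na.rm = TRUE) || (!fit$converged) || degenerate) {
    worst <- names(beta)[which.max(abs(beta) * (names(beta) != "(Intercept)"))]
    abort(paste0("complete or quasi-complete separation (term `", worst,
                 "` diverges)."),
          class = "coastflight_separation_error")
  }
  if (any(is.na(beta)))
    abort(paste0("inestimable coefficient(s): ",
                 paste(names(beta)[is.na(beta)], collapse = ", ")),
          class = "coastflight_fit_error")
  structure(list(glm = fit, rows = rows, formula = formula,
                 loglik = as.numeric(logLik(fit)), aic = AIC(fit),
                 n = nrow(rows), n_offshore = sum(rows$route01)),
            class = "route_fit")
}

#' @export
print.route_fit <- function(x, ...) {
  cat("<route_fit> ", x$n, " birds (", x$n_offshore, " offshore)\n",
      sep = "")
  print(tidy(x), n = Inf)
  cat("loglik = ", format(x$loglik), ", AIC = ", format(x$aic), "\n",
      sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.route_fit <- function(x, ...) {
  sm <- summary(x$glm)$coefficients
  tibble(term = rownames(sm), estimate = unname(sm[, "Estimate"]),
         std_error = unname(sm[, "Std. Error"]),
         statistic = unname(sm[, "z value"]),
         p_value = unname(sm[, "Pr(>|z|)"]))
}

#' @exportS3Method generics::glance
glance.route_fit <- function(x, ...) {
  null_fit <- fit_route_glm(x$rows, ~1)
  r2 <- nagelkerke_r2(x, null_fit)
  tibble(n = x$n, n_offshore = x$n_offshore, loglik = x$loglik,
         aic = x$aic, r2_cox_snell = r2$cox_snell,
         r2_nagelkerke = r2$nagelkerke)
}

#' All-subsets AIC selection for the route model
#'
#' Enumerates every subset of `candidate_terms` (2^k fits on identical
#' rows), returns the lowest-AIC fit and the ranking; the empty subset is
#' the intercept-only model. Ties break towards fewer terms, then
#' lexicographic formula; separating/non-converging candidates are skipped
#' with a message.
#'
#' @param rows Route-row tibble.
#' @param candidate_terms Character vector of candidate terms.
#' @return List with `best` (a `route_fit`) and `ranking`.
#' @export
all_subsets_aic <- function(rows, candidate_terms) {
  fitter <- function(terms_k) {
    rhs <- if (length(terms_k) == 0) "1" else paste(terms_k, collapse = " + ")
    fit_route_glm(rows, as.formula(paste("~", rhs)))
  }
  .aic_subset_search(candidate_terms, character(), fitter,
                     allow_empty = TRUE)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox–Snell `1 - exp((2/n) (l0 - l1))` rescaled by its maximum
#' `1 - exp((2/n) l0)` so a perfectly predictive model approaches 1.
#'
#' @param fit,null_fit `route_fit` objects on the same rows (`null_fit`
#'   intercept-only).
#' @return List with `nagelkerke` and `cox_snell`.
#' @export
nagelkerke_r2 <- function(fit, null_fit) {
  stopifnot(inherits(fit, "route_fit"), inherits(null_fit, "route_fit"))
  if (fit$n != null_fit$n)
    abort("fits must use the same rows.", class = "coastflight_config_error")
  l1 <- fit$loglik; l0 <- null_fit$loglik; n <- fit$n
  if (l1 < l0 - 1e-8)
    abort("alternative log-likelihood below the null: not nested MLEs.",
          class = "coastflight_fit_error")
  cs <- 1 - exp(2 * (l0 - l1) / n)
  list(nagelkerke = cs / (1 - exp(2 * l0 / n)), cox_snell = cs)
}

#' Coefficient plot of a fitted route model
#'
#' @param object A `route_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.route_fit <- function(object, ...) {
  td <- tidy(object) |>
    filter(.data$term != "(Intercept)") |>
    mutate(lo = .data$estimate - 1.96 * .data$std_error,
           hi = .data$estimate + 1.96 * .data$std_error)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo,
                                          xmax = .data$hi)) +
    ggplot2::labs(x = "log odds (offshore)", y = NULL) +
    ggplot2::theme_minimal()
}
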