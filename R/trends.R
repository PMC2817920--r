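# Trendline families for descriptor-score relations, and the rank-paired
# log-log correlation against activity data.
#
# Families mirror spreadsheet trendlines: exponential (y = a*e^(b*x)) and
# power (y = a*x^b) fits are ordinary least squares on log-transformed data,
# with R^2 reported on the transformed scale, which is how such trendline
# coefficients are conventionally produced.

ASF_FIT_FAMILIES <- c("linear", "quadratic", "exponential", "power",
                      "logarithmic")

#' Fit a trendline family
#'
#' Least-squares fit of one of five two- or three-parameter families:
#'
#' * `linear`: `y = a*x + b`, coefficients `(a, b)`
#' * `quadratic`: `y = a*x^2 + b*x + c`, coefficients `(a, b, c)`
#' * `logarithmic`: `y = a*ln(x) + b`, coefficients `(a, b)`, requires x > 0
#' * `exponential`: `y = a*e^(b*x)`, coefficients `(a, b)`, requires y > 0;
#'   fitted by linear regression of `ln(y)` on `x`
#' * `power`: `y = a*x^b`, coefficients `(a, b)`, requires x, y > 0;
#'   fitted by linear regression of `ln(y)` on `ln(x)`
#'
#' For the log-transformed families the reported R^2 refers to the
#' transformed (fitted) scale. A constant response yields slope 0 and
#' R^2 = 0 by convention.
#'
#' @param x,y Equal-length numeric vectors.
#' @param family One of `"linear"`, `"quadratic"`, `"exponential"`,
#'   `"power"`, `"logarithmic"`.
#' @return An object of class `asf_fit`: a list with elements `family`,
#'   `coefficients` (named, highest-order term first), `r_squared`, `n`.
#'   Supports [tidy()], [glance()], `predict()`, `print()` and [autoplot()].
#' @export
#' @examples
#' x <- 1:10
#' fit_relation(x, 2 * x^2 - x + 3, "quadratic")
fit_relation <- function(x, y, family = ASF_FIT_FAMILIES) {
  family <- rlang::arg_match(family, ASF_FIT_FAMILIES)
  if (length(x) != length(y)) {
    abort_asf("x and y must have the same length.", "asfscreen_fit_error")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  arity <- if (family == "quadratic") 3L else 2L
  if (length(x) < arity) {
    abort_asf(paste0("Need at least ", arity, " finite points for a ",
                     family, " fit; got ", length(x), "."),
              "asfscreen_fit_error")
  }
  if (family %in% c("power", "logarithmic") && any(x <= 0)) {
    abort_asf(paste0(family, " fits require x > 0."), "asfscreen_fit_error")
  }
  if (family %in% c("power", "exponential") && any(y <= 0)) {
    abort_asf(paste0(family, " fits require y > 0 (fit via log-transform)."),
              "asfscreen_fit_error")
  }
  xt <- switch(family, power = log(x), logarithmic = log(x), x)
  yt <- switch(family, power = log(y), exponential = log(y), y)
  if (isTRUE(all.equal(stats::var(xt), 0)) || stats::var(xt) == 0) {
    abort_asf("x has zero variance; the fit is degenerate.",
              "asfscreen_fit_error")
  }

  model <- if (family == "quadratic") {
    stats::lm(yt ~ xt + I(xt^2))
  } else {
    stats::lm(yt ~ xt)
  }
  b <- stats::coef(model)
  coefficients <- switch(
    family,
    linear = c(a = unname(b["xt"]), b = unname(b["(Intercept)"])),
    logarithmic = c(a = unname(b["xt"]), b = unname(b["(Intercept)"])),
    quadratic = c(a = unname(b["I(xt^2)"]), b = unname(b["xt"]),
                  c = unname(b["(Intercept)"])),
    exponential = c(a = exp(unname(b["(Intercept)"])), b = unname(b["xt"])),
    power = c(a = exp(unname(b["(Intercept)"])), b = unname(b["xt"]))
  )

  ss_res <- sum(stats::residuals(model)^2)
  ss_tot <- sum((yt - mean(yt))^2)
  r_squared <- if (ss_tot == 0) {
    0  # constant response: no variance to explain
  } else if (ss_res < .Machine$double.eps^0.5 * ss_tot) {
    1  # residuals vanish up to rounding
  } else {
    max(0, min(1, 1 - ss_res / ss_tot))
  }

  structure(
    list(family = family, coefficients = coefficients,
         r_squared = r_squared, n = length(x), data = tibble(x = x, y = y)),
    class = "asf_fit"
  )
}

#' Evaluate a fitted trendline
#'
#' @param object An `asf_fit`.
#' @param newdata Numeric vector of x values (default: the fitted x).
#' @param ... Unused.
#' @return Predicted y on the original (untransformed) scale.
#' @export
predict.asf_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata
  cf <- object$coefficients
  switch(object$family,
         linear = cf[["a"]] * x + cf[["b"]],
         quadratic = cf[["a"]] * x^2 + cf[["b"]] * x + cf[["c"]],
         logarithmic = cf[["a"]] * log(x) + cf[["b"]],
         exponential = cf[["a"]] * exp(cf[["b"]] * x),
         power = cf[["a"]] * x^cf[["b"]])
}

#' @export
print.asf_fit <- function(x, ...) {
  eq <- switch(x$family,
               linear = "y = a*x + b",
               quadratic = "y = a*x^2 + b*x + c",
               logarithmic = "y = a*ln(x) + b",
               exponential = "y = a*e^(b*x)",
               power = "y = a*x^b")
  cat("<asf_fit> ", x$family, " trendline: ", eq, "\n", sep = "")
  print(signif(x$coefficients, 6))
  cat("R^2 = ", format(x$r_squared, digits = 4), " on n = ", x$n,
      " points\n", sep = "")
  invisible(x)
}

#' Tidy a fitted trendline
#'
#' @param x An `asf_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.asf_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' One-row summary of a fitted trendline
#'
#' @param x An `asf_fit`.
#' @param ... Unused.
#' @return A tibble with columns `family`, `r_squared`, `n`.
#' @export
glance.asf_fit <- function(x, ...) {
  tibble(family = x$family, r_squared = x$r_squared, n = x$n)
}

#' Rank-paired log-log correlation of ASF against activity
#'
#' Implements the sorted-correlation procedure used to compare computed
#' scores with cell-line growth inhibition: both data sets are log10
#' transformed, each is sorted highest to lowest *independently*, the two
#' sorted series are truncated to the shorter length and paired by rank,
#' and a quadratic trendline is fitted through the pairs.
#'
#' Note that pairing independently sorted lists destroys sample identity:
#' the resulting R^2 measures agreement of the two marginal distributions'
#' shapes, not a per-sample association. The returned object carries this
#' caveat in its `warnings` field. Non-positive values (e.g. negative ASF
#' scores) have no logarithm and are excluded; the exclusion counts are
#' reported.
#'
#' @param asf_values Numeric vector of ASF scores.
#' @param activity_values Numeric vector of positive activity values
#'   (e.g. GI50 concentrations).
#' @return An object of class `asf_sorted_correlation`: a list with `pairs`
#'   (tibble: `rank`, `log_asf`, `log_activity`), `fit` (quadratic
#'   [fit_relation()] of `log_activity` on `log_asf`), `n_pairs`,
#'   `n_excluded_asf`, `n_excluded_activity`, `warnings`.
#' @export
#' @examples
#' sorted_log_correlation(c(1e-5, 2e-5, 4e-5), c(1e-8, 1e-7, 1e-6))
sorted_log_correlation <- function(asf_values, activity_values) {
  if (length(asf_values) == 0 || length(activity_values) == 0) {
    abort_asf("Both input lists must be non-empty.", "asfscreen_domain_error")
  }
  pos_asf <- asf_values[is.finite(asf_values) & asf_values > 0]
  pos_act <- activity_values[is.finite(activity_values) & activity_values > 0]
  n_excl_asf <- length(asf_values) - length(pos_asf)
  n_excl_act <- length(activity_values) - length(pos_act)
  if (length(pos_asf) == 0 || length(pos_act) == 0) {
    abort_asf("No positive values left to log-transform.",
              "asfscreen_domain_error")
  }
  la <- sort(log10(pos_asf), decreasing = TRUE)
  lg <- sort(log10(pos_act), decreasing = TRUE)
  n <- min(length(la), length(lg))
  pairs <- tibble(rank = seq_len(n), log_asf = la[seq_len(n)],
                  log_activity = lg[seq_len(n)])
  fit <- fit_relation(pairs$log_asf, pairs$log_activity, "quadratic")
  warnings <- c(
    "rank-paired: series were sorted independently, so pairs do not preserve sample identity",
    if (n_excl_asf > 0)
      paste0(n_excl_asf, " non-positive ASF value(s) excluded before log10"),
    if (n_excl_act > 0)
      paste0(n_excl_act, " non-positive activity value(s) excluded before log10"),
    if (length(la) != length(lg))
      paste0("series truncated to the shorter length (", n, ")")
  )
  structure(
    list(pairs = pairs, fit = fit, n_pairs = n,
         n_excluded_asf = n_excl_asf, n_excluded_activity = n_excl_act,
         warnings = warnings),
    class = "asf_sorted_correlation"
  )
}

#' @export
print.asf_sorted_correlation <- function(x, ...) {
  cat("<asf_sorted_correlation> ", x$n_pairs, " rank-paired points\n",
      sep = "")
  cat("quadratic fit R^2 = ", format(x$fit$r_squared, digits = 4), "\n",
      sep = "")
  for (w in x$warnings) cat(" note: ", w, "\n", sep = "")
  invisible(x)
}
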