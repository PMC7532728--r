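#' Negative-binomial regression with log link
#'
#' Fits a count response to predictors by NB maximum likelihood
#' (dispersion estimated jointly), optionally absorbing spatial grouping
#' structure (site, transect) as categorical fixed adjustments — a
#' deliberately light-weight stand-in for random intercepts whose
#' inferential target here is only the sign and scale of the fixed
#' effects.
#'
#' @param table Data.frame.
#' @param response Name of a non-negative integer count column.
#' @param predictors Character vector of predictor column names (may be
#'   empty for an intercept-only model).
#' @param grouping Optional character vector of columns to absorb as
#'   factors.
#' @return Object of class `"nb_fit"` wrapping the underlying
#'   `MASS::glm.nb` fit, with `response`, `predictors`, `grouping`,
#'   `coefficients` table, `logLik`, `df` (including the dispersion) and
#'   `aic` (`2k - 2 logLik` with the dispersion counted in `k`), plus a
#'   `converged` flag.
#' @examples
#' d <- data.frame(y = rpois(50, 5))
#' fit_nb_regression(d, "y", character(0))
#' @export
fit_nb_regression <- function(table, response, predictors = character(0),
                              grouping = NULL) {
  cols <- c(response, predictors, grouping)
  miss <- setdiff(cols, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  y <- table[[response]]
  if (any(y < 0) || any(y != round(y)))
    stop("response must be non-negative integer counts")
  dat <- table[, cols, drop = FALSE]
  for (g in grouping) dat[[g]] <- factor(dat[[g]])
  rhs <- c(predictors, grouping)
  fml <- stats::reformulate(if (length(rhs)) rhs else "1",
                            response = response)
  fit <- suppressWarnings(MASS::glm.nb(fml, data = dat))
  ll <- as.numeric(stats::logLik(fit))
  k <- length(stats::coef(fit)) + 1L  # + dispersion
  ct <- summary(fit)$coefficients
  structure(list(fit = fit, response = response, predictors = predictors,
                 grouping = grouping %||% character(0),
                 coefficients = ct, theta = fit$theta,
                 logLik = ll, df = k, aic = 2 * k - 2 * ll,
                 converged = isTRUE(fit$converged)),
            class = "nb_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nb_fit <- function(x, ...) {
  cat("NB regression:", deparse_model(x), "\n")
  stats::printCoefmat(x$coefficients, signif.stars = FALSE)
  cat(sprintf("theta = %.3f   logLik = %.2f   AIC = %.2f%s\n",
              x$theta, x$logLik, x$aic,
              if (x$converged) "" else "   [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.nb_fit <- function(object, ...) stats::coef(object$fit)

#' @export
logLik.nb_fit <- function(object, ...)
  structure(object$logLik, df = object$df, class = "logLik")

#' Likelihood-ratio test of nested NB regressions
#'
#' `chi^2 = 2 (logLik_full - logLik_reduced)` with degrees of freedom
#' equal to the difference in parameter counts; p-value from the upper
#' chi-squared tail.
#'
#' @param full,reduced [fit_nb_regression()] objects; `reduced` must be
#'   nested in `full` (same response, predictor subset).
#' @return Object of class `"model_comparison"` with `statistic`, `df`,
#'   `p_value` and the rule applied.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "nb_fit"), inherits(reduced, "nb_fit"))
  if (!identical(full$response, reduced$response))
    stop("models have different responses")
  if (!all(reduced$predictors %in% full$predictors) ||
      full$df < reduced$df)
    stop("'reduced' is not nested in 'full'")
  chisq <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- full$df - reduced$df
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  structure(list(rule = "LRT", statistic = chisq, df = df, p_value = p,
                 full = deparse_model(full), reduced = deparse_model(reduced)),
            class = "model_comparison")
}

deparse_model <- function(x)
  paste(x$response, "~",
        paste(c(x$predictors, x$grouping, if (!length(c(x$predictors, x$grouping))) "1"),
              collapse = " + "))

#' AIC-based selection over nested candidate models
#'
#' Walks candidates from simplest to most complex and adopts a more
#' complex model only when it improves on the AIC of the best simpler
#' model by more than `threshold` (default 2) — a parsimony-first rule.
#'
#' @param candidates List of [fit_nb_regression()] objects ordered from
#'   simple to complex.
#' @param threshold Required AIC reduction (> 0).
#' @return A `"model_comparison"` object with the `selected` index and
#'   model, and the AIC table.
#' @export
aic_select <- function(candidates, threshold = 2) {
  if (!length(candidates)) stop("empty candidate list")
  if (threshold <= 0) stop("threshold must be positive")
  stopifnot(all(vapply(candidates, inherits, logical(1), "nb_fit")))
  aics <- vapply(candidates, `[[`, numeric(1), "aic")
  best <- 1L
  for (k in seq_along(candidates)[-1]) {
    if (aics[best] - aics[k] > threshold) best <- k
  }
  structure(list(rule = sprintf("AIC reduction > %g", threshold),
                 aic = aics, selected = best,
                 model = candidates[[best]],
                 labels = vapply(candidates, deparse_model, character(1))),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  if (x$rule == "LRT") {
    cat(sprintf("LRT: %s  vs  %s\n", x$full, x$reduced))
    cat(sprintf("chi-squared = %.3f, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  } else {
    cat("Model selection,", x$rule, "\n")
    print(data.frame(model = x$labels, AIC = round(x$aic, 2),
                     selected = seq_along(x$aic) == x$selected))
  }
  invisible(x)
}

#' Predict per-individual fecundity from proxy measurements
#'
#' Applies a fitted proxy model (e.g. seeds ~ height) to new individuals
#' via the log link, giving positive expected seed counts that can be
#' attached back to plots for density-dependence regressions.
#'
#' @param fit An [fit_nb_regression()] object.
#' @param table Data.frame containing all the fit's predictors; may be
#'   empty.
#' @return Numeric vector of predicted mean seed counts (length
#'   `nrow(table)`).
#' @export
predict_fecundity <- function(fit, table) {
  stopifnot(inherits(fit, "nb_fit"))
  if (nrow(table) == 0L) return(numeric(0))
  miss <- setdiff(c(fit$predictors, fit$grouping), names(table))
  if (length(miss)) stop("missing predictor columns: ",
                         paste(miss, collapse = ", "))
  dat <- table
  for (g in fit$grouping) dat[[g]] <- factor(dat[[g]])
  as.numeric(stats::predict(fit$fit, newdata = dat, type = "response"))
}
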