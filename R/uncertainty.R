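#' Taylor-expansion error propagation
#'
#' Propagates parameter uncertainty through a scalar metric by first- or
#' second-order Taylor expansion around the point estimates, using
#' numerical central-difference derivatives. Order 1 gives the classic
#' delta-method SD `sqrt(g' Sigma g)`; order 2 adds the standard
#' second-order corrections (mean shift `tr(H Sigma)/2`, extra variance
#' `tr((H Sigma)^2)/2`, exact under multivariate normality of the inputs).
#'
#' @param f Metric: a function of a named numeric vector.
#' @param estimates Named numeric vector of point estimates.
#' @param cov Covariance matrix of the estimates (symmetric PSD, ordered
#'   like `estimates`; a named matrix is permuted to match).
#' @param order 1 or 2.
#' @param step Relative step for numerical derivatives (absolute for
#'   parameters equal to zero).
#' @return Object of class `"propagation"`: `value` (order-2 includes the
#'   mean correction), `sd`, `method`, `point` (the uncorrected f at the
#'   estimates).
#' @examples
#' taylor_propagate(function(p) p[["x"]]^2, c(x = 2),
#'                  matrix(0.01, 1, 1), order = 1)  # sd 0.4
#' @export
taylor_propagate <- function(f, estimates, cov, order = 1, step = 1e-6) {
  cov <- as.matrix(cov)
  k <- length(estimates)
  if (!all(dim(cov) == k)) stop("covariance dimension mismatch")
  if (!is.null(rownames(cov)) && !is.null(names(estimates)) &&
      all(names(estimates) %in% rownames(cov)))
    cov <- cov[names(estimates), names(estimates), drop = FALSE]
  if (max(abs(cov - t(cov))) > 1e-8 * (1 + max(abs(cov))))
    stop("covariance must be symmetric")
  if (!order %in% c(1, 2)) stop("order must be 1 or 2")

  h <- ifelse(estimates == 0, step, abs(estimates) * step)
  f0 <- f(estimates)
  if (!is.finite(f0)) stop("metric not finite at the estimates")
  perturb <- function(i, d) { p <- estimates; p[i] <- p[i] + d; f(p) }
  grad <- vapply(seq_len(k), function(i)
    (perturb(i, h[i]) - perturb(i, -h[i])) / (2 * h[i]), numeric(1))

  v <- drop(t(grad) %*% cov %*% grad)
  val <- f0
  if (order == 2) {
    hs <- ifelse(estimates == 0, sqrt(step), abs(estimates) * 1e-4)
    H <- matrix(0, k, k)
    for (i in seq_len(k)) {
      H[i, i] <- (perturb(i, hs[i]) - 2 * f0 + perturb(i, -hs[i])) / hs[i]^2
      for (j in seq_len(k)) if (j > i) {
        pp <- function(di, dj) {
          p <- estimates; p[i] <- p[i] + di; p[j] <- p[j] + dj; f(p)
        }
        H[i, j] <- H[j, i] <-
          (pp(hs[i], hs[j]) - pp(hs[i], -hs[j]) -
             pp(-hs[i], hs[j]) + pp(-hs[i], -hs[j])) / (4 * hs[i] * hs[j])
      }
    }
    HS <- H %*% cov
    val <- f0 + 0.5 * sum(diag(HS))
    v <- v + 0.5 * sum(HS * t(HS))
  }
  if (!is.finite(v) || v < 0) stop("propagated variance not finite/non-negative")
  structure(list(value = val, sd = sqrt(v),
                 method = paste0("taylor", order), point = f0),
            class = "propagation")
}

#' Monte-Carlo error propagation
#'
#' Oracle companion to [taylor_propagate()]: draws parameter vectors from
#' a multivariate normal at the estimates/covariance, evaluates the metric
#' on each admissible draw (draws where the metric errors or is
#' non-finite, e.g. a negative alpha, are rejected and counted) and
#' reports the empirical mean and SD. Errors out if more than half the
#' draws are inadmissible — the propagation regime is then invalid.
#'
#' @inheritParams taylor_propagate
#' @param n_draws Number of draws (>= 1000; default 1e5).
#' @param seed Integer seed.
#' @return A `"propagation"` object with `value` (mean over accepted
#'   draws), `sd`, `n` (accepted draws) and `rejected` (fraction).
#' @export
mc_propagate <- function(f, estimates, cov, n_draws = 1e5, seed = 1) {
  if (n_draws < 1000) stop("n_draws must be >= 1000")
  cov <- as.matrix(cov)
  if (!is.null(rownames(cov)) && !is.null(names(estimates)) &&
      all(names(estimates) %in% rownames(cov)))
    cov <- cov[names(estimates), names(estimates), drop = FALSE]
  draws <- with_seed(seed,
    MASS::mvrnorm(n_draws, mu = estimates, Sigma = cov))
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = length(estimates))
  colnames(draws) <- names(estimates)
  vals <- apply(draws, 1, function(p)
    tryCatch(f(p), error = function(e) NA_real_))
  ok <- is.finite(vals)
  rej <- mean(!ok)
  if (rej > 0.5)
    stop(sprintf("%.0f%% of draws inadmissible: propagation regime invalid",
                 100 * rej))
  structure(list(value = mean(vals[ok]), sd = stats::sd(vals[ok]),
                 method = "monte_carlo", n = sum(ok), rejected = rej),
            class = "propagation")
}

#' Bootstrap standard error of a pairwise metric
#'
#' Evaluates a metric of the shared 6-parameter vector on each pair of
#' bootstrap replicates (the two species' replicate sets paired by index)
#' and reports the mean and SD over admissible replicates. This is the
#' default provenance of the reported SEs: it propagates uncertainty from
#' the resampled data itself rather than from a curvature approximation.
#'
#' @param boots_i,boots_j [bootstrap_fit()] objects with equally many
#'   replicates.
#' @param f Metric of a named vector with elements `lambda_i`, `lambda_j`,
#'   `alpha_ii`, `alpha_ij`, `alpha_jj`, `alpha_ji`.
#' @return A `"propagation"` object (`method = "bootstrap"`, `n` =
#'   admissible replicate pairs, `dropped` = count excluded).
#' @export
bootstrap_metric_se <- function(boots_i, boots_j, f) {
  stopifnot(inherits(boots_i, "bh_boot"), inherits(boots_j, "bh_boot"))
  n <- min(nrow(boots_i$replicates), nrow(boots_j$replicates))
  if (nrow(boots_i$replicates) != nrow(boots_j$replicates))
    message("replicate sets unequal; pairing the first ", n)
  vals <- vapply(seq_len(n), function(b) {
    p <- pair_vector(boots_i$replicates[b, ], boots_j$replicates[b, ])
    tryCatch(f(p), error = function(e) NA_real_)
  }, numeric(1))
  ok <- is.finite(vals)
  if (sum(ok) < 2) stop("fewer than 2 admissible replicate pairs")
  if (any(!ok)) message(sum(!ok), " inadmissible replicate pair(s) dropped")
  structure(list(value = mean(vals[ok]), sd = stats::sd(vals[ok]),
                 method = "bootstrap", n = sum(ok), dropped = sum(!ok)),
            class = "propagation")
}

#' @export
print.propagation <- function(x, ...) {
  cat(sprintf("%s propagation: value %.6g, sd %.6g", x$method, x$value, x$sd))
  if (!is.null(x$n)) cat(sprintf(" (n = %d)", x$n))
  if (!is.null(x$rejected) && x$rejected > 0)
    cat(sprintf(", %.1f%% rejected", 100 * x$rejected))
  cat("\n")
  invisible(x)
}
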