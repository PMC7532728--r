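#' Niche overlap of two competitors
#'
#' `rho = sqrt((alpha_ij * alpha_ji) / (alpha_ii * alpha_jj))`: the
#' geometric mean of the inter/intra interaction ratios. `rho = 1`
#' (niche difference `1 - rho = 0`) when each species limits its
#' competitor exactly as strongly as it limits itself (`alpha_ii =
#' alpha_ij` and `alpha_jj = alpha_ji`); `rho` near 0 means strong
#' stabilization.
#'
#' @param alpha_ii,alpha_ij,alpha_jj,alpha_ji Interaction coefficients
#'   (all > 0; `alpha_xy` = effect on x of one y neighbour).
#' @return Niche overlap (positive scalar).
#' @examples
#' niche_overlap(0.25, 0.29, 0.73, 0.45)  # 0.85 at 2 dp
#' @export
niche_overlap <- function(alpha_ii, alpha_ij, alpha_jj, alpha_ji) {
  check_pos(c(alpha_ii = alpha_ii, alpha_ij = alpha_ij,
              alpha_jj = alpha_jj, alpha_ji = alpha_ji))
  sqrt((alpha_ij * alpha_ji) / (alpha_ii * alpha_jj))
}

#' Demographic (potential) ratio of species j relative to species i
#'
#' `(lambda_j - 1) / (lambda_i - 1)`: the ratio of net per-capita seed
#' surpluses of annual plants. Values > 1 mean species j has the higher
#' demographic potential. Requires both populations to be self-replacing
#' (`lambda > 1`), otherwise the surplus is non-positive and the ratio is
#' undefined here.
#'
#' Optionally, germination fractions weight the fecundities
#' (`eta = lambda * g`), giving `(eta_j - 1) / (eta_i - 1)` — a
#' sensitivity variant for when germination is substantially below 1 and
#' should discount the seed surplus. The unweighted form is the default
#' and is the form the published summary-table ratios correspond to.
#'
#' @param lambda_j,lambda_i Intrinsic fecundities (> 1).
#' @param g_j,g_i Optional germination fractions in `(0, 1]` for the
#'   g-weighted variant; both or neither must be supplied.
#' @return Positive scalar.
#' @examples
#' demographic_ratio(650.0, 365.9)  # 1.78 at 2 dp
#' @export
demographic_ratio <- function(lambda_j, lambda_i, g_j = NULL, g_i = NULL) {
  if (is.null(g_j) != is.null(g_i))
    stop("supply both germination fractions or neither")
  if (!is.null(g_j)) {
    lambda_j <- lambda_j * g_j
    lambda_i <- lambda_i * g_i
  }
  if (!is.finite(lambda_i) || !is.finite(lambda_j) ||
      lambda_i <= 1 || lambda_j <= 1)
    stop("demographic ratio requires (g-weighted) lambda > 1 for both species")
  (lambda_j - 1) / (lambda_i - 1)
}

#' Competitive response ratio of species i relative to species j
#'
#' `sqrt((alpha_ii * alpha_ij) / (alpha_jj * alpha_ji))`: how strongly
#' species i responds to competition (from either neighbour type) relative
#' to species j. A value < 1 means species i is the less sensitive
#' competitor.
#'
#' @inheritParams niche_overlap
#' @return Positive scalar.
#' @examples
#' competitive_response_ratio(0.25, 0.29, 0.73, 0.45)  # 0.47 at 2 dp
#' @export
competitive_response_ratio <- function(alpha_ii, alpha_ij, alpha_jj, alpha_ji) {
  check_pos(c(alpha_ii = alpha_ii, alpha_ij = alpha_ij,
              alpha_jj = alpha_jj, alpha_ji = alpha_ji))
  sqrt((alpha_ii * alpha_ij) / (alpha_jj * alpha_ji))
}

#' Average fitness ratio kappa_j / kappa_i
#'
#' The competitive-ability asymmetry that decides the winner in the
#' absence of niche differences: the product of the demographic ratio
#' (j relative to i) and the competitive response ratio (i relative to j).
#' A value > 1 favours species j.
#'
#' @param lambda_i,lambda_j Intrinsic fecundities (> 1).
#' @inheritParams niche_overlap
#' @return Positive scalar, exactly
#'   `demographic_ratio(lambda_j, lambda_i) *
#'    competitive_response_ratio(alpha_ii, alpha_ij, alpha_jj, alpha_ji)`.
#' @export
fitness_ratio <- function(lambda_i, lambda_j,
                          alpha_ii, alpha_ij, alpha_jj, alpha_ji) {
  demographic_ratio(lambda_j, lambda_i) *
    competitive_response_ratio(alpha_ii, alpha_ij, alpha_jj, alpha_ji)
}

#' Low-density invasion growth rate
#'
#' Per-capita growth of an invader (species j) at vanishing density
#' against a resident (species i) sitting at its single-species
#' Beverton-Holt equilibrium `N* = (lambda_i - 1) / alpha_ii`:
#' `lambda_j / (1 + alpha_ji * (lambda_i - 1) / alpha_ii)`. A value > 1
#' means the invader can increase when rare; mutual rates > 1 imply
#' coexistence.
#'
#' @param lambda_j Invader intrinsic fecundity (> 0).
#' @param lambda_i Resident intrinsic fecundity (> 1, so an equilibrium
#'   exists).
#' @param alpha_ji Effect on the invader of one resident plant (>= 0).
#' @param alpha_ii Resident self-limitation (> 0).
#' @return Positive scalar.
#' @examples
#' invasion_growth_rate(391.23, 327.4, 0.27, 0.47)  # 2.08 at 2 dp
#' @export
invasion_growth_rate <- function(lambda_j, lambda_i, alpha_ji, alpha_ii) {
  if (!is.finite(alpha_ii) || alpha_ii <= 0)
    stop("resident self-limitation alpha_ii must be > 0 for an equilibrium")
  if (!is.finite(lambda_i) || lambda_i <= 1)
    stop("resident lambda_i must exceed 1 for an equilibrium")
  if (!is.finite(alpha_ji) || alpha_ji < 0)
    stop("alpha_ji must be >= 0")
  lambda_j / (1 + alpha_ji * (lambda_i - 1) / alpha_ii)
}

#' Classify the long-term pairwise outcome
#'
#' Applies the stabilization condition `rho < kappa < 1/rho`: coexistence
#' when the fitness ratio sits inside the band the niche difference opens
#' up. With `kappa = kappa_j/kappa_i`, `kappa <= rho` means species i
#' excludes species j, `kappa >= 1/rho` means species j excludes species
#' i, and with destabilizing overlap (`rho > 1`) an intermediate fitness
#' ratio yields a priority effect (the first-arriving species wins).
#' Boundary cases within `tol` are flagged `"indeterminate"` rather than
#' assigned a side.
#'
#' @param rho Niche overlap (> 0).
#' @param kappa Average fitness ratio kappa_j/kappa_i (> 0).
#' @param tol Boundary tolerance.
#' @return One of `"coexistence"`, `"i excludes j"`, `"j excludes i"`,
#'   `"priority effect"`, `"indeterminate"`.
#' @examples
#' classify_outcome(0.85, 0.83)  # native i excludes invader j
#' @export
classify_outcome <- function(rho, kappa, tol = 1e-9) {
  if (!is.finite(rho) || !is.finite(kappa) || rho <= 0 || kappa <= 0)
    stop("rho and kappa must be positive finite")
  if (abs(kappa - rho) < tol || abs(kappa - 1 / rho) < tol)
    return("indeterminate")
  if (rho < 1) {
    if (kappa > rho && kappa < 1 / rho) return("coexistence")
    if (kappa < rho) return("i excludes j")
    return("j excludes i")
  }
  if (abs(rho - 1) < tol) return("indeterminate")
  # rho > 1: the band is inverted; intermediate kappa -> founder control
  if (kappa > 1 / rho && kappa < rho) return("priority effect")
  if (kappa <= 1 / rho) return("i excludes j")
  "j excludes i"
}

check_pos <- function(x) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad))
    stop("interaction coefficients must be positive and finite; offending: ",
         paste(names(x)[bad], collapse = ", "))
  invisible(x)
}

# Named 6-vector (lambda_i, lambda_j, alpha_ii, alpha_ij, alpha_jj,
# alpha_ji) -> each coexistence metric; shared by the propagation and
# bootstrap machinery.
metric_functions <- function() {
  list(
    niche_overlap = function(p)
      niche_overlap(p[["alpha_ii"]], p[["alpha_ij"]],
                    p[["alpha_jj"]], p[["alpha_ji"]]),
    niche_difference = function(p)
      1 - niche_overlap(p[["alpha_ii"]], p[["alpha_ij"]],
                        p[["alpha_jj"]], p[["alpha_ji"]]),
    demographic_ratio = function(p)
      demographic_ratio(p[["lambda_j"]], p[["lambda_i"]]),
    competitive_response_ratio = function(p)
      competitive_response_ratio(p[["alpha_ii"]], p[["alpha_ij"]],
                                 p[["alpha_jj"]], p[["alpha_ji"]]),
    fitness_ratio = function(p)
      fitness_ratio(p[["lambda_i"]], p[["lambda_j"]],
                    p[["alpha_ii"]], p[["alpha_ij"]],
                    p[["alpha_jj"]], p[["alpha_ji"]]),
    igr_i_into_j = function(p)
      invasion_growth_rate(p[["lambda_i"]], p[["lambda_j"]],
                           p[["alpha_ij"]], p[["alpha_jj"]]),
    igr_j_into_i = function(p)
      invasion_growth_rate(p[["lambda_j"]], p[["lambda_i"]],
                           p[["alpha_ji"]], p[["alpha_ii"]])
  )
}

# Assemble the shared 6-parameter vector from two single-species objects.
pair_vector <- function(est_i, est_j) {
  c(lambda_i = unname(est_i[["lambda"]]),
    lambda_j = unname(est_j[["lambda"]]),
    alpha_ii = unname(est_i[["alpha_intra"]]),
    alpha_ij = unname(est_i[["alpha_inter"]]),
    alpha_jj = unname(est_j[["alpha_intra"]]),
    alpha_ji = unname(est_j[["alpha_inter"]]))
}

#' Summarize the coexistence outcome for a fitted species pair
#'
#' Combines the two per-focal-species fits for one treatment into the full
#' set of coexistence quantities: niche overlap and difference, the
#' demographic and competitive response ratios, the average fitness ratio,
#' both low-density invasion growth rates, and the outcome classification.
#' Standard errors are attached per metric: `"bootstrap"` pairs the two
#' species' bootstrap replicate sets by index and takes the SD of the
#' metric over replicates (the default when replicate sets are supplied);
#' `"taylor1"`/`"taylor2"` propagate the fits' covariance matrices
#' (block-diagonal across species — the two fits are computed separately,
#' so cross-species covariance is taken as zero).
#'
#' @param fit_i,fit_j [fit_competition()] objects (or [bootstrap_fit()]
#'   objects, whose full-data fits and replicates are both used) for focal
#'   species i and j in the same treatment.
#' @param se_method `"bootstrap"`, `"taylor1"`, `"taylor2"` or `"none"`.
#' @param point `"bootstrap"` to report bootstrap-mean parameter values as
#'   the headline point estimates (conventional for this design),
#'   `"full_data"` for the plain ML estimates. Ignored without replicates.
#' @param digits Rounding used by the print method only; stored values are
#'   full precision.
#' @return Object of class `"coexistence_summary"`: a data.frame `metrics`
#'   (metric, value, se, se_method), the `outcome` label, the treatment
#'   and the parameter vector used.
#' @export
summarize_pair <- function(fit_i, fit_j,
                           se_method = c("bootstrap", "taylor1", "taylor2", "none"),
                           point = c("bootstrap", "full_data"), digits = 2) {
  se_method <- match.arg(se_method)
  point <- match.arg(point)
  boots_i <- if (inherits(fit_i, "bh_boot")) fit_i else NULL
  boots_j <- if (inherits(fit_j, "bh_boot")) fit_j else NULL
  if (inherits(fit_i, "bh_boot")) fit_i <- fit_i$fit
  if (inherits(fit_j, "bh_boot")) fit_j <- fit_j$fit
  stopifnot(inherits(fit_i, "bh_fit"), inherits(fit_j, "bh_fit"))
  if (!identical(fit_i$treatment, fit_j$treatment))
    stop("fits are from different treatments: ",
         fit_i$treatment, " vs ", fit_j$treatment)
  if (se_method == "bootstrap" && (is.null(boots_i) || is.null(boots_j)))
    stop("se_method = 'bootstrap' needs bh_boot objects for both species")

  est <- if (point == "bootstrap" && !is.null(boots_i) && !is.null(boots_j))
    pair_vector(colMeans(boots_i$replicates), colMeans(boots_j$replicates))
  else pair_vector(fit_i$estimates, fit_j$estimates)

  fns <- metric_functions()
  vals <- vapply(fns, function(f) f(est), numeric(1))

  ses <- rep(NA_real_, length(fns))
  if (se_method %in% c("taylor1", "taylor2")) {
    ord <- if (se_method == "taylor1") 1L else 2L
    Sigma <- pair_vcov(fit_i, fit_j)
    ses <- vapply(fns, function(f)
      taylor_propagate(f, est, Sigma, order = ord)$sd, numeric(1))
  } else if (se_method == "bootstrap") {
    ses <- vapply(fns, function(f)
      bootstrap_metric_se(boots_i, boots_j, f)$sd, numeric(1))
  }

  metrics <- data.frame(metric = names(fns), value = unname(vals),
                        se = unname(ses), se_method = se_method)
  outcome <- classify_outcome(vals[["niche_overlap"]], vals[["fitness_ratio"]])
  structure(list(metrics = metrics, outcome = outcome,
                 treatment = fit_i$treatment, estimates = est,
                 digits = digits),
            class = "coexistence_summary")
}

# Block-diagonal covariance of the shared 6-parameter vector from two
# independent single-species fits (theta rows dropped).
pair_vcov <- function(fit_i, fit_j) {
  keep <- c("lambda", "alpha_intra", "alpha_inter")
  vi <- fit_i$vcov[keep, keep]
  vj <- fit_j$vcov[keep, keep]
  nm <- c("lambda_i", "lambda_j", "alpha_ii", "alpha_ij",
          "alpha_jj", "alpha_ji")
  S <- matrix(0, 6, 6, dimnames = list(nm, nm))
  ix <- c("lambda_i", "alpha_ii", "alpha_ij")
  jx <- c("lambda_j", "alpha_jj", "alpha_ji")
  S[ix, ix] <- vi
  S[jx, jx] <- vj
  S
}

#' @export
print.coexistence_summary <- function(x, ...) {
  cat(sprintf("Coexistence summary, treatment %s\n", x$treatment))
  m <- x$metrics
  m$value <- round(m$value, x$digits)
  m$se <- round(m$se, x$digits)
  print.data.frame(m, row.names = FALSE)
  cat("Outcome:", x$outcome, "\n")
  invisible(x)
}
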