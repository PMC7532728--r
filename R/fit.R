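#' Negative-binomial log-likelihood of the Beverton-Holt seed model
#'
#' Total NB2 log-likelihood of one focal species x treatment slice of a
#' seed-production table under the mean model
#' `mu = lambda / (1 + alpha_intra * N_intra + alpha_inter * N_inter)`
#' with dispersion `theta` (variance `mu + mu^2/theta`).
#'
#' @param params Named numeric vector with elements `lambda`,
#'   `alpha_intra`, `alpha_inter`, `theta`.
#' @param table A seed-production data.frame (columns `focal`,
#'   `treatment`, `neighbour`, `density`, `seeds`).
#' @param focal,treatment Slice selectors; `NULL` uses the whole table
#'   (which must then be a single slice already).
#' @return The scalar log-likelihood.
#' @export
nb_loglik <- function(params, table, focal = NULL, treatment = NULL) {
  sl <- slice_table(table, focal, treatment)
  mu <- bh_mean(params[["lambda"]], params[["alpha_intra"]],
                params[["alpha_inter"]], sl$n_intra, sl$n_inter)
  if (any(!is.finite(mu) | mu <= 0))
    stop("mean model gives non-positive expected counts at these parameters")
  sum(stats::dnbinom(sl$seeds, mu = mu, size = params[["theta"]], log = TRUE))
}

# Filter a seed-production table to one focal x treatment and derive the
# con-/heterospecific neighbour counts.
slice_table <- function(table, focal = NULL, treatment = NULL) {
  need <- c("focal", "treatment", "neighbour", "density", "seeds")
  if (!all(need %in% names(table)))
    stop("seed-production table lacks columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  sl <- table
  if (!is.null(focal)) sl <- sl[sl$focal == focal, , drop = FALSE]
  if (!is.null(treatment)) sl <- sl[sl$treatment == treatment, , drop = FALSE]
  if (is.null(focal) &&
      (length(unique(sl$focal)) > 1L || length(unique(sl$treatment)) > 1L))
    stop("table mixes focal species or treatments; pass focal/treatment")
  na_f <- is.na(sl$seeds)
  if (any(na_f)) {
    message(sum(na_f), " row(s) with missing seed counts dropped")
    sl <- sl[!na_f, , drop = FALSE]
  }
  if (nrow(sl) == 0L) stop("no rows for this focal x treatment slice")
  if (any(sl$seeds < 0) || any(sl$seeds != round(sl$seeds)))
    stop("seed counts must be non-negative integers")
  if (any(sl$density != round(sl$density)))
    stop("neighbour densities must be integers")
  if (any((sl$density == 0) != (sl$neighbour == "none")))
    stop("density 0 must coincide with neighbour type 'none'")
  sl$n_intra <- ifelse(sl$neighbour == "conspecific", sl$density, 0)
  sl$n_inter <- ifelse(sl$neighbour == "heterospecific", sl$density, 0)
  sl
}

#' Fit the Beverton-Holt competition model to seed counts
#'
#' Jointly estimates `lambda` (intrinsic fecundity), both interaction
#' coefficients and the NB2 dispersion `theta` for one focal species in
#' one treatment, by maximum likelihood over [nb_loglik()]. The
#' no-neighbour pots anchor `lambda` and are shared by the conspecific and
#' heterospecific response curves, which is why both alphas are estimated
#' in a single likelihood rather than two separate regressions.
#'
#' `lambda` and `theta` are optimized on the log scale; the alphas are
#' log-scaled too when `constrain_alpha = TRUE` (the default, since
#' competitive effects are expected non-negative) and unconstrained
#' otherwise, with a warning, to allow apparent facilitation. Optimization
#' is multi-start (alpha starts 0.01/0.1/1; `lambda` starts at the mean
#' no-neighbour seed count; `theta` at a method-of-moments value) with a
#' relative tolerance of 1e-8, followed by a quasi-Newton polish. The
#' covariance of the estimates comes from the observed information at the
#' optimum, mapped to the natural scale by the delta method.
#'
#' @param table Seed-production data.frame.
#' @param focal,treatment Slice selectors (may be omitted if `table` is
#'   already a single slice).
#' @param constrain_alpha Keep alphas non-negative (log parameterization).
#' @param control List; `reltol` overrides the optimizer tolerance.
#' @return Object of class `"bh_fit"`: estimates, SEs, covariance, logLik,
#'   convergence flag and diagnostics. Standard methods `print`,
#'   `summary`, `coef`, `vcov`, `logLik`, `predict`, `simulate`,
#'   `residuals` apply.
#' @examples
#' pars <- published_estimates()$dry$params
#' tab <- simulate_seed_production(make_design(treatments = "dry"), pars, seed = 42)
#' fit <- fit_competition(tab, focal = "i", treatment = "dry")
#' coef(fit)
#' @export
fit_competition <- function(table, focal = NULL, treatment = NULL,
                            constrain_alpha = TRUE, control = list()) {
  sl <- slice_table(table, focal, treatment)
  for (nb in c("intra", "inter")) {
    nn <- sl[[paste0("n_", nb)]]
    if (all(nn == 0))
      stop("degenerate design: no pots with nonzero ", nb,
           "specific neighbour density; alpha_", nb, " is unidentifiable")
  }
  if (!constrain_alpha)
    warning("alphas unconstrained: negative estimates denote facilitation")

  reltol <- if (is.null(control$reltol)) 1e-8 else control$reltol
  f0 <- sl$seeds[sl$n_intra == 0 & sl$n_inter == 0]
  lam0 <- max(mean(if (length(f0)) f0 else sl$seeds), 1)
  m <- mean(sl$seeds); v <- stats::var(sl$seeds)
  th0 <- if (is.finite(v) && v > m) min(max(m^2 / (v - m), 0.1), 100) else 5

  t_alpha <- if (constrain_alpha) log else identity
  u_alpha <- if (constrain_alpha) exp else identity
  negll <- function(p) {
    pars <- c(lambda = exp(p[1]), alpha_intra = u_alpha(p[2]),
              alpha_inter = u_alpha(p[3]), theta = exp(p[4]))
    ll <- tryCatch(nb_loglik(pars, sl), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- lapply(c(0.01, 0.1, 1), function(a0)
    c(log(lam0), t_alpha(a0), t_alpha(a0), log(th0)))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = reltol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  polish <- tryCatch(
    stats::optim(best$par, negll, method = "BFGS",
                 control = list(maxit = 500, reltol = reltol)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish

  p <- best$par
  est <- c(lambda = exp(p[1]), alpha_intra = u_alpha(p[2]),
           alpha_inter = u_alpha(p[3]), theta = exp(p[4]))
  H <- tryCatch(stats::optimHess(p, negll), error = function(e) NULL)
  vc <- matrix(NA_real_, 4, 4, dimnames = list(names(est), names(est)))
  ok_vc <- FALSE
  if (!is.null(H)) {
    vt <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vt)) {
      # delta method: natural = g(transformed), J diagonal
      jd <- c(est[["lambda"]],
              if (constrain_alpha) est[["alpha_intra"]] else 1,
              if (constrain_alpha) est[["alpha_inter"]] else 1,
              est[["theta"]])
      J <- diag(jd)
      vc <- J %*% ((vt + t(vt)) / 2) %*% J
      dimnames(vc) <- list(names(est), names(est))
      ok_vc <- all(is.finite(diag(vc))) && all(diag(vc) >= 0)
    }
  }
  converged <- best$convergence == 0 && is.finite(best$value)
  structure(list(
    estimates = est,
    se = if (ok_vc) sqrt(diag(vc)) else stats::setNames(rep(NA_real_, 4), names(est)),
    vcov = vc,
    logLik = -best$value,
    converged = converged,
    focal = if (is.null(focal)) unique(sl$focal) else focal,
    treatment = if (is.null(treatment)) unique(sl$treatment) else treatment,
    n = nrow(sl),
    constrain_alpha = constrain_alpha,
    data = sl,
    optim = list(counts = best$counts, convergence = best$convergence,
                 value = best$value)),
    class = "bh_fit")
}

#' @export
print.bh_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Beverton-Holt NB fit: focal %s, treatment %s (n = %d pots)\n",
              x$focal, x$treatment, x$n))
  print(round(x$estimates, digits))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.bh_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$estimates, `Std. Error` = object$se)
  structure(list(table = tab, logLik = object$logLik,
                 converged = object$converged, focal = object$focal,
                 treatment = object$treatment, n = object$n),
            class = "summary.bh_fit")
}

#' @export
print.summary.bh_fit <- function(x, ...) {
  cat(sprintf("Beverton-Holt NB fit: focal %s, treatment %s (n = %d pots)\n",
              x$focal, x$treatment, x$n))
  stats::printCoefmat(x$table)
  cat(sprintf("logLik: %.3f   converged: %s\n", x$logLik, x$converged))
  invisible(x)
}

#' @export
coef.bh_fit <- function(object, ...) object$estimates

#' @export
vcov.bh_fit <- function(object, ...) object$vcov

#' @export
logLik.bh_fit <- function(object, ...) {
  structure(object$logLik, df = 4L, nobs = object$n, class = "logLik")
}

#' @export
predict.bh_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else {
    nd <- newdata
    if (!all(c("n_intra", "n_inter") %in% names(nd))) {
      nd$n_intra <- ifelse(nd$neighbour == "conspecific", nd$density, 0)
      nd$n_inter <- ifelse(nd$neighbour == "heterospecific", nd$density, 0)
    }
    nd
  }
  e <- object$estimates
  bh_mean(e[["lambda"]], e[["alpha_intra"]], e[["alpha_inter"]],
          d$n_intra, d$n_inter)
}

#' @export
residuals.bh_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- predict(object)
  r <- object$data$seeds - mu
  if (type == "pearson")
    r <- r / sqrt(mu + mu^2 / object$estimates[["theta"]])
  r
}

#' @export
simulate.bh_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- predict(object)
  th <- object$estimates[["theta"]]
  draw <- function() stats::rnbinom(length(mu), mu = mu, size = th)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' @export
plot.bh_fit <- function(x, ...) {
  d <- x$data
  dens <- d$density
  graphics::plot(jitter(dens), d$seeds,
                 pch = ifelse(d$neighbour == "heterospecific", 1, 16),
                 xlab = "neighbour density", ylab = "seeds per focal plant",
                 main = sprintf("focal %s, %s", x$focal, x$treatment), ...)
  nn <- seq(0, max(dens), length.out = 100)
  e <- x$estimates
  graphics::lines(nn, bh_mean(e[["lambda"]], e[["alpha_intra"]], 0, nn, 0), lty = 1)
  graphics::lines(nn, bh_mean(e[["lambda"]], 0, e[["alpha_inter"]], 0, nn), lty = 2)
  invisible(x)
}

#' Stratified nonparametric bootstrap of a competition fit
#'
#' Resamples pots with replacement within each neighbour-type x density
#' cell (preserving the experimental design) and refits the model to each
#' replicate. Replicates that fail to converge are excluded and counted.
#' The bootstrap means and SDs are the conventional headline estimates and
#' standard errors for this design; the full-data ML fit is kept alongside.
#'
#' @param table,focal,treatment As in [fit_competition()].
#' @param n_boot Number of replicates (>= 2; default 50).
#' @param seed Integer seed; fixed seed gives identical replicate sets.
#' @param ... Passed to [fit_competition()].
#' @return Object of class `"bh_boot"`: matrix `replicates` (one row per
#'   converged replicate: lambda, alpha_intra, alpha_inter, theta), the
#'   full-data `fit`, counts and the seed.
#' @export
bootstrap_fit <- function(table, focal = NULL, treatment = NULL,
                          n_boot = 50, seed = 1, ...) {
  if (n_boot < 2) stop("n_boot must be >= 2 (a single replicate has no SD)")
  full <- fit_competition(table, focal, treatment, ...)
  sl <- full$data
  strata <- interaction(sl$neighbour, sl$density, drop = TRUE)
  if (any(table(strata) == 0)) stop("empty design stratum")
  idx_by <- split(seq_len(nrow(sl)), strata)

  reps <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(idx_by, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]))
      tryCatch({
        f <- fit_competition(sl[idx, , drop = FALSE], ...)
        if (f$converged) f$estimates else NULL
      }, error = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  if (sum(ok) < 2) stop("fewer than 2 bootstrap replicates converged")
  mat <- do.call(rbind, reps[ok])
  structure(list(replicates = mat, fit = full, n_boot = n_boot,
                 n_failed = sum(!ok), seed = seed,
                 focal = full$focal, treatment = full$treatment),
            class = "bh_boot")
}

#' @export
print.bh_boot <- function(x, ...) {
  cat(sprintf("Bootstrap of Beverton-Holt fit (focal %s, %s): %d/%d replicates converged\n",
              x$focal, x$treatment, nrow(x$replicates), x$n_boot))
  print(summary(x))
  invisible(x)
}

#' @export
summary.bh_boot <- function(object, ...) {
  cbind(mean = colMeans(object$replicates),
        se = apply(object$replicates, 2, stats::sd),
        full_data = object$fit$estimates)
}

#' Estimate germination fractions from trial counts
#'
#' Pools germinants over pots per species; the estimate is the pooled
#' fraction with its binomial standard error `sqrt(g (1 - g) / n_sown)`.
#'
#' @param trials Data.frame with columns `species`, `sown`, `germinated`.
#' @return Data.frame, one row per species: `species`, `germinated`,
#'   `sown`, `g`, `se`.
#' @examples
#' estimate_germination(data.frame(species = "i", sown = 432, germinated = 289))
#' @export
estimate_germination <- function(trials) {
  need <- c("species", "sown", "germinated")
  if (!all(need %in% names(trials)))
    stop("germination trials lack columns: ",
         paste(setdiff(need, names(trials)), collapse = ", "))
  if (any(trials$germinated < 0) || any(trials$germinated > trials$sown))
    stop("germinants must lie between 0 and seeds sown")
  out <- do.call(rbind, lapply(split(trials, trials$species), function(d) {
    n <- sum(d$sown)
    if (n <= 0) stop("zero seeds sown for species ", d$species[1])
    k <- sum(d$germinated)
    g <- k / n
    data.frame(species = d$species[1], germinated = k, sown = n,
               g = g, se = sqrt(g * (1 - g) / n))
  }))
  rownames(out) <- NULL
  out
}
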