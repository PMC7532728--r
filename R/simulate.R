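#' Expected seed production under the Beverton-Holt annual-plant model
#'
#' Per-germinant fecundity declines hyperbolically with weighted neighbour
#' densities: `mu = lambda / (1 + alpha_intra * N_intra + alpha_inter *
#' N_inter)`.
#'
#' @param lambda Intrinsic fecundity (seeds per plant at zero neighbours).
#' @param alpha_intra,alpha_inter Interaction coefficients for conspecific
#'   and heterospecific neighbours.
#' @param n_intra,n_inter Neighbour counts.
#' @return Expected seed count(s).
#' @examples
#' bh_mean(365.9, 0.25, 0.29, n_intra = 20, n_inter = 0)  # 60.98...
#' @export
bh_mean <- function(lambda, alpha_intra, alpha_inter, n_intra, n_inter) {
  lambda / (1 + alpha_intra * n_intra + alpha_inter * n_inter)
}

#' Simulate seed production for a pot experiment
#'
#' Draws per-pot seed counts from a negative binomial (NB2) whose mean
#' follows the Beverton-Holt competition model given the focal species'
#' intrinsic fecundity and the composition of its neighbourhood.
#' Neighbour densities are taken as exact (the experiment thins germinants
#' to target densities). Both focal species use the parameter set's shared
#' dispersion `theta`.
#'
#' The treatment labels in `design` are labels only: to emulate distinct
#' wet/dry biology, call once per treatment with that treatment's
#' parameter set (as [run_pipeline()] does).
#'
#' @param design A [make_design()] data.frame (or any data.frame with
#'   columns `focal`, `treatment`, `neighbour`, `density`, `reps`).
#' @param params A [competition_params()] object.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A data.frame of class `"seed_production"` with one row per pot:
#'   `pot`, `treatment`, `focal`, `neighbour`, `density`, `seeds`.
#' @export
simulate_seed_production <- function(design, params, seed = 1) {
  stopifnot(inherits(params, "competition_params"))
  need <- c("focal", "treatment", "neighbour", "density", "reps")
  if (!all(need %in% names(design)))
    stop("design lacks columns: ",
         paste(setdiff(need, names(design)), collapse = ", "))
  species <- unique(design$focal)
  if (length(species) > 2L) stop("design has more than two focal species")

  rows <- design[rep(seq_len(nrow(design)), design$reps), , drop = FALSE]
  rows$reps <- NULL
  rows$pot <- seq_len(nrow(rows))
  # species[1] plays role i, species[2] role j
  is_i <- rows$focal == species[1]
  lam <- ifelse(is_i, params$lambda_i, params$lambda_j)
  a_intra <- ifelse(is_i, params$alpha_ii, params$alpha_jj)
  a_inter <- ifelse(is_i, params$alpha_ij, params$alpha_ji)
  n_intra <- ifelse(rows$neighbour == "conspecific", rows$density, 0)
  n_inter <- ifelse(rows$neighbour == "heterospecific", rows$density, 0)
  mu <- bh_mean(lam, a_intra, a_inter, n_intra, n_inter)
  bad <- !is.finite(mu) | mu <= 0
  if (any(bad))
    stop("non-positive or non-finite expected seed count for pot(s) ",
         paste(utils::head(rows$pot[bad], 5L), collapse = ", "))
  rows$seeds <- with_seed(seed,
    stats::rnbinom(nrow(rows), mu = mu, size = params$theta))
  out <- rows[, c("pot", "treatment", "focal", "neighbour", "density", "seeds")]
  rownames(out) <- NULL
  class(out) <- c("seed_production", "data.frame")
  out
}

#' Simulate germination trials
#'
#' Per-pot germinant counts are binomial draws at each species' germination
#' fraction; the default layout (72 pots of 3 seeds per species, 432 seeds
#' each) mirrors a standard spring germination trial.
#'
#' @param params A [competition_params()] object (uses `g_i`, `g_j`).
#' @param pots_per_species,seeds_per_pot Trial layout.
#' @param species Labels for the two species.
#' @param seed Integer seed.
#' @return A data.frame with columns `species`, `pot`, `sown`,
#'   `germinated`.
#' @export
simulate_germination <- function(params, pots_per_species = 72,
                                 seeds_per_pot = 3,
                                 species = c("i", "j"), seed = 1) {
  stopifnot(inherits(params, "competition_params"))
  if (pots_per_species < 1 || seeds_per_pot < 1)
    stop("trial layout counts must be positive")
  g <- c(params$g_i, params$g_j)
  out <- data.frame(
    species = rep(species, each = pots_per_species),
    pot = rep(seq_len(pots_per_species), 2L),
    sown = seeds_per_pot)
  out$germinated <- with_seed(seed,
    stats::rbinom(nrow(out), size = seeds_per_pot, prob = rep(g, each = pots_per_species)))
  out
}

#' Parameters for the synthetic field survey generator
#'
#' Controls a generative model that emulates a two-scale field survey:
#' 1-m2 plots nested in transects within sites, each containing two
#' 0.1-m2 subplots. Abundances of the two species are negative-binomial
#' with log-link means; the introduced species' log-mean is linear in the
#' native species' count, so a negative `assoc` reproduces an inverse
#' abundance pattern. Individual plants carry fecundity proxies (height,
#' inflorescence number, main inflorescence size) and a seed count whose
#' log-mean depends on height plus an interspecific density effect for the
#' introduced species only.
#'
#' @param n_plots Number of 1-m2 plots (each yields two 0.1-m2 subplots).
#' @param n_sites,transects_per_site Nesting structure; plots are split
#'   evenly across transects.
#' @param mean_p,mean_v Baseline expected counts per 0.1-m2 subplot for
#'   the native (P) and introduced (V) species.
#' @param assoc Cross-species association: coefficient of the native count
#'   in the introduced species' log-mean (per plant; negative = inverse
#'   pattern).
#' @param theta NB2 dispersion of the abundance counts (> 0).
#' @param sd_site,sd_transect SDs of log-scale random intercepts.
#' @param seed_dd Interspecific density-dependence of introduced-species
#'   fecundity: coefficient of native count in the log seed mean.
#' @param beta_height Common log-linear effect of plant height (cm) on
#'   seed count.
#' @param theta_seeds NB2 dispersion of individual seed counts.
#' @return A named list of class `"field_params"`.
#' @export
field_params <- function(n_plots = 70, n_sites = 2, transects_per_site = 5,
                         mean_p = 8, mean_v = 6, assoc = -0.05, theta = 2,
                         sd_site = 0.2, sd_transect = 0.3,
                         seed_dd = -0.03, beta_height = 0.08,
                         theta_seeds = 3) {
  fp <- as.list(environment())
  if (fp$theta <= 0 || fp$theta_seeds <= 0)
    stop("dispersions must be positive")
  if (fp$n_plots < 1 || fp$n_sites < 1 || fp$transects_per_site < 1)
    stop("nesting specification must be positive")
  structure(fp, class = "field_params")
}

#' Simulate a two-scale field survey
#'
#' Generates plot-level abundances and per-individual fecundity proxies
#' under the generative model described in [field_params()]. Soil moisture
#' (%VWC at two probe depths) and a binary soil depth class are drawn as
#' plot-level covariates uncorrelated with the counts by default.
#'
#' @param fp A [field_params()] object.
#' @param seed Integer seed.
#' @return A list of class `"field_survey"` with elements `plots` (one row
#'   per plot at both spatial scales: `site`, `transect`, `plot`, `area_m2`,
#'   `count_p`, `count_v`, `vwc_7.6`, `vwc_12`, `depth_class`) and
#'   `individuals` (per measured plant: `plot`, `species`, `height`,
#'   `inflorescences`, `infl_size`, `seeds`). The 0.1-m2 rows are the
#'   direct-interaction scale used by the regression stage.
#' @export
simulate_field_survey <- function(fp = field_params(), seed = 1) {
  stopifnot(inherits(fp, "field_params"))
  with_seed(seed, {
    n_tr <- fp$n_sites * fp$transects_per_site
    plot_site <- rep(seq_len(fp$n_sites), length.out = fp$n_plots)
    plot_transect <- rep(seq_len(n_tr), length.out = fp$n_plots)
    re_site <- stats::rnorm(fp$n_sites, 0, fp$sd_site)
    re_tr <- stats::rnorm(n_tr, 0, fp$sd_transect)

    sub <- data.frame(
      site = rep(plot_site, each = 2L),
      transect = rep(plot_transect, each = 2L),
      plot = paste0("P", rep(seq_len(fp$n_plots), each = 2L), c("a", "b")),
      parent = rep(seq_len(fp$n_plots), each = 2L),
      area_m2 = 0.1)
    eta <- re_site[sub$site] + re_tr[sub$transect]
    sub$count_p <- stats::rnbinom(nrow(sub), mu = fp$mean_p * exp(eta),
                                  size = fp$theta)
    mu_v <- fp$mean_v * exp(eta + fp$assoc * sub$count_p)
    sub$count_v <- stats::rnbinom(nrow(sub), mu = mu_v, size = fp$theta)

    big <- data.frame(
      site = plot_site, transect = plot_transect,
      plot = paste0("P", seq_len(fp$n_plots)),
      parent = seq_len(fp$n_plots), area_m2 = 1)
    agg_p <- tapply(sub$count_p, sub$parent, sum)
    agg_v <- tapply(sub$count_v, sub$parent, sum)
    # the 1-m2 count includes the two nested subplots plus the rest of the
    # plot, modelled as three further subplot-equivalents
    eta1 <- re_site[big$site] + re_tr[big$transect]
    big$count_p <- as.integer(agg_p) +
      stats::rnbinom(nrow(big), mu = 3 * fp$mean_p * exp(eta1), size = fp$theta)
    extra_v_mu <- 3 * fp$mean_v * exp(eta1 + fp$assoc * as.integer(agg_p) / 2)
    big$count_v <- as.integer(agg_v) +
      stats::rnbinom(nrow(big), mu = extra_v_mu, size = fp$theta)

    plots <- rbind(big, sub)[, c("site", "transect", "plot", "area_m2",
                                 "count_p", "count_v")]
    plots$vwc_7.6 <- pmin(100, pmax(0, stats::rnorm(nrow(plots), 18, 5)))
    plots$vwc_12 <- pmin(100, pmax(0, plots$vwc_7.6 +
                                     stats::rnorm(nrow(plots), 2, 2)))
    plots$depth_class <- sample(c("<12cm", ">12cm"), nrow(plots),
                                replace = TRUE)
    rownames(plots) <- NULL

    # measured individuals: up to 10 per species per 0.1-m2 subplot
    ind <- do.call(rbind, lapply(seq_len(nrow(sub)), function(r) {
      np <- min(sub$count_p[r], 10L); nv <- min(sub$count_v[r], 10L)
      if (np + nv == 0L) return(NULL)
      data.frame(plot = sub$plot[r],
                 species = c(rep("P", np), rep("V", nv)),
                 other_count = c(rep(sub$count_v[r], np),
                                 rep(sub$count_p[r], nv)))
    }))
    if (is.null(ind)) ind <- data.frame(plot = character(), species = character(),
                                        other_count = integer())
    n_ind <- nrow(ind)
    ind$height <- stats::rlnorm(n_ind, log(20), 0.25)
    ind$inflorescences <- 1L + stats::rpois(n_ind, 2)
    ind$infl_size <- stats::rlnorm(n_ind, log(1.5), 0.3)
    log_mu <- log(15) + fp$beta_height * (ind$height - 20) +
      ifelse(ind$species == "V", fp$seed_dd * ind$other_count, 0)
    ind$seeds <- stats::rnbinom(n_ind, mu = exp(log_mu), size = fp$theta_seeds)
    ind$other_count <- NULL
    rownames(ind) <- NULL

    structure(list(plots = plots, individuals = ind, params = fp),
              class = "field_survey")
  })
}

#' @export
print.field_survey <- function(x, ...) {
  cat(sprintf("Synthetic field survey: %d plot rows (%d at 1 m2, %d at 0.1 m2), %d individuals\n",
              nrow(x$plots), sum(x$plots$area_m2 == 1),
              sum(x$plots$area_m2 == 0.1), nrow(x$individuals)))
  invisible(x)
}

#' Write the simulated tables as CSV
#'
#' @param x A `seed_production` data.frame, germination data.frame, or
#'   `field_survey` object.
#' @param path Output file (for a field survey, two files are written with
#'   `_plots` and `_individuals` suffixes).
#' @return Invisibly, the path(s) written.
#' @export
write_survey_csv <- function(x, path) {
  if (inherits(x, "field_survey")) {
    base <- sub("\\.csv$", "", path)
    p1 <- paste0(base, "_plots.csv"); p2 <- paste0(base, "_individuals.csv")
    utils::write.csv(x$plots, p1, row.names = FALSE)
    utils::write.csv(x$individuals, p2, row.names = FALSE)
    return(invisible(c(p1, p2)))
  }
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
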