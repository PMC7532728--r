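test_that("nb_loglik matches closed forms and is additive", {
  one <- data.frame(pot = 1, treatment = "dry", focal = "i",
                    neighbour = "none", density = 0, seeds = 0)
  for (mu in c(2, 50)) for (th in c(0.5, 5)) {
    p <- c(lambda = mu, alpha_intra = 0.1, alpha_inter = 0.1, theta = th)
    expect_equal(nb_loglik(p, one), th * log(th / (th + mu)))
  }
  tab <- noise_free_slice()[1:10, ]
  p <- c(lambda = 180, alpha_intra = 0.25, alpha_inter = 0.2, theta = 4)
  expect_equal(nb_loglik(p, rbind(tab, tab)), 2 * nb_loglik(p, tab))
  # theta -> infinity approaches the Poisson log-likelihood
  mu <- bh_mean(p[["lambda"]], p[["alpha_intra"]], p[["alpha_inter"]],
                ifelse(tab$neighbour == "conspecific", tab$density, 0),
                ifelse(tab$neighbour == "heterospecific", tab$density, 0))
  pois <- sum(dpois(tab$seeds, mu, log = TRUE))
  p_inf <- p; p_inf[["theta"]] <- 1e6
  expect_lt(abs(nb_loglik(p_inf, tab) - pois), 1e-3)
  expect_error(nb_loglik(p, tab[0, ]), "no rows")
})

test_that("fit recovers noise-free parameters almost exactly", {
  tab <- noise_free_slice(lambda = 200, a_ii = 0.3, a_ij = 0.2)
  f <- fit_competition(tab)
  expect_true(f$converged)
  expect_equal(unname(coef(f)[["lambda"]]), 200, tolerance = 0.02)
  expect_equal(unname(coef(f)[["alpha_intra"]]), 0.3, tolerance = 0.05)
  expect_equal(unname(coef(f)[["alpha_inter"]]), 0.2, tolerance = 0.05)
})

test_that("fitted likelihood beats an independent grid-search oracle", {
  p <- dry_params()
  tab <- simulate_seed_production(make_design(treatments = "dry"), p, seed = 21)
  f <- fit_competition(tab, focal = "j", treatment = "dry")
  expect_true(f$converged)
  g <- grid_oracle(f$data,
                   lambda_grid = seq(450, 900, by = 25),
                   alpha_grid = seq(0.2, 1.2, by = 0.05),
                   theta_grid = c(2, 3, 4, 5, 7, 10))
  expect_gte(f$logLik, g$loglik - 1e-4)
})

test_that("fit is invariant to row permutation and flags degenerate designs", {
  p <- dry_params()
  tab <- simulate_seed_production(make_design(treatments = "dry"), p, seed = 33)
  f1 <- fit_competition(tab, focal = "i", treatment = "dry")
  perm <- tab[sample(nrow(tab)), ]
  f2 <- fit_competition(perm, focal = "i", treatment = "dry")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  # covariance is symmetric PSD with positive SEs
  expect_equal(f1$vcov, t(f1$vcov))
  expect_true(all(eigen(f1$vcov, only.values = TRUE)$values > -1e-8))
  expect_true(all(f1$se > 0))
  # constant data with no neighbours: alphas unidentifiable
  flat <- data.frame(pot = 1:8, treatment = "dry", focal = "i",
                     neighbour = "none", density = 0, seeds = 50)
  expect_error(fit_competition(flat), "unidentifiable")
  noint <- tab[tab$focal == "i" & tab$neighbour != "heterospecific", ]
  expect_error(fit_competition(noint), "inter")
  expect_warning(fit_competition(tab, focal = "i", treatment = "dry",
                                 constrain_alpha = FALSE), "facilitation")
})

test_that("stratified bootstrap is deterministic and centred on the fit", {
  p <- dry_params()
  tab <- simulate_seed_production(make_design(treatments = "dry"), p, seed = 8)
  b1 <- bootstrap_fit(tab, focal = "i", treatment = "dry", n_boot = 20, seed = 13)
  b2 <- bootstrap_fit(tab, focal = "i", treatment = "dry", n_boot = 20, seed = 13)
  expect_identical(b1$replicates, b2$replicates)
  expect_equal(nrow(b1$replicates) + b1$n_failed, 20)
  # bootstrap mean close to the full-data estimate (bias well inside one SE)
  sm <- summary(b1)
  expect_lt(abs(sm["lambda", "mean"] - sm["lambda", "full_data"]),
            sm["lambda", "se"])
  expect_error(bootstrap_fit(tab, focal = "i", treatment = "dry", n_boot = 1),
               "n_boot")
})

test_that("bootstrap SE of lambda is on the reported scale for species j, dry", {
  p <- dry_params()
  tab <- simulate_seed_production(make_design(treatments = "dry"), p, seed = 17)
  b <- bootstrap_fit(tab, focal = "j", treatment = "dry", n_boot = 50, seed = 19)
  se <- summary(b)["lambda", "se"]
  # order-of-magnitude consistency with the published bootstrap SE (57.4)
  expect_gt(se, 57.4 / 2)
  expect_lt(se, 57.4 * 2)
})

test_that("germination estimation pools counts with binomial SEs", {
  e <- estimate_germination(data.frame(species = "i", sown = 432,
                                       germinated = 289))
  expect_equal(e$g, 0.669, tolerance = 1e-3)
  expect_equal(e$se, sqrt(e$g * (1 - e$g) / 432))
  e2 <- estimate_germination(data.frame(species = c("i", "j"),
                                        sown = 432, germinated = c(432, 0)))
  expect_equal(e2$g, c(1, 0))
  expect_equal(e2$se, c(0, 0))
  expect_error(estimate_germination(data.frame(species = "i", sown = 0,
                                               germinated = 0)), "zero")
  expect_error(estimate_germination(data.frame(species = "i", sown = 3,
                                               germinated = 4)), "between")
})
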