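test_that("default design reproduces the pot experiment layout", {
  d <- make_design()
  per <- aggregate(reps ~ focal + treatment, data = d, sum)
  expect_true(all(per$reps == 72))
  expect_equal(sum(d$reps), 288)
  # one no-neighbour cell, con+het cells at each nonzero density
  one <- d[d$focal == "i" & d$treatment == "dry", ]
  expect_equal(sum(one$neighbour == "none"), 1)
  expect_equal(sort(unique(one$density)), c(0, 4, 10, 20))
})

test_that("design overrides and error handling behave", {
  d1 <- make_design(reps = c(`0` = 1, `4` = 1, `10` = 1, `20` = 1),
                    treatments = "dry")
  expect_equal(sum(d1$reps[d1$focal == "i"]), 7)
  expect_error(make_design(reps = c(`0` = 0, `4` = 1)), "positive")
  expect_error(make_design(reps = c(`0` = 16, `4` = 2.5)), "positive integers")
  expect_error(make_design(reps = c(`4` = 12)), "density-0")
})

test_that("seed production follows the Beverton-Holt mean and NB2 noise", {
  expect_equal(bh_mean(365.9, 0.25, 0.29, 20, 0), 365.9 / (1 + 0.25 * 20))
  p <- competition_params(lambda_i = 365.9, lambda_j = 650,
                          alpha_ii = 0.25, alpha_ij = 0.29,
                          alpha_jj = 0.73, alpha_ji = 0.45, theta = 5)
  # large replication at N = 0: sample mean converges to lambda,
  # and the empirical variance matches var = mu + mu^2 / theta
  d <- make_design(reps = c(`0` = 10000, `4` = 1, `10` = 1, `20` = 1),
                   treatments = "dry", species = c("i", "j"))
  tab <- simulate_seed_production(d, p, seed = 11)
  f0 <- tab$seeds[tab$focal == "i" & tab$density == 0]
  expect_equal(mean(f0), 365.9, tolerance = 0.01)
  expect_equal(var(f0), 365.9 + 365.9^2 / 5, tolerance = 0.1)
  # rows out = pots in
  expect_equal(nrow(tab), sum(d$reps))
})

test_that("seed production simulation is deterministic and guards its mean", {
  p <- dry_params()
  d <- make_design(treatments = "dry")
  t1 <- simulate_seed_production(d, p, seed = 5)
  t2 <- simulate_seed_production(d, p, seed = 5)
  expect_identical(t1, t2)
  t3 <- simulate_seed_production(d, p, seed = 6)
  expect_false(identical(t1$seeds, t3$seeds))
  bad <- competition_params(lambda_i = 10, lambda_j = 10,
                            alpha_ii = -0.9, alpha_ij = 0, alpha_jj = 0.1,
                            alpha_ji = 0.1, allow_facilitation = TRUE)
  expect_error(simulate_seed_production(d, bad, seed = 1), "pot")
})

test_that("germination simulation is binomial with the stated defaults", {
  pg <- function(gi, gj) competition_params(
    lambda_i = 100, lambda_j = 100, alpha_ii = .1, alpha_ij = .1,
    alpha_jj = .1, alpha_ji = .1, g_i = gi, g_j = gj)
  g1 <- simulate_germination(pg(1, 0), seed = 2)
  expect_true(all(g1$germinated[g1$species == "i"] == g1$sown[g1$species == "i"]))
  expect_true(all(g1$germinated[g1$species == "j"] == 0))
  expect_equal(nrow(g1), 144)  # 72 pots x 2 species
  expect_true(all(g1$sown == 3))
  # pooled fraction within 3 binomial SEs of the truth
  g2 <- simulate_germination(pg(0.67, 0.891), seed = 3)
  for (sp in c("i", "j")) {
    gg <- g2[g2$species == sp, ]
    truth <- if (sp == "i") 0.67 else 0.891
    se <- sqrt(truth * (1 - truth) / 432)
    expect_lt(abs(sum(gg$germinated) / sum(gg$sown) - truth), 3 * se)
  }
  expect_error(competition_params(lambda_i = 1, lambda_j = 1, alpha_ii = .1,
                                  alpha_ij = .1, alpha_jj = .1, alpha_ji = .1,
                                  g_i = 1.2), "\\[0, 1\\]")
})

test_that("field survey generator matches its design and association knob", {
  fs <- simulate_field_survey(field_params(), seed = 4)
  expect_equal(sum(fs$plots$area_m2 == 1), 70)
  expect_equal(sum(fs$plots$area_m2 == 0.1), 140)
  expect_identical(fs, simulate_field_survey(field_params(), seed = 4))
  # zero association: counts uncorrelated at large n
  big <- simulate_field_survey(field_params(n_plots = 5000, assoc = 0,
                                            sd_site = 0, sd_transect = 0),
                               seed = 9)
  sub <- big$plots[big$plots$area_m2 == 0.1, ]
  expect_lt(abs(cor(sub$count_p, sub$count_v)), 0.1)
  # strongly negative association: negative rank correlation
  neg <- simulate_field_survey(field_params(n_plots = 1000, assoc = -0.3),
                               seed = 9)
  subn <- neg$plots[neg$plots$area_m2 == 0.1, ]
  expect_lt(cor(subn$count_p, subn$count_v, method = "spearman"), 0)
  expect_error(field_params(theta = -1), "positive")
})
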