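dry_a <- c(0.25, 0.29, 0.73, 0.45)  # alpha_ii, alpha_ij, alpha_jj, alpha_ji
wet_a <- c(0.37, 0.27, 0.47, 0.42)

test_that("niche overlap reproduces the published values and symmetry limit", {
  expect_equal(round(do.call(niche_overlap, as.list(dry_a)), 2), 0.85)
  expect_equal(round(do.call(niche_overlap, as.list(wet_a)), 2), 0.81)
  expect_equal(niche_overlap(0.4, 0.4, 0.4, 0.4), 1)
  expect_error(niche_overlap(0, 0.1, 0.1, 0.1), "positive")
})

test_that("demographic and competitive response ratios match the published table", {
  expect_equal(round(demographic_ratio(650.0, 365.9), 2), 1.78)
  expect_equal(round(demographic_ratio(327.4, 391.23), 2), 0.84)
  expect_equal(demographic_ratio(100, 100), 1)
  expect_error(demographic_ratio(0.9, 100), "lambda > 1")
  # g-weighted sensitivity variant discounts the seed surplus
  expect_equal(demographic_ratio(650.0, 365.9, g_j = 0.891, g_i = 0.670),
               (650.0 * 0.891 - 1) / (365.9 * 0.670 - 1))
  expect_error(demographic_ratio(650, 365.9, g_j = 0.9), "both")
  expect_equal(round(do.call(competitive_response_ratio, as.list(dry_a)), 2), 0.47)
  expect_equal(round(do.call(competitive_response_ratio, as.list(wet_a)), 2), 0.71)
  expect_equal(competitive_response_ratio(0.3, 0.3, 0.3, 0.3), 1)
})

test_that("fitness ratio is exactly the product of its two components", {
  k_dry <- fitness_ratio(365.9, 650.0, 0.25, 0.29, 0.73, 0.45)
  expect_identical(k_dry, demographic_ratio(650.0, 365.9) *
                     do.call(competitive_response_ratio, as.list(dry_a)))
  expect_lt(abs(k_dry - 0.83), 0.01 + 1e-9)
  k_wet <- fitness_ratio(391.23, 327.4, 0.37, 0.27, 0.47, 0.42)
  expect_lt(abs(k_wet - 0.60), 0.01)
  expect_equal(fitness_ratio(50, 50, .2, .2, .2, .2), 1)
})

test_that("invasion growth rates reproduce the published values", {
  expect_equal(round(invasion_growth_rate(391.23, 327.4, 0.27, 0.47), 2), 2.08)
  expect_equal(round(invasion_growth_rate(327.4, 391.23, 0.42, 0.37), 2), 0.74)
  expect_equal(round(invasion_growth_rate(650.0, 365.9, 0.45, 0.25), 2), 0.99)
  expect_lt(abs(invasion_growth_rate(365.9, 650.0, 0.29, 0.73) - 1.43), 0.02)
  expect_equal(invasion_growth_rate(42, 10, 0, 0.5), 42)
  expect_error(invasion_growth_rate(42, 10, 0.1, 0), "equilibrium")
})

test_that("outcome classification follows the stabilization band", {
  expect_equal(classify_outcome(0.85, 0.83), "i excludes j")
  expect_equal(classify_outcome(0.5, 1.0), "coexistence")
  expect_equal(classify_outcome(0.5, 2.5), "j excludes i")
  expect_equal(classify_outcome(1.25, 1.0), "priority effect")
  expect_equal(classify_outcome(1, 1), "indeterminate")
  expect_equal(classify_outcome(0.7, 0.7), "indeterminate")
  expect_error(classify_outcome(-1, 1), "positive")
})

test_that("classification agrees with mutual invasibility over random parameters", {
  set.seed(101)
  n_checked <- 0
  for (k in 1:1000) {
    p <- random_pair_params()
    if (p[["lambda_i"]] <= 1 || p[["lambda_j"]] <= 1) next
    rho <- niche_overlap(p[["alpha_ii"]], p[["alpha_ij"]],
                         p[["alpha_jj"]], p[["alpha_ji"]])
    kap <- fitness_ratio(p[["lambda_i"]], p[["lambda_j"]],
                         p[["alpha_ii"]], p[["alpha_ij"]],
                         p[["alpha_jj"]], p[["alpha_ji"]])
    # skip boundary cases
    if (min(abs(kap - rho), abs(kap - 1 / rho), abs(rho - 1)) < 1e-9) next
    lab <- classify_outcome(rho, kap)
    gi <- invasion_growth_rate(p[["lambda_i"]], p[["lambda_j"]],
                               p[["alpha_ij"]], p[["alpha_jj"]])
    gj <- invasion_growth_rate(p[["lambda_j"]], p[["lambda_i"]],
                               p[["alpha_ji"]], p[["alpha_ii"]])
    expected <- if (gi > 1 && gj > 1) "coexistence"
      else if (gi > 1) "i excludes j"
      else if (gj > 1) "j excludes i"
      else "priority effect"
    expect_identical(lab, expected)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 900)
})

test_that("swapping species labels maps the metrics as expected", {
  set.seed(77)
  for (k in 1:25) {
    p <- random_pair_params()
    q <- c(lambda_i = p[["lambda_j"]], lambda_j = p[["lambda_i"]],
           alpha_ii = p[["alpha_jj"]], alpha_ij = p[["alpha_ji"]],
           alpha_jj = p[["alpha_ii"]], alpha_ji = p[["alpha_ij"]])
    fns <- plantcoex:::metric_functions()
    expect_equal(fns$niche_overlap(q), fns$niche_overlap(p))
    expect_equal(fns$fitness_ratio(q), 1 / fns$fitness_ratio(p))
    expect_equal(fns$igr_i_into_j(q), fns$igr_j_into_i(p))
    expect_equal(fns$igr_j_into_i(q), fns$igr_i_into_j(p))
  }
})

test_that("summarize_pair assembles consistent metrics from fits", {
  p <- dry_params()
  tab <- simulate_seed_production(make_design(treatments = "dry"), p, seed = 3)
  bi <- bootstrap_fit(tab, "i", "dry", n_boot = 15, seed = 4)
  bj <- bootstrap_fit(tab, "j", "dry", n_boot = 15, seed = 5)
  s <- summarize_pair(bi, bj)
  m <- s$metrics
  expect_setequal(m$metric, c("niche_overlap", "niche_difference",
                              "demographic_ratio", "competitive_response_ratio",
                              "fitness_ratio", "igr_i_into_j", "igr_j_into_i"))
  val <- function(nm) m$value[m$metric == nm]
  expect_equal(val("fitness_ratio"),
               val("demographic_ratio") * val("competitive_response_ratio"))
  expect_equal(val("niche_difference"), 1 - val("niche_overlap"))
  expect_true(all(is.finite(m$se)))
  expect_identical(s$outcome,
                   classify_outcome(val("niche_overlap"), val("fitness_ratio")))
  # taylor SEs available from the same fits, same point values
  s2 <- summarize_pair(bi$fit, bj$fit, se_method = "taylor1", point = "full_data")
  expect_equal(s2$metrics$metric, m$metric)
  expect_true(all(is.finite(s2$metrics$se)))
  # mismatched treatments refuse to combine
  tabw <- simulate_seed_production(make_design(treatments = "wet"),
                                   wet_params(), seed = 6)
  fw <- fit_competition(tabw, "j", "wet")
  expect_error(summarize_pair(bi$fit, fw, se_method = "none"),
               "different treatments")
})
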