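test_that("twin correlations behave at the degenerate extremes", {
  v <- rnorm(50)
  zyg <- rep(c("MZ", "DZ"), 25)
  same <- twin_correlation(v, v, zyg)
  expect_equal(same$r_mz, 1)
  expect_equal(same$r_dz, 1)

  set.seed(3)
  indep <- twin_correlation(rnorm(20000), rnorm(20000), rep(c("MZ", "DZ"), 10000))
  expect_lt(abs(indep$r_mz), 0.03)
  expect_lt(abs(indep$r_dz), 0.03)

  const <- twin_correlation(rep(1, 10), rep(1, 10), rep(c("MZ", "DZ"), 5))
  expect_true(is.na(const$r_mz))
})

test_that("double-entry correlation is invariant to twin labelling", {
  set.seed(4)
  p <- simulate_pairs(300, 200, 0.5, 0.2)
  a <- twin_correlation(p$value1, p$value2, p$zygosity)
  b <- twin_correlation(p$value2, p$value1, p$zygosity)
  expect_equal(a$r_mz, b$r_mz)
  expect_equal(a$r_dz, b$r_dz)
})

test_that("generator-backed correlations land on the configured structure", {
  p <- simulate_pairs(20000, 20000, 0.43, 0.19, seed = 17)
  corr <- twin_correlation(p$value1, p$value2, p$zygosity)
  expect_lt(abs(corr$r_mz - 0.62), 0.02)
  expect_lt(abs(corr$r_dz - 0.405), 0.02)
})

test_that("interior ML solutions reproduce both group correlations exactly", {
  # saturated two-parameter model: at an interior optimum the expected MZ
  # and DZ correlations equal the observed ones, so a2 = 2(r_mz - r_dz)
  cases <- list(c(0.63, 0.42), c(0.71, 0.50), c(0.55, 0.31), c(0.5, 0.3))
  for (cs in cases) {
    fit <- fit_ace_continuous(twin_correlations(cs[1], cs[2], 218, 141), ci = FALSE)
    expect_equal(fit$a2, 2 * (cs[1] - cs[2]), tolerance = 1e-4)
    expect_equal(fit$c2, 2 * cs[2] - cs[1], tolerance = 1e-4)
    expect_equal(fit$a2 + fit$c2 + fit$e2, 1, tolerance = 1e-8)
  }
})

test_that("zero familial correlation gives a pure unique-environment fit", {
  fit <- fit_ace_continuous(twin_correlations(0, 0, 100, 100), ci = FALSE)
  expect_equal(fit$a2, 0)
  expect_equal(fit$c2, 0)
  expect_equal(fit$e2, 1)
})

test_that("r_mz below r_dz resolves to the a2 = 0 boundary, not an error", {
  fit <- fit_ace_continuous(twin_correlations(0.30, 0.45, 200, 200), ci = FALSE)
  expect_equal(fit$a2, 0)
  expect_gt(fit$c2, 0)
})

test_that("the ML point beats a fine grid over the (a2, c2) simplex", {
  corrs <- list(twin_correlations(0.63, 0.42, 218, 141),
                twin_correlations(0.58, 0.18, 218, 141),
                twin_correlations(0.47, 0.30, 201, 81))
  grid <- expand.grid(a2 = seq(0, 1, by = 0.01), c2 = seq(0, 1, by = 0.01))
  grid <- grid[grid$a2 + grid$c2 <= 1, ]
  for (corr in corrs) {
    fit <- fit_ace_continuous(corr, ci = FALSE)
    grid_dev <- mapply(ace_deviance, grid$a2, grid$c2,
                       MoreArgs = list(corr = corr))
    expect_lte(fit$minus2ll, min(grid_dev) + 1e-8)
  }
})

test_that("summary-correlation and raw-pair fits agree", {
  p <- simulate_pairs(400, 300, 0.5, 0.2, seed = 23)
  from_raw <- fit_ace_continuous(value1 = p$value1, value2 = p$value2,
                                 zygosity = p$zygosity, ci = FALSE)
  corr <- twin_correlation(p$value1, p$value2, p$zygosity)
  from_summary <- fit_ace_continuous(corr, ci = FALSE)
  expect_equal(from_raw$a2, from_summary$a2, tolerance = 1e-5)
  expect_equal(from_raw$c2, from_summary$c2, tolerance = 1e-5)
})

test_that("Falconer's formula approximates the interior ML heritability", {
  set.seed(29)
  for (i in 1:5) {
    a2 <- runif(1, 0.2, 0.5); c2 <- runif(1, 0.1, 0.3)
    p <- simulate_pairs(20000, 20000, a2, c2)
    corr <- twin_correlation(p$value1, p$value2, p$zygosity)
    fit <- fit_ace_continuous(corr, ci = FALSE)
    if (fit$c2 > 0 && fit$a2 > 0)
      expect_lt(abs(2 * (corr$r_mz - corr$r_dz) - fit$a2), 0.02)
  }
})

test_that("profile intervals bracket the estimate and truncate at boundaries", {
  fit <- fit_ace_continuous(twin_correlations(0.63, 0.42, 218, 141))
  expect_true(all(fit$ci95[, "lower"] <= c(fit$a2, fit$c2, fit$e2)))
  expect_true(all(fit$ci95[, "upper"] >= c(fit$a2, fit$c2, fit$e2)))
  # documentary agreement with the published male fasting-glucose interval
  expect_lt(abs(fit$ci95["a2", "lower"] - 0.19), 0.05)
  expect_lt(abs(fit$ci95["a2", "upper"] - 0.70), 0.05)

  boundary <- fit_ace_continuous(twin_correlations(0.58, 0.18, 218, 141))
  expect_identical(unname(boundary$ci95["c2", "lower"]), 0)
  expect_equal(boundary$c2, 0)
})

test_that("bisected CI endpoints agree with a fine deviance scan", {
  fit <- fit_ace_continuous(twin_correlations(0.63, 0.42, 218, 141))
  target <- fit$minus2ll + qchisq(0.95, 1)
  grid <- seq(0.001, 0.999, by = 0.001)
  prof <- vapply(grid, function(v) glycotwin:::profile_deviance(fit, "a2", v),
                 numeric(1))
  inside <- grid[prof <= target]
  expect_lt(abs(min(inside) - fit$ci95["a2", "lower"]), 0.005)
  expect_lt(abs(max(inside) - fit$ci95["a2", "upper"]), 0.005)
})

test_that("liability thresholds are upper-tail normal quantiles", {
  expect_equal(threshold_from_prevalence(0.5), 0)
  expect_equal(threshold_from_prevalence(0.282), 0.577, tolerance = 1e-3)
  expect_equal(threshold_from_prevalence(0.975), -1.96, tolerance = 1e-3)
  expect_error(threshold_from_prevalence(0), "inside")
  expect_error(threshold_from_prevalence(1.2), "inside")
})

test_that("tetrachoric correlation inverts the concordance map", {
  expect_equal(tetrachoric_from_concordance(0.282, 0.282), 0, tolerance = 1e-6)
  expect_gt(tetrachoric_from_concordance(0.9999, 0.282), 0.99)

  for (r in c(0, 0.2, 0.5, 0.8, 0.95)) {
    for (type in c("probandwise", "pairwise")) {
      conc <- concordance_from_liability(r, 0.282, type)
      back <- tetrachoric_from_concordance(conc, 0.282, type)
      expect_lt(abs(back - r), 1e-6)
    }
  }
  # round trip against the forward map at a published-style concordance
  r <- tetrachoric_from_concordance(0.667, 0.282)
  expect_equal(concordance_from_liability(r, 0.282), 0.667, tolerance = 1e-6)
})

test_that("sub-independence concordance hits the r = 0 boundary when forced", {
  expect_warning(r <- tetrachoric_from_concordance(0.10, 0.282, nonnegative = TRUE),
                 "independence")
  expect_equal(r, 0)
})

test_that("concordances equal to prevalence give a pure-environment fit", {
  fit <- fit_ace_liability(0.3, 0.3, prevalence = 0.3,
                           n_mz_pairs = 200, n_dz_pairs = 150, ci = FALSE)
  expect_equal(fit$a2, 0)
  expect_equal(fit$c2, 0)
  expect_equal(fit$e2, 1)
})

test_that("observed concordances are computed in both conventions", {
  a1 <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  a2 <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  zyg <- rep("MZ", 6)
  conc <- twin_concordance(a1, a2, zyg)
  # 2 concordant-affected pairs, 2 discordant: probandwise 4/6, pairwise 2/4
  expect_equal(conc$concordance[conc$zygosity == "MZ"], 4 / 6)
  concp <- twin_concordance(a1, a2, zyg, type = "pairwise")
  expect_equal(concp$concordance[concp$zygosity == "MZ"], 2 / 4)
})

test_that("nested model deviances are monotone and AIC flags the truth", {
  corr <- twin_correlations(0.63, 0.42, 218, 141)
  cmp <- compare_models(corr)
  dev <- setNames(cmp$minus2ll, cmp$model)
  expect_lte(dev[["ACE"]], dev[["AE"]] + 1e-8)
  expect_lte(dev[["ACE"]], dev[["CE"]] + 1e-8)
  expect_lte(dev[["AE"]], dev[["E"]] + 1e-8)
  expect_lte(dev[["CE"]], dev[["E"]] + 1e-8)
  expect_equal(sum(cmp$preferred), 1)

  # data generated without shared environment: AE wins AIC most of the time
  set.seed(41)
  wins <- vapply(1:100, function(i) {
    p <- simulate_pairs(500, 500, 0.5, 0)
    corr_i <- twin_correlation(p$value1, p$value2, p$zygosity)
    cmp_i <- compare_models(corr_i)
    cmp_i$model[cmp_i$preferred][1] == "AE"
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("boundary-mixture LRT p-values are super-uniform under the null", {
  set.seed(43)
  pvals <- vapply(1:200, function(i) {
    p <- simulate_pairs(400, 400, 0.4, 0)    # c2 truly zero
    corr_i <- twin_correlation(p$value1, p$value2, p$zygosity)
    cmp_i <- compare_models(corr_i)
    cmp_i$p_value[cmp_i$model == "AE"]
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  expect_lte(mean(pvals < 0.2), 0.2 + 3 * sqrt(0.2 * 0.8 / 200))
})

test_that("summary TSV tables drive both the continuous and liability fits", {
  corr_path <- system.file("extdata", "demo_twin_correlations.tsv",
                           package = "glycotwin")
  res <- fit_ace_table(corr_path)
  expect_equal(nrow(res), 6)
  expect_true(all(abs(res$a2 + res$c2 + res$e2 - 1) < 1e-8))
  male_fpg <- res[res$sex == "M" & res$trait == "fpg", ]
  expect_lt(abs(male_fpg$a2 - 0.43), 0.03)
  expect_lt(abs(male_fpg$e2 - 0.36), 0.03)
  expect_true(all(res$a2_lower <= res$a2 & res$a2 <= res$a2_upper))

  conc_path <- system.file("extdata", "demo_twin_concordances.tsv",
                           package = "glycotwin")
  lres <- fit_ace_table(conc_path)
  expect_equal(unique(lres$scale), "liability")
  male_ifg <- lres[lres$sex == "M" & lres$trait == "ifg", ]
  expect_lt(abs(male_ifg$a2 - 0.72), 0.05)
  expect_identical(male_ifg$c2, 0)

  expect_error(fit_ace_table(data.frame(trait = "x", r_mz = 0.5)), "n_mz")
})
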