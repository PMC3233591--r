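# clustered data with a known marginal mean structure: pair random effect
# with intra-pair correlation `icc`, gaussian or logistic outcome
simulate_clustered <- function(n_pairs, beta_t3 = 0, icc = 0.4,
                               family = "gaussian", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2 * n_pairs
  pair_id <- rep(sprintf("P%05d", seq_len(n_pairs)), each = 2)
  tertile <- factor(sample(c("T1", "T2", "T3"), n, replace = TRUE),
                    levels = c("T1", "T2", "T3"))
  x <- rnorm(n)
  u <- rep(rnorm(n_pairs, sd = sqrt(icc)), each = 2)
  eta <- 0.2 + beta_t3 * (tertile == "T3") + 0.1 * x
  if (family == "gaussian") {
    y <- eta + u + rnorm(n, sd = sqrt(1 - icc))
  } else {
    y <- rbinom(n, 1, plogis(eta + u))
  }
  data.frame(pair_id = pair_id, y = y, tertile = tertile, x = x)
}

test_that("GEE with size-1 clusters reduces to the independence fit", {
  set.seed(1)
  d <- data.frame(id = sprintf("S%03d", 1:80), y = rnorm(80), x = rnorm(80),
                  z = runif(80))
  fit <- gee_fit(y ~ x + z, d, id = "id")
  ols <- lm(y ~ x + z, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
})

test_that("robust variance matches the HC0 sandwich on independent clusters", {
  skip_if_not_installed("sandwich")
  set.seed(2)
  d <- data.frame(id = sprintf("S%03d", 1:150), x = rnorm(150))
  d$y <- rbinom(150, 1, plogis(-0.3 + 0.8 * d$x))
  fit <- gee_fit(y ~ x, d, id = "id", family = stats::binomial())
  ref <- glm(y ~ x, data = d, family = binomial())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(diag(vcov(fit))),
               unname(diag(sandwich::vcovHC(ref, type = "HC0"))),
               tolerance = 1e-4)
})

test_that("a known tertile effect is recovered within robust error", {
  d <- simulate_clustered(1000, beta_t3 = 0.10, seed = 33)
  res <- fit_clustered(d, "y", "tertile", covariates = "x")
  t3 <- res[res$term == "T3", ]
  expect_lt(abs(t3$estimate - 0.10), 3 * t3$robust_se)
  expect_true(t3$conf.low <= t3$estimate && t3$estimate <= t3$conf.high)
})

test_that("logistic fits report positive odds ratios with covering intervals", {
  d <- simulate_clustered(800, beta_t3 = 0.6, family = "binomial", seed = 44)
  res <- fit_clustered(d, "y", "tertile", covariates = "x", family = "binomial")
  expect_true(all(res$odds_ratio > 0))
  expect_true(all(res$conf.low <= res$odds_ratio &
                    res$odds_ratio <= res$conf.high))
  expect_gt(res$odds_ratio[res$term == "T3"], 1)
})

test_that("estimates are invariant to row shuffling", {
  d <- simulate_clustered(300, beta_t3 = 0.3, seed = 55)
  fit1 <- gee_fit(y ~ tertile + x, d, id = "pair_id")
  d2 <- d[sample(nrow(d)), ]
  fit2 <- gee_fit(y ~ tertile + x, d2, id = "pair_id")
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-9)
  expect_equal(vcov(fit1), vcov(fit2), tolerance = 1e-9)
})

test_that("a singular design names the collinear column", {
  d <- simulate_clustered(50, seed = 66)
  d$x2 <- 2 * d$x
  expect_error(gee_fit(y ~ x + x2, d, id = "pair_id"), "x2")
})

test_that("trend p-value is symmetric under reversed coding and powered", {
  d <- simulate_clustered(600, beta_t3 = 0.3, seed = 77)
  fwd <- trend_test(d, "y", "tertile", covariates = "x")
  d$rev <- factor(c(T1 = "T3", T2 = "T2", T3 = "T1")[as.character(d$tertile)],
                  levels = c("T1", "T2", "T3"))
  rev <- trend_test(d, "y", "rev", covariates = "x")
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-8)
  expect_equal(fwd$estimate, -rev$estimate, tolerance = 1e-8)

  strong <- simulate_clustered(2000, beta_t3 = 0.5, seed = 78)
  expect_lt(trend_test(strong, "y", "tertile", covariates = "x")$p_value, 1e-6)
})

test_that("sex interaction test requires both sexes and detects differences", {
  track_cohort <- function(n_pairs, r_m, r_f, seed) {
    set.seed(seed)
    sex <- rep(rep(c("M", "F"), each = 2), length.out = 2 * n_pairs)
    pair_id <- rep(sprintf("P%04d", seq_len(n_pairs)), each = 2)
    b <- rnorm(2 * n_pairs)
    r <- ifelse(sex == "M", r_m, r_f)
    f <- r * b + sqrt(1 - r^2) * rnorm(2 * n_pairs)
    data.frame(pair_id = pair_id, sex = sex, base = b, fol = f)
  }
  single <- track_cohort(50, 0.5, 0.5, 1)
  single$sex <- "M"
  expect_error(sex_interaction_test(single, "base", "fol"), "single-sex")

  hits <- vapply(1:25, function(i) {
    d <- track_cohort(800, 0.4, 0.7, seed = 100 + i)
    sex_interaction_test(d, "base", "fol")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
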