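test_that("nine distinct values in one stratum split three per tertile", {
  res <- assign_tertiles(values = c(4.1, 4.2, 4.3, 4.4, 4.5, 4.6, 4.7, 4.8, 4.9),
                         sex = rep("M", 9), age = rep(10, 9))
  expect_equal(as.vector(table(res$tertile)), c(3, 3, 3))
  expect_equal(as.character(res$tertile[order(c(4.1, 4.2, 4.3, 4.4, 4.5, 4.6,
                                                4.7, 4.8, 4.9))]),
               rep(c("T1", "T2", "T3"), each = 3))
})

test_that("tied values never straddle a tertile cut-point", {
  set.seed(14)
  vals <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  for (perm in list(seq_along(vals), rev(seq_along(vals)),
                    sample(seq_along(vals)))) {
    res <- assign_tertiles(vals[perm], rep("F", 9), rep(12, 9))
    lab <- tapply(as.character(res$tertile), vals[perm], unique)
    expect_true(all(lengths(lab) == 1))       # each value maps to one tertile
    expect_equal(as.vector(unlist(lab)), c("T1", "T2", "T3"))
  }
})

test_that("strata are ranked independently", {
  young <- c(4.0, 4.1, 4.2, 4.3, 4.4, 4.5)
  old <- young + 5                     # disjoint range
  res <- assign_tertiles(c(young, old), rep("M", 12),
                         c(rep(8, 6), rep(16, 6)))
  expect_equal(as.character(res$tertile[1:6]), as.character(res$tertile[7:12]))
  # a value that is T3 among the young is T1 among the old
  mixed <- assign_tertiles(c(young, 4.5, old[-1]), rep("M", 12),
                           c(rep(8, 6), rep(16, 6)))
  expect_equal(as.character(mixed$tertile[7]), "T1")
})

test_that("undersized strata merge into the nearest age bin with a warning", {
  expect_warning(
    res <- assign_tertiles(c(1:9, 10.5), rep("M", 10), c(rep(8, 9), 14)),
    "merged")
  expect_false(any(is.na(res$tertile)))
})

test_that("identical rankings give an identity transition and persistence 1", {
  base <- data.frame(subject_id = 1:9,
                     tertile = rep(c("T1", "T2", "T3"), each = 3))
  tm <- transition_matrix(base, base)
  expect_equal(unname(tm$proportions), diag(3))
  expect_equal(tm$persistence, 1)
  expect_equal(sum(tm$counts), 9)
})

test_that("independent rankings give uniform rows and persistence 2/3", {
  set.seed(5)
  n <- 30000
  base <- assign_tertiles(rnorm(n), rep("M", n), rep(10, n))
  fol <- assign_tertiles(rnorm(n), rep("M", n), rep(16, n))
  tm <- transition_matrix(data.frame(subject_id = 1:n, tertile = base$tertile),
                          data.frame(subject_id = 1:n, tertile = fol$tertile))
  expect_true(all(abs(tm$proportions - 1 / 3) < 0.02))
  expect_lt(abs(tm$persistence - 2 / 3), 0.02)
  expect_true(all(abs(rowSums(tm$proportions) - 1) < 1e-12))
})

test_that("subjects seen at one visit only are excluded and tallied", {
  base <- data.frame(subject_id = 1:9,
                     tertile = rep(c("T1", "T2", "T3"), each = 3))
  fol <- base[1:6, ]
  tm <- transition_matrix(base, fol)
  expect_equal(tm$n, 6)
  expect_equal(tm$n_excluded, 3)
  expect_equal(sum(tm$counts), 6)
})

test_that("persistence increases with the tracking correlation", {
  persistence_at <- function(r, seed) {
    set.seed(seed)
    n <- 4000
    b <- rnorm(n)
    f <- r * b + sqrt(1 - r^2) * rnorm(n)
    bt <- assign_tertiles(b, rep("M", n), rep(10, n))
    ft <- assign_tertiles(f, rep("M", n), rep(16, n))
    transition_matrix(data.frame(subject_id = 1:n, tertile = bt$tertile),
                      data.frame(subject_id = 1:n, tertile = ft$tertile))$persistence
  }
  p <- vapply(c(0.2, 0.5, 0.8), persistence_at, numeric(1), seed = 99)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 2 / 3) && all(p < 1))
})

test_that("persistence is invariant under monotone transforms of the trait", {
  set.seed(21)
  n <- 600
  b <- rnorm(n); f <- 0.6 * b + 0.8 * rnorm(n)
  persist <- function(bv, fv) {
    bt <- assign_tertiles(bv, rep("M", n), rep(10, n))
    ft <- assign_tertiles(fv, rep("M", n), rep(16, n))
    transition_matrix(data.frame(subject_id = 1:n, tertile = bt$tertile),
                      data.frame(subject_id = 1:n, tertile = ft$tertile))$persistence
  }
  expect_equal(persist(b, f), persist(exp(b), f^3 + 2 * f))
})

test_that("incidence is zero when nobody develops prediabetes", {
  n <- 30
  res <- incidence_by_tertile(rep(TRUE, n),
                              rep(c("T1", "T2", "T3"), each = 10),
                              rep(FALSE, n), rep("M", n))
  expect_equal(res$incidence, rep(0, 3))
  expect_equal(res$n, rep(10L, 3))
})

test_that("an empty tertile yields NA incidence with a warning", {
  expect_warning(
    res <- incidence_by_tertile(rep(TRUE, 6), rep(c("T1", "T2"), each = 3),
                                rep(FALSE, 6), rep("F", 6)),
    "tertile T3")
  expect_true(is.na(res$incidence[res$tertile == "T3"]))
})

test_that("tracked cohorts show rising incidence across baseline tertiles", {
  set.seed(31)
  n <- 20000
  b <- rnorm(n)
  f <- 0.6 * b + 0.8 * rnorm(n)
  thr <- qnorm(0.28, lower.tail = FALSE)    # ~28% incident threshold trait
  bt <- assign_tertiles(b, rep("M", n), rep(10, n))
  res <- incidence_by_tertile(rep(TRUE, n), bt$tertile, f > thr, rep("M", n))
  expect_true(all(diff(res$incidence[order(res$tertile)]) > 0))
})

test_that("the smoother is exact on constant and linear data", {
  x <- seq(1, 10, length.out = 40)
  const <- loess_track(x, rep(5.5, 40), rep("T1", 40))
  expect_true(all(abs(const$fitted - 5.5) < 1e-8))
  lin <- loess_track(x, 2 * x, rep("T1", 40))
  inner <- lin$x > 2 & lin$x < 9
  expect_true(all(abs(lin$fitted[inner] - 2 * lin$x[inner]) < 1e-6))
})

test_that("the smoother matches an independent local-regression oracle", {
  set.seed(8)
  n <- 120
  x <- sort(runif(n, 12, 28))
  y <- sin(x / 3) + rnorm(n, sd = 0.2)
  res <- loess_track(x, y, rep("T2", n), span = 0.5, n_grid = 25)
  oracle <- local_linear_oracle(x, y, res$x, span = 0.5)
  expect_lt(max(abs(res$fitted - oracle)), 1e-3)
})

test_that("degenerate smoother inputs are rejected", {
  expect_error(loess_track(rep(5, 12), rnorm(12), rep("T1", 12)), "degenerate")
  expect_error(loess_track(1:5, rnorm(5), rep("T1", 5)), "at least 10")
})
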