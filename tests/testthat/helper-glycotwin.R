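# shared fixtures: everything is generated in code at test time

quick_config <- function(...) {
  simulation_config(n_mz_pairs = 60, n_dz_pairs = 40, seed = 42L, ...)
}

# (value1, value2, zygosity) for one trait at one visit, pair-wise
pair_trait <- function(cohort, trait, visit = "followup") {
  d <- cohort[cohort$visit == visit, c("pair_id", "zygosity", trait)]
  d <- d[order(d$pair_id), ]
  first <- !duplicated(d$pair_id)
  list(value1 = d[[trait]][first], value2 = d[[trait]][!first],
       zygosity = d$zygosity[first])
}

# fast latent-scale twin-pair simulator used where only the correlation
# structure matters (no covariates, single trait, one visit)
simulate_pairs <- function(n_mz, n_dz, a2, c2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n, rho) {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    cbind(z1, z2)
  }
  mz <- draw(n_mz, a2 + c2)
  dz <- draw(n_dz, a2 / 2 + c2)
  list(value1 = c(mz[, 1], dz[, 1]), value2 = c(mz[, 2], dz[, 2]),
       zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)))
}

# independent local-regression oracle: tricube-weighted local linear fit
# with the nearest-neighbour bandwidth q = floor(n * span)
local_linear_oracle <- function(x, y, x0, span) {
  n <- length(x)
  q <- floor(n * span)
  vapply(x0, function(x0i) {
    d <- abs(x - x0i)
    h <- sort(d)[q]
    w <- pmax(1 - (d / h)^3, 0)^3
    X <- cbind(1, x - x0i)
    drop(solve(crossprod(X, w * X), crossprod(X, w * y)))[1]
  }, numeric(1))
}
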