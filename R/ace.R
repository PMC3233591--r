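#' Twin intraclass correlations by zygosity
#'
#' Double-entry Pearson correlation of a trait within twin pairs,
#' computed separately for monozygotic and dizygotic pairs: each pair is
#' entered in both orders, which makes the estimate invariant to the
#' arbitrary labelling of twin 1 and twin 2.
#'
#' @param value1,value2 trait values for the two members of each pair.
#' @param zygosity `"MZ"`/`"DZ"` per pair.
#' @return an object of class `twin_correlations`: list with `r_mz`,
#'   `r_dz`, `n_mz_pairs`, `n_dz_pairs`. A zero-variance group yields
#'   `NA` for its correlation.
#' @export
twin_correlation <- function(value1, value2, zygosity) {
  stopifnot(length(value1) == length(value2), length(value2) == length(zygosity))
  keep <- is.finite(value1) & is.finite(value2)
  r <- n <- c(MZ = NA_real_, DZ = NA_real_)
  for (zyg in c("MZ", "DZ")) {
    idx <- keep & zygosity == zyg
    n[zyg] <- sum(idx)
    if (n[zyg] < 2) next
    x <- c(value1[idx], value2[idx])
    y <- c(value2[idx], value1[idx])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next   # undefined: zero variance
    r[zyg] <- stats::cor(x, y)
  }
  twin_correlations(r[["MZ"]], r[["DZ"]], n[["MZ"]], n[["DZ"]])
}

#' Construct a `twin_correlations` summary
#'
#' @param r_mz,r_dz intraclass correlations per zygosity.
#' @param n_mz_pairs,n_dz_pairs pair counts per zygosity.
#' @return an object of class `twin_correlations`.
#' @export
twin_correlations <- function(r_mz, r_dz, n_mz_pairs, n_dz_pairs) {
  stopifnot(n_mz_pairs >= 2 || is.na(r_mz), n_dz_pairs >= 2 || is.na(r_dz))
  structure(list(r_mz = r_mz, r_dz = r_dz,
                 n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs)),
            class = "twin_correlations")
}

#' Two-group ACE deviance on standardized pair data
#'
#' The Wishart deviance of the classical twin model on standardized
#' phenotypes. The expected pair covariance matrix has unit diagonal and
#' off-diagonal `a2 + c2` for MZ pairs and `a2/2 + c2` for DZ pairs; each
#' zygosity group contributes `n * (log det Sigma + trace(S Sigma^-1))`
#' where `S` is the observed pair correlation matrix. For 2x2 matrices
#' this reduces to a closed form in the observed and expected
#' correlations.
#'
#' @param a2,c2 additive-genetic and shared-environment variance
#'   proportions (`e2 = 1 - a2 - c2`).
#' @param corr a `twin_correlations` object.
#' @return the deviance (-2 log-likelihood up to a data-only constant);
#'   `Inf` outside the admissible region (`a2, c2 >= 0`, `a2 + c2 <= 1`).
#' @export
ace_deviance <- function(a2, c2, corr) {
  if (a2 < -1e-12 || c2 < -1e-12 || a2 + c2 > 1 + 1e-12) return(Inf)
  dev_group <- function(rho, r, n) {
    rho <- min(rho, 1 - 1e-12)
    n * (log(1 - rho^2) + 2 * (1 - rho * r) / (1 - rho^2))
  }
  dev_group(a2 + c2, corr$r_mz, corr$n_mz_pairs) +
    dev_group(a2 / 2 + c2, corr$r_dz, corr$n_dz_pairs)
}

ace_start_points <- list(c(0.3, 0.3), c(0.6, 0.1), c(0.1, 0.6),
                         c(0.05, 0.05), c(0.8, 0.05))

# bounded quasi-Newton ACE optimization with multi-start; `fixed` pins
# components for the nested submodels (AE: c2 = 0; CE: a2 = 0; E: both)
ace_optimize <- function(corr, fixed = c(a2 = NA, c2 = NA)) {
  obj2 <- function(p) {
    v <- ace_deviance(p[1], p[2], corr)
    if (!is.finite(v)) 1e10 else v
  }
  free <- is.na(fixed)
  if (!any(free)) {
    par <- ifelse(free, 0, fixed)
    return(list(par = unname(par), value = obj2(ifelse(free, 0, fixed)),
                convergence = 0L))
  }
  best <- NULL
  for (s in ace_start_points) {
    p0 <- ifelse(free, s, fixed)
    if (sum(free) == 2) {
      o <- stats::optim(p0, obj2, method = "L-BFGS-B",
                        lower = c(0, 0), upper = c(1, 1),
                        control = list(factr = 1e4))
      par <- o$par
    } else {
      f1 <- function(x) { p <- fixed; p[free] <- x; obj2(p) }
      o <- stats::optimize(f1, c(0, 1), tol = 1e-10)
      par <- fixed; par[free] <- o$minimum
      o <- list(value = o$objective, convergence = 0L)
    }
    if (is.null(best) || o$value < best$value)
      best <- list(par = unname(par), value = o$value, convergence = o$convergence)
  }
  # polish: coordinate refinement around the incumbent, kept inside the
  # feasible simplex and only accepted when it improves the deviance
  if (sum(free) == 2) {
    for (rep in 1:2) {
      a <- stats::optimize(function(x) obj2(c(x, best$par[2])),
                           c(0, 1 - best$par[2]), tol = 1e-12)
      if (a$objective < best$value) {
        best$par[1] <- a$minimum; best$value <- a$objective
      }
      cc <- stats::optimize(function(x) obj2(c(best$par[1], x)),
                            c(0, 1 - best$par[1]), tol = 1e-12)
      if (cc$objective < best$value) {
        best$par[2] <- cc$minimum; best$value <- cc$objective
      }
    }
  }
  # snap boundary solutions
  best$par[best$par < 1e-6] <- 0
  best$value <- obj2(best$par)
  best
}

#' Maximum-likelihood ACE decomposition for a continuous trait
#'
#' Decomposes the phenotypic variance of a standardized trait into
#' additive-genetic (a2), shared-environment (c2) and unique-environment
#' (e2) proportions by maximizing the two-group likelihood over the
#' observed MZ and DZ twin-pair correlations, with `a2, c2 >= 0` and
#' `a2 + c2 + e2 = 1`. When the MZ correlation falls below the DZ
#' correlation the additive component is returned at its boundary of 0
#' rather than failing. 95% profile-likelihood confidence intervals are
#' computed for each component (see [profile_ci()]).
#'
#' @param corr a `twin_correlations` object, or `NULL` when raw pair data
#'   are supplied.
#' @param value1,value2,zygosity raw pair data (standardized internally
#'   via the double-entry correlation), used when `corr` is `NULL`.
#' @param model `"ACE"` (default) or a nested submodel: `"AE"` (c2 = 0),
#'   `"CE"` (a2 = 0), `"E"` (a2 = c2 = 0).
#' @param ci whether to compute profile-likelihood intervals.
#' @return an object of class `ace_fit`: list with `a2`, `c2`, `e2`,
#'   `ci95` (3x2 matrix, rows a2/c2/e2), `minus2ll`, `model`, `corr`,
#'   `converged`, `n_free`.
#' @examples
#' fit_ace_continuous(twin_correlations(0.63, 0.42, 218, 141))
#' @export
fit_ace_continuous <- function(corr = NULL, value1 = NULL, value2 = NULL,
                               zygosity = NULL,
                               model = c("ACE", "AE", "CE", "E"), ci = TRUE) {
  model <- match.arg(model)
  if (is.null(corr))
    corr <- twin_correlation(value1, value2, zygosity)
  if (!inherits(corr, "twin_correlations"))
    stop("corr must be a twin_correlations object", call. = FALSE)
  if (!is.finite(corr$r_mz) || !is.finite(corr$r_dz))
    stop("both zygosity correlations must be available", call. = FALSE)

  fixed <- switch(model,
                  ACE = c(a2 = NA, c2 = NA),
                  AE  = c(a2 = NA, c2 = 0),
                  CE  = c(a2 = 0, c2 = NA),
                  E   = c(a2 = 0, c2 = 0))
  opt <- ace_optimize(corr, fixed)
  a2 <- opt$par[1]; c2 <- opt$par[2]
  fit <- structure(list(a2 = a2, c2 = c2, e2 = 1 - a2 - c2,
                        ci95 = NULL, minus2ll = opt$value, model = model,
                        corr = corr, converged = opt$convergence == 0L,
                        n_free = sum(is.na(fixed))),
                   class = "ace_fit")
  if (ci) {
    fit$ci95 <- rbind(a2 = profile_ci(fit, "a2"),
                      c2 = profile_ci(fit, "c2"),
                      e2 = profile_ci(fit, "e2"))
    colnames(fit$ci95) <- c("lower", "upper")
  }
  fit
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(x$model, "fit: a2 =", round(x$a2, 3), " c2 =", round(x$c2, 3),
      " e2 =", round(x$e2, 3), "\n")
  if (!is.null(x$ci95)) {
    ci <- round(x$ci95, 3)
    for (k in rownames(ci))
      cat(sprintf("  %s 95%% CI (%.2f, %.2f)\n", k, ci[k, 1], ci[k, 2]))
  }
  cat("  -2logL =", round(x$minus2ll, 3), " (r_MZ =", round(x$corr$r_mz, 3),
      ", r_DZ =", round(x$corr$r_dz, 3), ")\n")
  invisible(x)
}

# deviance profiled over one component of the ACE fit
profile_deviance <- function(fit, component, value) {
  corr <- fit$corr
  switch(component,
    a2 = stats::optimize(function(c2) ace_deviance(value, c2, corr),
                         c(0, 1 - value), tol = 1e-10)$objective,
    c2 = stats::optimize(function(a2) ace_deviance(a2, value, corr),
                         c(0, 1 - value), tol = 1e-10)$objective,
    e2 = stats::optimize(function(a2) ace_deviance(a2, 1 - value - a2, corr),
                         c(0, 1 - value), tol = 1e-10)$objective,
    stop("component must be a2, c2 or e2", call. = FALSE))
}

#' Profile-likelihood confidence interval for an ACE component
#'
#' Finds the component values at which the profiled deviance (minimized
#' over the remaining free component) rises `qchisq(level, 1)` above its
#' minimum, by bisection. Intervals are truncated to the admissible
#' \[0, 1\] range, so a component estimated on its boundary reports an
#' endpoint of exactly 0 (or 1). A flat profile yields the admissible
#' bounds with a warning.
#'
#' @param fit an `ace_fit` from [fit_ace_continuous()].
#' @param component `"a2"`, `"c2"` or `"e2"`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
profile_ci <- function(fit, component = c("a2", "c2", "e2"), level = 0.95) {
  component <- match.arg(component)
  crit <- stats::qchisq(level, df = 1)
  hat <- fit[[component]]
  target <- fit$minus2ll + crit
  f <- function(v) profile_deviance(fit, component, v) - target

  eps <- 1e-9
  lower <- if (hat <= eps || f(eps) < 0) 0 else
    stats::uniroot(f, c(eps, hat), tol = 1e-8)$root
  upper <- if (hat >= 1 - eps || f(1 - eps) < 0) 1 else
    stats::uniroot(f, c(hat, 1 - eps), tol = 1e-8)$root
  if (lower == 0 && upper == 1 && f(eps) < 0 && f(1 - eps) < 0)
    warning("flat likelihood: ", component,
            " interval spans the admissible range", call. = FALSE)
  c(max(lower, 0), min(upper, 1))
}

#' Compare nested twin variance-component models
#'
#' Fits the ACE model and its nested submodels (AE, CE, E) to the same
#' twin correlations, and reports likelihood-ratio tests against ACE and
#' AIC. Dropping a single variance component tests a parameter on the
#' boundary of its space, so those p-values use the 50:50 mixture of a
#' point mass at zero and a chi-square with 1 df; dropping both (E vs
#' ACE) uses the corresponding two-component boundary mixture.
#'
#' @param corr a `twin_correlations` object.
#' @return a tibble with one row per model: `model`, `a2`, `c2`, `e2`,
#'   `minus2ll`, `df`, `lrt_vs_ace`, `p_value`, `aic`, `preferred`
#'   (minimum AIC).
#' @export
compare_models <- function(corr) {
  models <- c("ACE", "AE", "CE", "E")
  fits <- lapply(models, function(m) fit_ace_continuous(corr, model = m, ci = FALSE))
  names(fits) <- models
  dev <- vapply(fits, function(f) f$minus2ll, numeric(1))
  k <- vapply(fits, function(f) f$n_free, numeric(1))
  lrt <- dev - dev[["ACE"]]
  pval <- c(ACE = NA_real_,
            AE = boundary_mixture_p(lrt[["AE"]], 1),
            CE = boundary_mixture_p(lrt[["CE"]], 1),
            E  = boundary_mixture_p(lrt[["E"]], 2))
  aic <- dev + 2 * k
  tibble::tibble(model = models,
                 a2 = vapply(fits, `[[`, numeric(1), "a2"),
                 c2 = vapply(fits, `[[`, numeric(1), "c2"),
                 e2 = vapply(fits, `[[`, numeric(1), "e2"),
                 minus2ll = unname(dev), df = unname(k),
                 lrt_vs_ace = unname(lrt), p_value = unname(pval),
                 aic = unname(aic),
                 preferred = aic == min(aic))
}

# p-value for a likelihood-ratio statistic with `k` variance components on
# the boundary: mixture sum_{j=0..k} choose(k,j) 2^-k chi2_j
boundary_mixture_p <- function(stat, k) {
  if (stat <= 0) return(1)
  j <- seq_len(k)                       # the chi2_0 term has zero tail mass
  w <- choose(k, j) / 2^k
  sum(w * stats::pchisq(stat, df = j, lower.tail = FALSE))
}
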