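#' Generalized estimating equations for twin-pair clusters
#'
#' Fits a marginal regression model by generalized estimating equations
#' with an exchangeable working correlation and robust (sandwich)
#' standard errors. Tailored to the twin design: clusters are pairs, so
#' sizes are 1 or 2 and all cluster algebra uses closed-form 2x2
#' inverses. Gaussian-identity and binomial-logit families are supported.
#'
#' The working correlation is estimated by the usual moment estimator on
#' Pearson residuals; with clusters of size at most two the exchangeable
#' structure is saturated, so no generality is lost relative to an
#' unstructured working correlation.
#'
#' @param formula model formula.
#' @param data data frame.
#' @param id name of the cluster (pair) column in `data`.
#' @param family `stats::gaussian()` or `stats::binomial()` (identity and
#'   logit links).
#' @param maxit,tol iteration control.
#' @return an object of class `gee_fit` with elements `coefficients`,
#'   `vcov_robust`, `vcov_naive`, `alpha` (working correlation), `phi`
#'   (dispersion), `n_clusters`, `converged`, `family`, `formula`.
#' @export
gee_fit <- function(formula, data, id, family = stats::gaussian(),
                    maxit = 100, tol = 1e-10) {
  if (is.character(family)) family <- get(family, mode = "function")()
  if (is.function(family)) family <- family()
  if (!family$family %in% c("gaussian", "binomial"))
    stop("only gaussian and binomial families are supported", call. = FALSE)

  vars <- unique(c(all.vars(formula), id))
  data <- data[stats::complete.cases(data[vars]), , drop = FALSE]
  cl <- as.character(data[[id]])
  ord <- order(cl)
  data <- data[ord, , drop = FALSE]; cl <- cl[ord]

  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.numeric(y) - 1
  y <- as.numeric(y)
  X <- stats::model.matrix(formula, mf)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  sizes <- table(cl)[unique(cl)]
  if (any(sizes > 2))
    stop("cluster sizes above 2 are not supported (twin-pair design)", call. = FALSE)

  # index rows of size-1 clusters and the (first, second) rows of pairs
  first <- !duplicated(cl)
  pair_first <- which(first & cl %in% names(sizes)[sizes == 2])
  singles <- which(first & cl %in% names(sizes)[sizes == 1])
  i1 <- pair_first; i2 <- pair_first + 1L
  p <- ncol(X); n <- length(y)

  beta <- stats::glm.fit(X, y, family = family)$coefficients
  converged <- FALSE
  alpha <- 0; phi <- 1
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- family$linkinv(eta)
    dmu <- family$mu.eta(eta)
    A <- family$variance(mu)
    e <- (y - mu) / sqrt(A)                       # Pearson residuals
    phi <- sum(e^2) / (n - p)
    if (length(i1) > 0) {
      alpha <- sum(e[i1] * e[i2]) / (max(length(i1) - p, 1) * phi)
      alpha <- max(min(alpha, 0.999), -0.999)
    }
    u <- dmu / sqrt(A)

    H <- matrix(0, p, p); U <- numeric(p)
    if (length(singles) > 0) {
      Xs <- X[singles, , drop = FALSE] * u[singles]
      H <- H + crossprod(Xs) / phi
      U <- U + colSums(Xs * e[singles]) / phi
    }
    if (length(i1) > 0) {
      X1 <- X[i1, , drop = FALSE] * u[i1]
      X2 <- X[i2, , drop = FALSE] * u[i2]
      k <- 1 / (phi * (1 - alpha^2))
      H <- H + k * (crossprod(X1) + crossprod(X2) -
                      alpha * (crossprod(X1, X2) + crossprod(X2, X1)))
      U <- U + k * colSums(X1 * (e[i1] - alpha * e[i2]) +
                             X2 * (e[i2] - alpha * e[i1]))
    }
    step <- solve(H, U)
    beta <- beta + step
    if (sqrt(sum(step^2)) < tol * (sqrt(sum(beta^2)) + tol)) { converged <- TRUE; break }
  }

  eta <- drop(X %*% beta)
  if (family$family == "binomial" && any(abs(eta) > 30))
    warning("fitted probabilities numerically 0 or 1: possible separation",
            call. = FALSE)
  if (!converged)
    warning(sprintf("GEE did not converge in %d iterations (last step norm %.3g)",
                    maxit, sqrt(sum(step^2))), call. = FALSE)

  mu <- family$linkinv(eta); dmu <- family$mu.eta(eta)
  A <- family$variance(mu); e <- (y - mu) / sqrt(A); u <- dmu / sqrt(A)
  G <- matrix(0, 0, p)
  if (length(singles) > 0)
    G <- rbind(G, X[singles, , drop = FALSE] * (u[singles] * e[singles]) / phi)
  if (length(i1) > 0) {
    k <- 1 / (phi * (1 - alpha^2))
    G <- rbind(G, k * (X[i1, , drop = FALSE] * (u[i1] * (e[i1] - alpha * e[i2])) +
                         X[i2, , drop = FALSE] * (u[i2] * (e[i2] - alpha * e[i1]))))
  }
  Hi <- solve(H)
  vcov_robust <- Hi %*% crossprod(G) %*% Hi
  dimnames(vcov_robust) <- list(colnames(X), colnames(X))

  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 vcov_robust = vcov_robust, vcov_naive = Hi,
                 alpha = alpha, phi = phi,
                 n_clusters = length(sizes), n = n,
                 converged = converged, family = family$family,
                 formula = formula),
            class = "gee_fit")
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov_robust

#' @export
print.gee_fit <- function(x, ...) {
  cat("GEE (", x$family, ", exchangeable, ", x$n_clusters, " clusters, alpha = ",
      round(x$alpha, 3), ")\n", sep = "")
  print(summary(x))
  invisible(x)
}

#' @export
summary.gee_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov_robust))
  z <- object$coefficients / se
  tibble::tibble(term = names(object$coefficients),
                 estimate = unname(object$coefficients),
                 robust_se = unname(se), z = unname(z),
                 p_value = 2 * stats::pnorm(-abs(unname(z))))
}

prepare_regression_data <- function(data, outcome, exposure, covariates, cluster) {
  needed <- c(outcome, exposure, covariates, cluster)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  d <- data[needed]
  if ("activity" %in% covariates) {
    # keep unknown activity as its own level rather than dropping subjects
    a <- as.character(d$activity)
    a[is.na(a)] <- "N/A"
    d$activity <- factor(a, levels = c("low", "moderate", "high", "N/A"))
  }
  if ("smoking" %in% covariates) d$smoking <- as.logical(d$smoking)
  d
}

#' Pair-clustered tertile regression
#'
#' Regresses a follow-up outcome on baseline tertile (T1 reference) with
#' covariate adjustment, clustering on twin pair via [gee_fit()].
#' Gaussian outcomes report coefficients in outcome units; binary
#' outcomes use a logistic link and report odds ratios.
#'
#' @param data subject-level table: one row per subject with the outcome,
#'   the baseline tertile, the covariates and the pair id.
#' @param outcome name of the outcome column.
#' @param exposure name of the tertile factor column (levels T1, T2, T3).
#' @param covariates adjustment columns (default the full set: age,
#'   Tanner stage, smoking, BMI, activity).
#' @param family `"gaussian"` or `"binomial"`.
#' @param cluster name of the pair-id column.
#' @return a tibble with one row per non-reference tertile: `term`,
#'   `estimate` (beta, or odds ratio for binomial), `robust_se` (on the
#'   link scale), `conf.low`, `conf.high`, `p_value`. The underlying
#'   `gee_fit` is attached as attribute `fit`.
#' @export
fit_clustered <- function(data, outcome, exposure,
                          covariates = c("age", "tanner", "smoking", "bmi", "activity"),
                          family = c("gaussian", "binomial"),
                          cluster = "pair_id") {
  family <- match.arg(family)
  d <- prepare_regression_data(data, outcome, exposure, covariates, cluster)
  d[[exposure]] <- factor(as.character(d[[exposure]]), levels = c("T1", "T2", "T3"))
  fml <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- gee_fit(fml, d, id = cluster, family = family)
  res <- summary(fit)
  res <- res[grepl(paste0("^", exposure), res$term), ]
  res$term <- sub(paste0("^", exposure), "", res$term)
  zc <- stats::qnorm(0.975)
  res$conf.low <- res$estimate - zc * res$robust_se
  res$conf.high <- res$estimate + zc * res$robust_se
  if (family == "binomial") {
    res$estimate <- exp(res$estimate)
    res$conf.low <- exp(res$conf.low)
    res$conf.high <- exp(res$conf.high)
    names(res)[names(res) == "estimate"] <- "odds_ratio"
  }
  res$z <- NULL
  attr(res, "fit") <- fit
  res
}

#' Trend test across ordered tertiles
#'
#' Wald test of the exposure coefficient with tertile entered as an
#' ordinal score (T1 = 1, T2 = 2, T3 = 3), pair-clustered with robust
#' standard errors — the usual "P trend".
#'
#' @inheritParams fit_clustered
#' @return a one-row tibble: `estimate`, `robust_se`, `p_value`.
#' @export
trend_test <- function(data, outcome, exposure,
                       covariates = c("age", "tanner", "smoking", "bmi", "activity"),
                       family = c("gaussian", "binomial"),
                       cluster = "pair_id") {
  family <- match.arg(family)
  d <- prepare_regression_data(data, outcome, exposure, covariates, cluster)
  d$.score <- as.numeric(factor(as.character(d[[exposure]]),
                                levels = c("T1", "T2", "T3")))
  fml <- stats::reformulate(c(".score", covariates), response = outcome)
  fit <- gee_fit(fml, d, id = cluster, family = family)
  res <- summary(fit)
  res <- res[res$term == ".score", c("estimate", "robust_se", "p_value")]
  attr(res, "fit") <- fit
  res
}

#' Sex-difference test for tracking strength
#'
#' Tests whether a baseline value predicts its follow-up value more
#' strongly in one sex than the other: a pair-clustered model of the
#' follow-up value on baseline value, sex, and their interaction, with a
#' robust Wald test on the interaction term.
#'
#' @param data subject-level table with `baseline`, `followup` and `sex`
#'   columns named by the arguments.
#' @param baseline,outcome column names of the baseline and follow-up
#'   values.
#' @param covariates additional adjustment columns (default none).
#' @param cluster pair-id column.
#' @return one-row tibble: `estimate` (interaction coefficient),
#'   `robust_se`, `p_value`.
#' @export
sex_interaction_test <- function(data, baseline, outcome, covariates = character(),
                                 cluster = "pair_id") {
  if (length(unique(data$sex)) < 2)
    stop("sex interaction is inestimable from single-sex data", call. = FALSE)
  d <- prepare_regression_data(data, outcome, c(baseline, "sex"), covariates, cluster)
  d$sex <- factor(d$sex)
  fml <- stats::reformulate(c(paste0(baseline, " * sex"), covariates),
                            response = outcome)
  fit <- gee_fit(fml, d, id = cluster, family = stats::gaussian())
  res <- summary(fit)
  res <- res[grepl(":", res$term), c("term", "estimate", "robust_se", "p_value")]
  attr(res, "fit") <- fit
  res
}
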