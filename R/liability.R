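#' Liability threshold implied by a prevalence
#'
#' Under the liability-threshold model a binary trait is the indicator
#' that a standard-normal latent liability exceeds a threshold; the
#' threshold is the upper-tail normal quantile of the prevalence.
#'
#' @param prevalence proportion(s) affected, each in (0, 1).
#' @return threshold(s) z with `P(Z > z) = prevalence`.
#' @examples
#' threshold_from_prevalence(0.5)    # 0
#' threshold_from_prevalence(0.282)  # ~0.577
#' @export
threshold_from_prevalence <- function(prevalence) {
  if (any(!is.finite(prevalence)) || any(prevalence <= 0) || any(prevalence >= 1))
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  stats::qnorm(prevalence, lower.tail = FALSE)
}

#' Upper-orthant probability of a standard bivariate normal
#'
#' `P(X1 > z, X2 > z)` for standard normal margins with correlation `r`,
#' by one-dimensional quadrature of the conditional-normal form
#' `integral_z^Inf phi(x) Phi-bar((z - r x) / sqrt(1 - r^2)) dx`.
#'
#' @param z common threshold.
#' @param r correlation in (-1, 1); the limits r = 1 and r = -1 are
#'   handled by their closed forms.
#' @return the orthant probability.
#' @export
bvn_upper_tail <- function(z, r) {
  stopifnot(length(z) == 1, length(r) == 1, is.finite(z), r >= -1, r <= 1)
  p <- stats::pnorm(z, lower.tail = FALSE)
  if (r == 1) return(p)
  if (r == -1) return(max(0, 1 - 2 * stats::pnorm(z)))
  s <- sqrt(1 - r^2)
  stats::integrate(function(x) stats::dnorm(x) *
                     stats::pnorm((z - r * x) / s, lower.tail = FALSE),
                   lower = z, upper = Inf,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

#' Model-implied twin concordance on the liability scale
#'
#' Forward map from a liability correlation to the concordance of a
#' thresholded binary trait. Probandwise concordance is
#' `P(twin 2 affected | twin 1 affected)`; pairwise concordance is the
#' proportion of concordant-affected pairs among pairs with at least one
#' affected member.
#'
#' @param r liability correlation.
#' @param prevalence trait prevalence in (0, 1).
#' @param type concordance definition.
#' @return the concordance implied by the bivariate-normal liability.
#' @export
concordance_from_liability <- function(r, prevalence,
                                       type = c("probandwise", "pairwise")) {
  type <- match.arg(type)
  z <- threshold_from_prevalence(prevalence)
  both <- bvn_upper_tail(z, r)
  switch(type,
         probandwise = both / prevalence,
         pairwise = both / (2 * prevalence - both))
}

#' Tetrachoric liability correlation from a twin concordance
#'
#' Inverts [concordance_from_liability()]: finds the correlation of the
#' latent bivariate normal whose implied concordance (probandwise or
#' pairwise) at the threshold set by the prevalence equals the observed
#' concordance. Solved by root-finding on (-1, 1).
#'
#' @param concordance observed concordance in \[0, 1\].
#' @param prevalence trait prevalence in (0, 1).
#' @param type concordance definition.
#' @param nonnegative force `r >= 0`: a concordance below the
#'   independence value then returns the boundary `r = 0` with a warning.
#' @return the tetrachoric correlation.
#' @examples
#' tetrachoric_from_concordance(0.667, 0.282)  # male IFG-like inputs
#' @export
tetrachoric_from_concordance <- function(concordance, prevalence,
                                         type = c("probandwise", "pairwise"),
                                         nonnegative = FALSE) {
  type <- match.arg(type)
  stopifnot(concordance >= 0, concordance <= 1)
  z <- threshold_from_prevalence(prevalence)

  f <- function(r) concordance_from_liability(r, prevalence, type) - concordance
  lo <- if (nonnegative) 0 else -1 + 1e-9
  if (nonnegative && f(0) > 0) {
    warning("observed concordance below the independence value; ",
            "returning boundary r = 0", call. = FALSE)
    return(0)
  }
  if (f(1 - 1e-9) < 0) return(1)     # concordance at (or above) its maximum
  if (f(lo) > 0) return(lo + 1e-9)
  stats::uniroot(f, c(lo, 1 - 1e-9), tol = 1e-12)$root
}

#' Liability-threshold ACE decomposition for a binary trait
#'
#' Converts observed MZ and DZ twin concordances to tetrachoric
#' correlations on the latent liability scale (threshold fixed by the
#' trait prevalence), then fits the standardized ACE model to those
#' liability correlations exactly as [fit_ace_continuous()], with the
#' pair counts weighting the two zygosity groups.
#'
#' @param concordance_mz,concordance_dz observed concordances in \[0, 1\].
#' @param prevalence trait prevalence in (0, 1).
#' @param n_mz_pairs,n_dz_pairs pair counts.
#' @param type concordance definition (probandwise by default).
#' @param ci compute profile-likelihood intervals.
#' @return an `ace_fit` (see [fit_ace_continuous()]); the tetrachoric
#'   correlations appear as its `corr` element.
#' @examples
#' fit_ace_liability(0.667, 0.439, prevalence = 0.282,
#'                   n_mz_pairs = 218, n_dz_pairs = 141)
#' @export
fit_ace_liability <- function(concordance_mz, concordance_dz, prevalence,
                              n_mz_pairs, n_dz_pairs,
                              type = c("probandwise", "pairwise"), ci = TRUE) {
  type <- match.arg(type)
  r_mz <- tetrachoric_from_concordance(concordance_mz, prevalence, type)
  r_dz <- tetrachoric_from_concordance(concordance_dz, prevalence, type)
  fit_ace_continuous(twin_correlations(r_mz, r_dz, n_mz_pairs, n_dz_pairs), ci = ci)
}

#' Observed twin concordance for a binary trait
#'
#' Tabulates affected status within complete twin pairs and returns the
#' probandwise or pairwise concordance per zygosity, plus prevalence —
#' the raw-data entry point to [fit_ace_liability()].
#'
#' @param affected1,affected2 logical affected status of the two members
#'   of each pair.
#' @param zygosity `"MZ"`/`"DZ"` per pair.
#' @param type concordance definition.
#' @return tibble with one row per zygosity: `zygosity`, `n_pairs`,
#'   `concordance`, `prevalence` (overall, both zygosities pooled).
#' @export
twin_concordance <- function(affected1, affected2, zygosity,
                             type = c("probandwise", "pairwise")) {
  type <- match.arg(type)
  keep <- !is.na(affected1) & !is.na(affected2)
  prevalence <- mean(c(affected1[keep], affected2[keep]))
  out <- lapply(c("MZ", "DZ"), function(zyg) {
    idx <- keep & zygosity == zyg
    a1 <- affected1[idx]; a2 <- affected2[idx]
    both <- sum(a1 & a2); any_aff <- sum(a1 | a2)
    conc <- switch(type,
                   probandwise = 2 * both / (2 * both + sum(xor(a1, a2))),
                   pairwise = if (any_aff == 0) NA_real_ else both / any_aff)
    tibble::tibble(zygosity = zyg, n_pairs = sum(idx), concordance = conc)
  })
  out <- dplyr::bind_rows(out)
  out$prevalence <- prevalence
  out
}
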