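#' Configuration for a synthetic twin cohort
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' defaults emulate a rural Chinese child/adolescent twin cohort followed
#' over six years: same-sex MZ/DZ pairs (218/141 male, 201/81 female),
#' baseline ages 6-21 years, an oral glucose tolerance test at both visits,
#' and trait variance decomposed into additive-genetic (a2), shared-
#' environment (c2) and unique-environment (e2) components on the
#' standardized scale.
#'
#' Continuous traits are drawn, pair by pair, from a multivariate normal
#' over (twin 1, twin 2) x (baseline, follow-up) whose within-pair
#' correlation at a visit is `a2 + c2` for MZ pairs and `a2/2 + c2` for DZ
#' pairs, and whose within-subject cross-visit correlation is `tracking_r`.
#' The cross-twin cross-visit correlation is the product of the two
#' (separable Kronecker structure). Binary traits are defined by
#' thresholding a standardized follow-up liability at the normal quantile
#' implied by the configured prevalence; a liability trait may be coupled
#' to a continuous trait (sharing its latent score) or carry its own
#' independent liability with the same familial structure.
#'
#' @param n_mz_pairs,n_dz_pairs number of monozygotic / dizygotic pairs.
#' @param sex_ratio proportion of male pairs; length 1, or length 2 giving
#'   the MZ and DZ proportions separately. The default reproduces pair
#'   counts of 218/201 (MZ male/female) and 141/81 (DZ).
#' @param ace named list, one entry per continuous trait (`fpg`, `pg2h`,
#'   `fpi`), each a numeric vector `c(a2, c2, e2)` summing to 1.
#' @param tracking_r within-subject baseline-to-follow-up correlation on
#'   the latent (standardized) scale, in (-1, 1).
#' @param trait_means,trait_sds nested lists `[[sex]][[visit]]` of named
#'   vectors over traits; units are mmol/L for `fpg` and `pg2h` and uU/mL
#'   for `fpi`. `fpi` is generated log-normally (moment-matched) so values
#'   are strictly positive.
#' @param liability named list of binary liability traits. Each entry is a
#'   list with `prevalence` (named by sex, each in (0,1)) and `coupled_to`
#'   (name of a continuous trait, or `NA` for an independent liability with
#'   the ACE structure given in its `ace` field, defaulting to the `fpg`
#'   structure).
#' @param age_range baseline age range in years (uniform draw per pair).
#' @param followup_gap years between visits; follow-up age = baseline + gap.
#' @param bmi_mean,bmi_sd nested lists `[[sex]][[visit]]`, kg/m^2.
#' @param bmi_pair_r,bmi_visit_r within-pair and cross-visit correlation of
#'   BMI (zygosity-independent; covariates carry no genetic signal so that
#'   regression recovery tests have a known target).
#' @param bmi_effect optional linear effect of mean-centred BMI on fasting
#'   glucose, mmol/L per kg/m^2 (default 0: covariates independent of
#'   glucose).
#' @param smoking_prob probability of smoking at follow-up (baseline rows
#'   are always non-smoking: subjects are children at baseline).
#' @param activity_probs probabilities of the follow-up activity categories
#'   `low`, `moderate`, `high`, `na` (questionnaire administered at
#'   follow-up only; baseline activity is missing).
#' @param dropout completely-at-random probability that a subject's
#'   follow-up row is dropped.
#' @param seed integer seed stored with the configuration; used by
#'   [generate_cohort()] unless overridden.
#'
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
simulation_config <- function(n_mz_pairs = 419,
                              n_dz_pairs = 222,
                              sex_ratio = c(218 / 419, 141 / 222),
                              ace = list(
                                fpg  = c(a2 = 0.43, c2 = 0.19, e2 = 0.38),
                                pg2h = c(a2 = 0.27, c2 = 0.33, e2 = 0.40),
                                fpi  = c(a2 = 0.57, c2 = 0.00, e2 = 0.43)
                              ),
                              tracking_r = 0.5,
                              trait_means = list(
                                M = list(baseline = c(fpg = 4.5, pg2h = 4.7, fpi = 7.1),
                                         followup = c(fpg = 5.4, pg2h = 5.8, fpi = 8.2)),
                                F = list(baseline = c(fpg = 4.4, pg2h = 4.7, fpi = 7.5),
                                         followup = c(fpg = 5.3, pg2h = 5.9, fpi = 10.7))
                              ),
                              trait_sds = list(
                                M = list(baseline = c(fpg = 0.5, pg2h = 0.9, fpi = 5.7),
                                         followup = c(fpg = 0.4, pg2h = 1.4, fpi = 4.1)),
                                F = list(baseline = c(fpg = 0.5, pg2h = 0.8, fpi = 6.4),
                                         followup = c(fpg = 0.4, pg2h = 1.3, fpi = 4.8))
                              ),
                              liability = list(
                                ifg = list(prevalence = c(M = 0.282, F = 0.189),
                                           coupled_to = "fpg")
                              ),
                              age_range = c(6, 21),
                              followup_gap = 6,
                              bmi_mean = list(M = list(baseline = 15.8, followup = 19.2),
                                              F = list(baseline = 15.6, followup = 19.9)),
                              bmi_sd = list(M = list(baseline = 2.4, followup = 2.5),
                                            F = list(baseline = 2.3, followup = 2.4)),
                              bmi_pair_r = 0.5,
                              bmi_visit_r = 0.7,
                              bmi_effect = 0,
                              smoking_prob = 0.15,
                              activity_probs = c(low = 0.31, moderate = 0.31,
                                                 high = 0.23, na = 0.15),
                              dropout = 0,
                              seed = 20260101L) {
  config <- list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    sex_ratio = rep_len(sex_ratio, 2L), ace = ace, tracking_r = tracking_r,
    trait_means = trait_means, trait_sds = trait_sds, liability = liability,
    age_range = age_range, followup_gap = followup_gap,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    bmi_pair_r = bmi_pair_r, bmi_visit_r = bmi_visit_r,
    bmi_effect = bmi_effect, smoking_prob = smoking_prob,
    activity_probs = activity_probs, dropout = dropout,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(config) <- "simulation_config"
  validate_simulation_config(config)
  config
}

validate_simulation_config <- function(config) {
  stopifnot(
    config$n_mz_pairs >= 1L, config$n_dz_pairs >= 1L,
    all(config$sex_ratio >= 0), all(config$sex_ratio <= 1),
    config$followup_gap > 0, diff(config$age_range) >= 0,
    config$dropout >= 0, config$dropout < 1,
    config$smoking_prob >= 0, config$smoking_prob <= 1
  )
  if (abs(sum(config$activity_probs) - 1) > 1e-8)
    stop("activity_probs must sum to 1", call. = FALSE)
  for (trait in names(config$ace)) {
    p <- config$ace[[trait]]
    if (length(p) != 3L || any(p < 0) || any(p > 1))
      stop("ace[['", trait, "']] must be three proportions in [0, 1]", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-8)
      stop("ace[['", trait, "']]: a2 + c2 + e2 must equal 1 (got ",
           format(sum(p)), ")", call. = FALSE)
  }
  if (abs(config$tracking_r) >= 1)
    stop("tracking_r must lie strictly inside (-1, 1)", call. = FALSE)
  for (sex in c("M", "F")) for (visit in c("baseline", "followup")) {
    m <- config$trait_means[[sex]][[visit]]; s <- config$trait_sds[[sex]][[visit]]
    stopifnot(all(is.finite(m)), all(is.finite(s)), all(s > 0))
  }
  for (nm in names(config$liability)) {
    prev <- config$liability[[nm]]$prevalence
    if (any(prev <= 0) || any(prev >= 1))
      stop("liability[['", nm, "']]$prevalence must lie in (0, 1)", call. = FALSE)
  }
  invisible(config)
}

# Correlation matrix of (twin1.base, twin1.fu, twin2.base, twin2.fu):
# Kronecker product of the pair matrix [[1, rho], [rho, 1]] with the visit
# matrix [[1, t], [t, 1]].  Positive definite iff |rho| < 1 and |t| < 1;
# checked explicitly so a bad (a2, c2, tracking_r) combination is named.
pair_visit_corr <- function(rho, tracking_r, a2 = NA, c2 = NA) {
  R <- kronecker(matrix(c(1, rho, rho, 1), 2), matrix(c(1, tracking_r, tracking_r, 1), 2))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop(sprintf(paste0("implied pair/visit covariance is not positive definite ",
                        "(a2 = %s, c2 = %s, tracking_r = %s give within-pair ",
                        "correlation %s)"),
                 format(a2), format(c2), format(tracking_r), format(rho)),
         call. = FALSE)
  R
}

# log-normal parameters matching a target mean and sd
lognormal_pars <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Generate a synthetic longitudinal twin cohort
#'
#' Draws a cohort under a [simulation_config()]: same-sex twin pairs with
#' continuous OGTT traits carrying a known ACE correlation structure and
#' baseline-to-follow-up tracking, covariates (age, Tanner stage, BMI,
#' smoking, physical activity), and threshold-defined binary liability
#' traits. Deterministic for a fixed seed and configuration.
#'
#' @param config a `simulation_config`.
#' @param seed integer; overrides `config$seed` when supplied.
#' @return a tibble in long (subject x visit) format with columns
#'   `subject_id`, `pair_id`, `zygosity`, `sex`, `visit`, `age`, `tanner`,
#'   `bmi`, `smoking`, `activity`, `fpg`, `pg2h`, `fpi`, plus one logical
#'   column per configured liability trait (constant within subject,
#'   defined at follow-up).
#' @examples
#' cohort <- generate_cohort(simulation_config(n_mz_pairs = 50, n_dz_pairs = 30))
#' table(cohort$zygosity, cohort$visit)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_simulation_config(config)
  if (!is.null(seed)) set.seed(as.integer(seed))

  pairs <- make_pair_frame(config)
  n_pairs <- nrow(pairs)

  # latent standardized scores: list [[trait]] of n_pairs x 4 matrices
  latents <- list()
  for (trait in names(config$ace)) {
    p <- config$ace[[trait]]
    latents[[trait]] <- draw_pair_latents(pairs$zygosity, p[["a2"]], p[["c2"]],
                                          config$tracking_r)
  }

  # BMI: zygosity-independent familial resemblance, no genetic signal
  bmi_lat <- rbind_latents(
    pair_visit_corr(config$bmi_pair_r, config$bmi_visit_r), n_pairs)

  cohort <- expand_to_long(pairs, config)

  for (trait in names(config$ace)) {
    z <- latent_long(latents[[trait]], pairs)     # one standardized score per row
    cohort[[paste0(".z_", trait)]] <- z
    cohort[[trait]] <- scale_trait(z, trait, cohort$sex, cohort$visit, config)
  }
  cohort$bmi <- scale_bmi(latent_long(bmi_lat, pairs), cohort$sex, cohort$visit, config)

  if (config$bmi_effect != 0) {
    centred <- cohort$bmi - bmi_reference(cohort$sex, cohort$visit, config)
    cohort$fpg <- cohort$fpg + config$bmi_effect * centred
  }

  for (nm in names(config$liability)) {
    spec <- config$liability[[nm]]
    cohort[[nm]] <- liability_indicator(cohort, nm, spec, pairs, config)
  }
  cohort[startsWith(names(cohort), ".z_")] <- NULL
  cohort$twin <- NULL
  lead <- c("subject_id", "pair_id", "zygosity", "sex", "visit", "age",
            "tanner", "bmi", "smoking", "activity", "fpg", "pg2h", "fpi")
  cohort <- cohort[c(lead, setdiff(names(cohort), lead))]

  if (config$dropout > 0) {
    # completely-at-random loss of the follow-up visit, drawn per subject
    subjects <- unique(cohort$subject_id)
    keep <- stats::runif(length(subjects)) >= config$dropout
    names(keep) <- subjects
    cohort <- cohort[cohort$visit == "baseline" | keep[cohort$subject_id], ]
  }
  tibble::as_tibble(cohort)
}

make_pair_frame <- function(config) {
  n <- c(MZ = config$n_mz_pairs, DZ = config$n_dz_pairs)
  n_male <- round(n * config$sex_ratio)
  pairs <- data.frame(
    zygosity = rep(c("MZ", "DZ"), times = n),
    sex = c(rep(c("M", "F"), c(n_male[["MZ"]], n[["MZ"]] - n_male[["MZ"]])),
            rep(c("M", "F"), c(n_male[["DZ"]], n[["DZ"]] - n_male[["DZ"]])))
  )
  pairs$pair_id <- sprintf("P%04d", seq_len(nrow(pairs)))
  pairs$age_base <- stats::runif(nrow(pairs), config$age_range[1], config$age_range[2])
  pairs
}

# n x 4 latent matrix (twin1.base, twin1.fu, twin2.base, twin2.fu), with the
# zygosity-specific within-pair correlation
draw_pair_latents <- function(zygosity, a2, c2, tracking_r) {
  out <- matrix(NA_real_, length(zygosity), 4)
  for (zyg in c("MZ", "DZ")) {
    idx <- zygosity == zyg
    if (!any(idx)) next
    rho <- if (zyg == "MZ") a2 + c2 else a2 / 2 + c2
    R <- pair_visit_corr(rho, tracking_r, a2, c2)
    out[idx, ] <- MASS::mvrnorm(sum(idx), mu = rep(0, 4), Sigma = R)
  }
  out
}

rbind_latents <- function(R, n) MASS::mvrnorm(n, mu = rep(0, 4), Sigma = R)

expand_to_long <- function(pairs, config) {
  long <- pairs[rep(seq_len(nrow(pairs)), each = 4L),
                c("pair_id", "zygosity", "sex", "age_base")]
  long$twin <- rep(rep(1:2, each = 2L), nrow(pairs))
  long$visit <- rep(c("baseline", "followup"), 2L * nrow(pairs))
  long$subject_id <- paste0(long$pair_id, "_", long$twin)
  long$age <- long$age_base + ifelse(long$visit == "followup", config$followup_gap, 0)
  long$tanner <- tanner_from_age(long$age)
  n_sub <- nrow(long) / 2L
  smoke <- stats::runif(n_sub) < config$smoking_prob
  long$smoking <- ifelse(long$visit == "followup", smoke[match(long$subject_id,
                         unique(long$subject_id))], FALSE)
  act_levels <- c("low", "moderate", "high", NA)
  act <- sample(act_levels, n_sub, replace = TRUE, prob = config$activity_probs)
  long$activity <- ifelse(long$visit == "followup",
                          act[match(long$subject_id, unique(long$subject_id))],
                          NA_character_)
  long$age_base <- NULL
  rownames(long) <- NULL
  long[c("subject_id", "pair_id", "zygosity", "sex", "visit", "twin",
         "age", "tanner", "smoking", "activity")]
}

# map an n_pairs x 4 latent matrix onto the long row order
# (twin1.base, twin1.fu, twin2.base, twin2.fu per pair)
latent_long <- function(latents, pairs) as.vector(t(latents))

tanner_from_age <- function(age) pmin(5L, pmax(1L, floor((age - 8) / 2) + 1L))

scale_trait <- function(z, trait, sex, visit, config) {
  out <- numeric(length(z))
  for (s in c("M", "F")) for (v in c("baseline", "followup")) {
    idx <- sex == s & visit == v
    m <- config$trait_means[[s]][[v]][[trait]]
    sd <- config$trait_sds[[s]][[v]][[trait]]
    if (trait == "fpi") {
      lp <- lognormal_pars(m, sd)
      out[idx] <- exp(lp$mu + lp$sigma * z[idx])
    } else {
      out[idx] <- m + sd * z[idx]
    }
  }
  out
}

scale_bmi <- function(z, sex, visit, config) {
  out <- numeric(length(z))
  for (s in c("M", "F")) for (v in c("baseline", "followup")) {
    idx <- sex == s & visit == v
    out[idx] <- config$bmi_mean[[s]][[v]] + config$bmi_sd[[s]][[v]] * z[idx]
  }
  out
}

bmi_reference <- function(sex, visit, config) {
  ref <- numeric(length(sex))
  for (s in c("M", "F")) for (v in c("baseline", "followup")) {
    idx <- sex == s & visit == v
    ref[idx] <- config$bmi_mean[[s]][[v]]
  }
  ref
}

liability_indicator <- function(cohort, nm, spec, pairs, config) {
  if (!is.null(spec$coupled_to) && !is.na(spec$coupled_to)) {
    z <- cohort[[paste0(".z_", spec$coupled_to)]]
  } else {
    p <- spec$ace %||% config$ace[["fpg"]]
    lat <- draw_pair_latents(pairs$zygosity, p[["a2"]], p[["c2"]], config$tracking_r)
    z <- latent_long(lat, pairs)
  }
  # liability is the standardized follow-up score; constant within subject
  z_fu <- z[cohort$visit == "followup"]
  thr <- threshold_from_prevalence(spec$prevalence)
  sex_fu <- cohort$sex[cohort$visit == "followup"]
  affected <- z_fu > thr[sex_fu]
  affected[match(cohort$subject_id, cohort$subject_id[cohort$visit == "followup"])]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read or write a cohort table as CSV
#'
#' Plain-CSV serialization of the long cohort schema produced by
#' [generate_cohort()].
#'
#' @param cohort a cohort tibble.
#' @param path file path.
#' @return `read_cohort` returns a tibble; `write_cohort` returns `path`
#'   invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort$smoking <- as.logical(cohort$smoking)
  tibble::as_tibble(cohort)
}
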