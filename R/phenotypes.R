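#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' HOMA-IR = fasting insulin (uU/mL) x fasting glucose (mmol/L) / 22.5.
#'
#' @param fpi fasting plasma insulin, uU/mL, non-negative.
#' @param fpg fasting plasma glucose, mmol/L, non-negative.
#' @return dimensionless index, vectorized.
#' @examples
#' compute_homa_ir(8.2, 5.4)   # ~2.0
#' @export
compute_homa_ir <- function(fpi, fpg) {
  if (any(!is.finite(fpi)) || any(!is.finite(fpg)))
    stop("fpi and fpg must be finite", call. = FALSE)
  if (any(fpi < 0) || any(fpg < 0))
    stop("fpi and fpg must be non-negative", call. = FALSE)
  fpi * fpg / 22.5
}

#' Natural-log transform of HOMA-IR
#'
#' HOMA-IR is right-skewed; analyses use its natural logarithm.
#'
#' @param h HOMA-IR values, strictly positive.
#' @return log-scale values.
#' @export
log_homa <- function(h) {
  if (any(!is.finite(h)) || any(h <= 0))
    stop("log_homa requires strictly positive finite values", call. = FALSE)
  log(h)
}

#' Glycemic status from an oral glucose tolerance test
#'
#' American Diabetes Association criteria on fasting (FPG) and 2-hour
#' post-load (2hPG) plasma glucose, both in mmol/L:
#' diabetes if FPG >= 7.0 or 2hPG >= 11.1; otherwise impaired fasting
#' glucose (IFG) if FPG in \[5.6, 7.0) with 2hPG < 7.8; impaired glucose
#' tolerance (IGT) if 2hPG in \[7.8, 11.1) with FPG < 5.6; `IFG_IGT` when
#' both ranges hold; else normal glucose tolerance (NGT). Prediabetes is
#' IFG and/or IGT (including the combined category); diabetes is not
#' prediabetes. The printed one-decimal ranges are implemented as
#' half-open intervals so the categories partition the plane without gaps.
#'
#' @param fpg,pg2h glucose measurements, mmol/L, vectorized.
#' @param combined how to label a subject meeting both the IFG and IGT
#'   ranges: own category (default), or folded into `IFG` or `IGT` for
#'   tabulations that dichotomize.
#' @return a tibble with columns `category` (factor with levels NGT, IFG,
#'   IGT, IFG_IGT, DIABETES) and `prediabetes` (logical).
#' @examples
#' classify_glycemic(c(5.5, 5.6, 7.0, 5.8), c(7.7, 7.0, 5.0, 8.0))
#' @export
classify_glycemic <- function(fpg, pg2h,
                              combined = c("IFG_IGT", "IFG", "IGT")) {
  combined <- match.arg(combined)
  if (any(!is.finite(fpg)) || any(!is.finite(pg2h)))
    stop("fpg and pg2h must be finite", call. = FALSE)
  if (any(fpg < 0) || any(pg2h < 0))
    stop("fpg and pg2h must be non-negative", call. = FALSE)

  diabetes <- fpg >= 7.0 | pg2h >= 11.1
  high_fast <- fpg >= 5.6           # within [5.6, 7.0) once diabetes excluded
  high_load <- pg2h >= 7.8          # within [7.8, 11.1) once diabetes excluded

  category <- rep("NGT", length(fpg))
  category[!diabetes & high_fast & !high_load] <- "IFG"
  category[!diabetes & !high_fast & high_load] <- "IGT"
  category[!diabetes & high_fast & high_load] <- combined
  category[diabetes] <- "DIABETES"
  category <- factor(category, levels = c("NGT", "IFG", "IGT", "IFG_IGT", "DIABETES"))
  tibble::tibble(category = category,
                 prediabetes = category %in% c("IFG", "IGT", "IFG_IGT"))
}

#' Add derived glycemic phenotypes to a cohort table
#'
#' Vectorized over the rows of a cohort in the [generate_cohort()] schema:
#' appends `homa_ir`, `log_homa`, `glycemic_category` and `prediabetes`.
#'
#' @param cohort a cohort tibble with `fpg`, `pg2h`, `fpi` columns.
#' @inheritParams classify_glycemic
#' @return the cohort with four added columns.
#' @export
add_glycemic_phenotypes <- function(cohort, combined = "IFG_IGT") {
  cohort$homa_ir <- compute_homa_ir(cohort$fpi, cohort$fpg)
  cohort$log_homa <- log_homa(cohort$homa_ir)
  status <- classify_glycemic(cohort$fpg, cohort$pg2h, combined = combined)
  cohort$glycemic_category <- status$category
  cohort$prediabetes <- status$prediabetes
  cohort
}
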