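#' Age- and sex-specific tertile assignment
#'
#' Ranks a trait into tertiles within strata defined by sex and an age
#' bin, so that a subject is compared only with peers of the same sex and
#' similar age. Cut-points are the within-stratum empirical 1/3 and 2/3
#' quantiles; equal values always share a tertile (ties never straddle a
#' cut-point). Strata with fewer than `min_stratum` subjects are merged
#' into the nearest age bin of the same sex, with a warning.
#'
#' @param values trait measurements (one per subject).
#' @param sex character vector, `"M"`/`"F"`.
#' @param age ages in years.
#' @param age_bin_width width of the age bins, years (default 2).
#' @param min_stratum smallest stratum ranked on its own (default 3).
#' @return a tibble with columns `tertile` (ordered factor T1 < T2 < T3)
#'   and `stratum` (label `"sex:[lo,hi)"`), aligned with the input.
#' @export
assign_tertiles <- function(values, sex, age, age_bin_width = 2, min_stratum = 3) {
  stopifnot(length(values) == length(sex), length(sex) == length(age))
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)

  bin <- floor((age - min(age)) / age_bin_width)
  merged <- merge_small_bins(bin, sex, min_stratum)
  stratum <- paste0(sex, ":", merged)

  tertile <- rep(NA_character_, length(values))
  for (s in unique(stratum)) {
    idx <- stratum == s
    tertile[idx] <- cut_tertiles(values[idx])
  }
  tibble::tibble(
    tertile = factor(tertile, levels = c("T1", "T2", "T3"), ordered = TRUE),
    stratum = stratum
  )
}

# merge age bins with < min_stratum members into the nearest bin of the
# same sex (repeatedly, since a merge can still be small)
merge_small_bins <- function(bin, sex, min_stratum) {
  bin <- as.numeric(bin)
  for (s in unique(sex)) {
    repeat {
      idx <- sex == s
      counts <- table(bin[idx])
      small <- names(counts)[counts < min_stratum]
      if (length(small) == 0 || length(counts) == 1) break
      b <- as.numeric(small[1])
      others <- as.numeric(setdiff(names(counts), small[1]))
      nearest <- others[which.min(abs(others - b))]
      warning(sprintf("age bin %s (%s) has fewer than %d subjects; merged into bin %s",
                      format(b), s, min_stratum, format(nearest)), call. = FALSE)
      bin[idx & bin == b] <- nearest
    }
  }
  bin
}

cut_tertiles <- function(x) {
  if (length(x) < 3) stop("cannot form tertiles from fewer than 3 values", call. = FALSE)
  q <- stats::quantile(x, c(1, 2) / 3, names = FALSE)
  breaks <- unique(c(-Inf, q, Inf))
  labels <- c("T1", "T2", "T3")[seq_len(length(breaks) - 1)]
  as.character(cut(x, breaks = breaks, labels = labels, right = TRUE))
}

#' Baseline-to-follow-up tertile transition matrix
#'
#' Cross-tabulates baseline against follow-up tertile over the subjects
#' present at both visits, and summarizes tracking by the "middle-or-top
#' persistence": the probability of remaining in T2 or T3 at follow-up
#' given T2 or T3 at baseline.
#'
#' @param base,follow data frames with columns `subject_id` and `tertile`
#'   (the output of [assign_tertiles()] plus the subject id).
#' @return an object of class `transition_matrix`: a list with `counts`
#'   (3x3), `proportions` (row-stochastic 3x3), `persistence`, `n` and
#'   `n_excluded` (subjects seen at one visit only).
#' @export
transition_matrix <- function(base, follow) {
  common <- intersect(base$subject_id, follow$subject_id)
  n_excluded <- length(unique(c(base$subject_id, follow$subject_id))) - length(common)
  b <- base$tertile[match(common, base$subject_id)]
  f <- follow$tertile[match(common, follow$subject_id)]
  levels3 <- c("T1", "T2", "T3")
  counts <- table(factor(b, levels3), factor(f, levels3))
  counts <- matrix(as.integer(counts), 3, 3, dimnames = list(baseline = levels3,
                                                             followup = levels3))
  proportions <- counts / pmax(rowSums(counts), 1L)
  up_base <- b %in% c("T2", "T3")
  persistence <- mean(f[up_base] %in% c("T2", "T3"))
  structure(list(counts = counts, proportions = proportions,
                 persistence = persistence, n = length(common),
                 n_excluded = n_excluded),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Tertile transition matrix (", x$n, " subjects, ",
      x$n_excluded, " excluded)\n", sep = "")
  print(round(x$proportions, 3))
  cat("middle-or-top persistence:", round(x$persistence, 3), "\n")
  invisible(x)
}

#' Prediabetes incidence by baseline tertile
#'
#' Among subjects with normal glucose tolerance at baseline, the
#' proportion developing prediabetes by follow-up, within each baseline
#' tertile of a trait, stratified by sex.
#'
#' @param baseline_ngt logical, normal glucose tolerance at baseline (the
#'   analysis restricts to these subjects).
#' @param tertile baseline tertile (factor T1/T2/T3), one per subject.
#' @param followup_prediabetes logical, prediabetes at follow-up.
#' @param sex subject sex.
#' @return a tibble with columns `sex`, `tertile`, `n`, `incidence`
#'   (proportion; `NA` with a warning for an empty tertile).
#' @export
incidence_by_tertile <- function(baseline_ngt, tertile, followup_prediabetes, sex) {
  stopifnot(length(baseline_ngt) == length(tertile),
            length(tertile) == length(followup_prediabetes),
            length(sex) == length(tertile))
  keep <- baseline_ngt & !is.na(followup_prediabetes)
  out <- expand.grid(sex = sort(unique(sex)), tertile = c("T1", "T2", "T3"),
                     stringsAsFactors = FALSE)
  out$n <- NA_integer_; out$incidence <- NA_real_
  for (i in seq_len(nrow(out))) {
    idx <- keep & sex == out$sex[i] & tertile == out$tertile[i]
    out$n[i] <- sum(idx)
    if (out$n[i] == 0) {
      warning(sprintf("no baseline-NGT subjects in %s tertile %s",
                      out$sex[i], out$tertile[i]), call. = FALSE)
    } else {
      out$incidence[i] <- mean(followup_prediabetes[idx])
    }
  }
  tibble::as_tibble(out)
}

#' Smoothed tracking curves by baseline tertile
#'
#' Locally weighted regression (local linear fit with tricube weights) of
#' follow-up glucose on follow-up age, fitted separately within each
#' baseline-tertile group and evaluated on a common age grid — the
#' graphical view of tracking.
#'
#' @param x follow-up ages.
#' @param y follow-up trait values.
#' @param group baseline tertile (or any grouping factor).
#' @param span smoothing span (fraction of points in each local
#'   neighbourhood, default 0.6).
#' @param n_grid number of evaluation points over the observed age range.
#' @return a tibble with columns `group`, `x`, `fitted`.
#' @export
loess_track <- function(x, y, group, span = 0.6, n_grid = 50) {
  stopifnot(length(x) == length(y), length(y) == length(group))
  out <- list()
  for (g in unique(group)) {
    idx <- group == g
    if (sum(idx) < 10)
      stop("each group needs at least 10 points (group ", g, " has ",
           sum(idx), ")", call. = FALSE)
    if (diff(range(x[idx])) == 0)
      stop("degenerate x in group ", g, ": all ages equal", call. = FALSE)
    grid <- seq(min(x[idx]), max(x[idx]), length.out = n_grid)
    fit <- stats::loess(y ~ x, data = data.frame(x = x[idx], y = y[idx]),
                        span = span, degree = 1, family = "gaussian",
                        surface = "direct")
    out[[length(out) + 1L]] <- tibble::tibble(
      group = g, x = grid, fitted = stats::predict(fit, newdata = data.frame(x = grid)))
  }
  dplyr::bind_rows(out)
}
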