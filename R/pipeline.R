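#' One row per subject with baseline and follow-up columns
#'
#' Reshapes the long cohort table to subject level, suffixing measurement
#' and covariate columns by visit — the layout the tracking and
#' regression stages work from.
#'
#' @param cohort a cohort tibble (long format), optionally already
#'   carrying derived phenotype columns.
#' @return a tibble with one row per subject present at baseline;
#'   follow-up columns are `NA` for subjects lost to follow-up.
#' @export
subject_table <- function(cohort) {
  id_cols <- c("subject_id", "pair_id", "zygosity", "sex")
  value_cols <- setdiff(names(cohort), c(id_cols, "visit"))
  base <- cohort[cohort$visit == "baseline", c(id_cols, value_cols)]
  fu <- cohort[cohort$visit == "followup", c("subject_id", value_cols)]
  names(base)[match(value_cols, names(base))] <- paste0(value_cols, "_baseline")
  names(fu)[match(value_cols, names(fu))] <- paste0(value_cols, "_followup")
  tibble::as_tibble(merge(base, fu, by = "subject_id", all.x = TRUE, sort = TRUE))
}

#' Cohort summary table
#'
#' Mean and SD of the anthropometric and glycemic variables by sex and
#' visit, with prevalence counts for IFG, IGT and prediabetes and the
#' follow-up physical-activity distribution — the shape of a cohort
#' characteristics table.
#'
#' @param cohort a phenotyped cohort ([add_glycemic_phenotypes()]).
#' @return a tibble with columns `sex`, `visit`, `variable`, `mean`,
#'   `sd`, `n`, `percent` (counts/percent filled for categorical rows).
#' @export
cohort_summary <- function(cohort) {
  num_vars <- intersect(c("age", "bmi", "fpg", "pg2h", "fpi", "homa_ir"),
                        names(cohort))
  out <- list()
  for (s in unique(cohort$sex)) for (v in c("baseline", "followup")) {
    d <- cohort[cohort$sex == s & cohort$visit == v, ]
    if (nrow(d) == 0) next
    for (nm in num_vars)
      out[[length(out) + 1L]] <- tibble::tibble(
        sex = s, visit = v, variable = nm,
        mean = mean(d[[nm]]), sd = stats::sd(d[[nm]]),
        n = NA_integer_, percent = NA_real_)
    if ("glycemic_category" %in% names(d)) {
      for (nm in c("IFG", "IGT")) {
        cnt <- sum(d$glycemic_category == nm)
        out[[length(out) + 1L]] <- tibble::tibble(
          sex = s, visit = v, variable = nm, mean = NA_real_, sd = NA_real_,
          n = cnt, percent = 100 * cnt / nrow(d))
      }
      cnt <- sum(d$prediabetes)
      out[[length(out) + 1L]] <- tibble::tibble(
        sex = s, visit = v, variable = "prediabetes", mean = NA_real_,
        sd = NA_real_, n = cnt, percent = 100 * cnt / nrow(d))
    }
    if (v == "followup" && "activity" %in% names(d)) {
      a <- as.character(d$activity); a[is.na(a)] <- "N/A"
      for (lev in c("low", "moderate", "high", "N/A")) {
        cnt <- sum(a == lev)
        out[[length(out) + 1L]] <- tibble::tibble(
          sex = s, visit = v, variable = paste0("activity_", lev),
          mean = NA_real_, sd = NA_real_, n = cnt, percent = 100 * cnt / nrow(d))
      }
    }
  }
  dplyr::bind_rows(out)
}

pipeline_tracking <- function(subjects, traits = c("fpg", "pg2h")) {
  transitions <- list(); incidence <- list()
  for (trait in traits) {
    for (s in unique(subjects$sex)) {
      d <- subjects[subjects$sex == s, ]
      ok <- !is.na(d[[paste0(trait, "_followup")]])
      base_t <- assign_tertiles(d[[paste0(trait, "_baseline")]][ok],
                                d$sex[ok], d$age_baseline[ok])
      fu_t <- assign_tertiles(d[[paste0(trait, "_followup")]][ok],
                              d$sex[ok], d$age_followup[ok])
      tm <- transition_matrix(
        data.frame(subject_id = d$subject_id[ok], tertile = base_t$tertile),
        data.frame(subject_id = d$subject_id[ok], tertile = fu_t$tertile))
      transitions[[length(transitions) + 1L]] <- tibble::tibble(
        trait = trait, sex = s,
        baseline = rep(c("T1", "T2", "T3"), 3),
        followup = rep(c("T1", "T2", "T3"), each = 3),
        count = as.vector(tm$counts),
        proportion = as.vector(tm$proportions),
        persistence = tm$persistence, n = tm$n)

      inc <- incidence_by_tertile(d$glycemic_category_baseline[ok] == "NGT",
                                  base_t$tertile,
                                  d$prediabetes_followup[ok], d$sex[ok])
      inc$trait <- trait
      incidence[[length(incidence) + 1L]] <- inc
    }
  }
  list(transitions = dplyr::bind_rows(transitions),
       incidence = dplyr::bind_rows(incidence))
}

pipeline_regression <- function(subjects,
                                exposures = c("fpg", "pg2h", "homa_ir"),
                                outcomes = c(fpg_followup = "gaussian",
                                             pg2h_followup = "gaussian",
                                             log_homa_followup = "gaussian",
                                             prediabetes_followup = "binomial")) {
  rows <- list()
  for (s in unique(subjects$sex)) {
    d <- subjects[subjects$sex == s, ]
    d <- d[!is.na(d$fpg_followup), ]
    names(d)[names(d) == "activity_followup"] <- "activity"
    covs <- c("age_followup", "tanner_followup", "smoking_followup",
              "bmi_followup", "activity")
    for (expo in exposures) {
      tert <- assign_tertiles(d[[paste0(expo, "_baseline")]], d$sex, d$age_baseline)
      d$.tertile <- tert$tertile
      for (out_nm in names(outcomes)) {
        fam <- outcomes[[out_nm]]
        res <- fit_clustered(d, out_nm, ".tertile", covariates = covs,
                             family = fam)
        tr <- trend_test(d, out_nm, ".tertile", covariates = covs, family = fam)
        est_col <- if (fam == "binomial") "odds_ratio" else "estimate"
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sex = s, exposure = expo, outcome = out_nm, tertile = res$term,
          estimate = res[[est_col]], robust_se = res$robust_se,
          conf.low = res$conf.low, conf.high = res$conf.high,
          p_value = res$p_value, p_trend = tr$p_value)
      }
    }
  }
  dplyr::bind_rows(rows)
}

pipeline_twin <- function(subjects,
                          continuous = c("fpg", "pg2h", "log_homa"),
                          binary = "ifg") {
  rows <- list()
  fmt_ci <- function(ci) sprintf("(%.2f~%.2f)", ci[1], ci[2])
  for (s in unique(subjects$sex)) {
    d <- subjects[subjects$sex == s & !is.na(subjects$fpg_followup), ]
    pair_tab <- pair_values(d)
    for (trait in continuous) {
      col <- paste0(trait, "_followup")
      corr <- twin_correlation(pair_tab[[paste0(col, "_1")]],
                               pair_tab[[paste0(col, "_2")]], pair_tab$zygosity)
      fit <- fit_ace_continuous(corr)
      rows[[length(rows) + 1L]] <- twin_row(s, trait, corr$r_mz, corr$r_dz, fit)
    }
    for (trait in binary) {
      col <- paste0(trait, "_followup")
      if (!paste0(col, "_1") %in% names(pair_tab)) next
      conc <- twin_concordance(pair_tab[[paste0(col, "_1")]] > 0,
                               pair_tab[[paste0(col, "_2")]] > 0,
                               pair_tab$zygosity)
      fit <- fit_ace_liability(conc$concordance[conc$zygosity == "MZ"],
                               conc$concordance[conc$zygosity == "DZ"],
                               prevalence = conc$prevalence[1],
                               n_mz_pairs = conc$n_pairs[conc$zygosity == "MZ"],
                               n_dz_pairs = conc$n_pairs[conc$zygosity == "DZ"])
      rows[[length(rows) + 1L]] <- twin_row(
        s, trait, conc$concordance[conc$zygosity == "MZ"],
        conc$concordance[conc$zygosity == "DZ"], fit, liability = TRUE)
    }
  }
  dplyr::bind_rows(rows)
}

twin_row <- function(sex, trait, r_mz, r_dz, fit, liability = FALSE) {
  tibble::tibble(
    sex = sex, trait = trait, scale = if (liability) "liability" else "phenotype",
    r_mz = r_mz, r_dz = r_dz,
    a2 = fit$a2, a2_ci = sprintf("(%.2f~%.2f)", fit$ci95["a2", 1], fit$ci95["a2", 2]),
    c2 = fit$c2, c2_ci = sprintf("(%.2f~%.2f)", fit$ci95["c2", 1], fit$ci95["c2", 2]),
    e2 = fit$e2, e2_ci = sprintf("(%.2f~%.2f)", fit$ci95["e2", 1], fit$ci95["e2", 2]),
    model = fit$model)
}

# wide pair layout: one row per pair, member columns suffixed _1 / _2
pair_values <- function(subjects) {
  s <- subjects[order(subjects$pair_id, subjects$subject_id), ]
  first <- !duplicated(s$pair_id)
  complete <- s$pair_id %in% s$pair_id[duplicated(s$pair_id)]
  s <- s[complete, ]
  first <- !duplicated(s$pair_id)
  one <- s[first, ]; two <- s[!first, ]
  val_cols <- setdiff(names(s), c("subject_id", "pair_id", "zygosity", "sex"))
  out <- one[c("pair_id", "zygosity", "sex")]
  for (cc in val_cols) {
    out[[paste0(cc, "_1")]] <- one[[cc]]
    out[[paste0(cc, "_2")]] <- two[[cc]]
  }
  tibble::as_tibble(out)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file either names a cohort CSV (`cohort_csv: path`) or supplies
#' arguments for [simulation_config()] under `simulation:`; both may set
#' `seed`.
#'
#' @param path configuration file.
#' @return a list with elements `cohort_csv` (or `NULL`), `config` (a
#'   `simulation_config` or `NULL`) and `seed`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  config <- NULL
  if (is.null(raw$cohort_csv))
    config <- do.call(simulation_config, raw$simulation %||% list())
  list(cohort_csv = raw$cohort_csv, config = config, seed = raw$seed)
}

#' Run the full analysis pipeline
#'
#' Executes generate (or load) -> derive phenotypes -> tracking ->
#' clustered regression -> twin variance-component fits, writing
#' tab-separated report tables and a JSON run manifest. Every stage is a
#' pure function of the inputs, configuration and seed, so a rerun with
#' the same arguments reproduces identical numeric tables.
#'
#' @param config a `simulation_config` (ignored when `cohort` given).
#' @param outdir output directory (created if needed).
#' @param seed integer seed for cohort generation.
#' @param cohort optionally, an existing cohort tibble or path to a
#'   cohort CSV; skips the simulation stage.
#' @return the manifest, invisibly, with element `files` naming all
#'   outputs (`cohort.csv`, `cohort_summary.tsv`, `transitions.tsv`,
#'   `incidence.tsv`, `regression.tsv`, `twin_models.tsv`,
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = simulation_config(), outdir,
                         seed = config$seed, cohort = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  collect <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  withCallingHandlers({
    if (is.null(cohort)) {
      cohort <- generate_cohort(config, seed = seed)
    } else if (is.character(cohort)) {
      cohort <- read_cohort(cohort)
    }
    cohort <- add_glycemic_phenotypes(cohort)
    subjects <- subject_table(cohort)

    summary_tab <- cohort_summary(cohort)
    tracking <- pipeline_tracking(subjects)
    regression <- pipeline_regression(subjects)
    twin <- pipeline_twin(subjects)
  }, warning = collect)

  files <- c(cohort = "cohort.csv", summary = "cohort_summary.tsv",
             transitions = "transitions.tsv", incidence = "incidence.tsv",
             regression = "regression.tsv", twin = "twin_models.tsv",
             manifest = "manifest.json")
  paths <- file.path(outdir, files)
  names(paths) <- names(files)
  write_cohort(cohort, paths["cohort"])
  write_tsv_plain(summary_tab, paths["summary"])
  write_tsv_plain(tracking$transitions, paths["transitions"])
  write_tsv_plain(tracking$incidence, paths["incidence"])
  write_tsv_plain(regression, paths["regression"])
  write_tsv_plain(twin, paths["twin"])

  manifest <- list(
    package_version = as.character(utils::packageVersion("glycotwin")),
    seed = if (is.null(seed)) NA else as.integer(seed),
    config_hash = rlang::hash(config),
    created = format(Sys.time(), tz = "UTC"),
    files = as.list(paths),
    warnings = warnings_log)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, null = "null", na = "null")
  invisible(manifest)
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
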