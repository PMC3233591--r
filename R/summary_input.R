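#' Fit twin variance-component models from a summary table
#'
#' Entry point for published or pre-aggregated twin summaries: a TSV with
#' one row per trait holding either pair correlations (columns `r_mz`,
#' `r_dz`, `n_mz`, `n_dz`) for continuous traits, or concordances
#' (columns `conc_mz`, `conc_dz`, `prevalence`, `n_mz`, `n_dz`) for
#' binary traits fitted on the liability scale. Any further columns
#' (e.g. `sex`, `trait`) are carried through to the output.
#'
#' @param path TSV file, or a data frame already in that layout.
#' @param type concordance convention for the liability rows.
#' @return a tibble with the input identifier columns plus `r_mz`, `r_dz`
#'   (tetrachoric for liability rows), `a2`, `c2`, `e2`, their 95%
#'   profile CIs (`*_lower`, `*_upper`) and `scale`.
#' @examples
#' path <- system.file("extdata", "demo_twin_correlations.tsv",
#'                     package = "glycotwin")
#' fit_ace_table(path)
#' @export
fit_ace_table <- function(path, type = c("probandwise", "pairwise")) {
  type <- match.arg(type)
  tab <- if (is.data.frame(path)) path
         else utils::read.delim(path, stringsAsFactors = FALSE)
  liability <- all(c("conc_mz", "conc_dz", "prevalence") %in% names(tab))
  if (!liability && !all(c("r_mz", "r_dz") %in% names(tab)))
    stop("summary table needs either r_mz/r_dz or conc_mz/conc_dz/prevalence ",
         "columns (plus n_mz, n_dz)", call. = FALSE)
  if (!all(c("n_mz", "n_dz") %in% names(tab)))
    stop("summary table needs pair counts n_mz and n_dz", call. = FALSE)

  id_cols <- setdiff(names(tab), c("r_mz", "r_dz", "conc_mz", "conc_dz",
                                   "prevalence", "n_mz", "n_dz"))
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    fit <- if (liability) {
      fit_ace_liability(row$conc_mz, row$conc_dz, prevalence = row$prevalence,
                        n_mz_pairs = row$n_mz, n_dz_pairs = row$n_dz, type = type)
    } else {
      fit_ace_continuous(twin_correlations(row$r_mz, row$r_dz,
                                           row$n_mz, row$n_dz))
    }
    out <- tibble::as_tibble(row[id_cols])
    out$scale <- if (liability) "liability" else "phenotype"
    out$r_mz <- fit$corr$r_mz; out$r_dz <- fit$corr$r_dz
    for (comp in c("a2", "c2", "e2")) {
      out[[comp]] <- fit[[comp]]
      out[[paste0(comp, "_lower")]] <- fit$ci95[comp, "lower"]
      out[[paste0(comp, "_upper")]] <- fit$ci95[comp, "upper"]
    }
    out
  })
  dplyr::bind_rows(rows)
}
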