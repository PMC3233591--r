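#!/usr/bin/env Rscript
# Stage 2: derive glycemic phenotypes and summarize the cohort.
#
# Adds HOMA-IR (insulin x glucose / 22.5), its natural log, the ADA
# glycemic category and the prediabetes flag; writes a cohort
# characteristics table (means +/- SD and prevalence counts by sex and
# visit).

library(glycotwin)

cohort <- add_glycemic_phenotypes(read_cohort("results/cohort.csv"))
write_cohort(cohort, "results/cohort_phenotyped.csv")

summary_tab <- cohort_summary(cohort)
write.table(summary_tab, "results/cohort_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fu <- cohort[cohort$visit == "followup", ]
base <- cohort[cohort$visit == "baseline", ]
cat(sprintf("prediabetes prevalence: baseline %.1f%%, follow-up %.1f%%\n",
            100 * mean(base$prediabetes), 100 * mean(fu$prediabetes)))
for (s in c("M", "F"))
  cat(sprintf("  %s follow-up: IFG %.1f%%, IGT %.1f%%, mean HOMA-IR %.2f\n", s,
              100 * mean(fu$glycemic_category[fu$sex == s] == "IFG"),
              100 * mean(fu$glycemic_category[fu$sex == s] == "IGT"),
              mean(fu$homa_ir[fu$sex == s])))
cat("wrote results/cohort_phenotyped.csv, results/cohort_summary.tsv\n")
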