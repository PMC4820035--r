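#!/usr/bin/env Rscript
# Step 3: gene-set enrichment on the simulated cohort.
#
# Applies the rare-CNV QC cascade, then runs the nested deviance test
# for every simulated gene set: overall, stratified by CNV type,
# duplication-vs-deletion among case CNVs, and the leave-one-study-out
# sensitivity refit ("minus best"). Bonferroni correction is applied
# over the tested family. Only the TARGET set carries injected
# enrichment; the background sets are the negative controls.

suppressPackageStartupMessages(library(cnvenrich))

cn <- read_cnv_table("results/cohort/cnvs.tsv")$cnvs
cohorts <- read_cohort_table("results/cohort/cohorts.tsv")
genes <- read_interval_bed("results/cohort/genes.bed")$intervals
sets <- read_gmt("results/cohort/sets.gmt")$sets

qc <- qc_cnvs(cn, cohorts, min_length_bp = 5e5)
cat(sprintf("QC: %d CNVs in, %d retained, %d excluded\n",
            nrow(cn), nrow(qc$cnvs), nrow(qc$excluded)))
cnvs <- qc$cnvs
index <- build_gene_index(genes)
hits <- genes_hit(cnvs, index)

rows <- lapply(names(sets), function(id) {
  tg <- test_gene_set(cnvs, index, sets[[id]], set_id = id, hits = hits)
  lo <- leave_one_study_out(cnvs, index, sets[[id]], set_id = id, hits = hits)
  dvd <- differential_dup_del(cnvs[cnvs$is_case == 1L, ], index, sets[[id]],
                              set_id = id, hits = hits[cnvs$is_case == 1L])
  all_row <- tg[tg$stratum == "ALL", ]
  data.frame(set_id = id, n_genes = length(sets[[id]]),
             P = all_row$p_value,
             P_minus_best = lo$minus_best$p_value,
             best_study = lo$best_study,
             P_del = tg$p_value[tg$stratum == "DEL"],
             P_dup = tg$p_value[tg$stratum == "DUP"],
             P_dup_vs_del = dvd$p_value,
             beta_hit = all_row$beta_hit,
             n_case_hits = all_row$n_case_hits,
             n_control_hits = all_row$n_control_hits)
})
tab <- do.call(rbind, rows)
tab$P_bonferroni <- bonferroni_adjust(tab$P, m = nrow(tab))
write_results_tsv(tab, "results/enrichment.tsv")

cat("\nHypothesis-set enrichment (results/enrichment.tsv):\n")
print(tab[, c("set_id", "n_genes", "P", "P_minus_best", "P_del", "P_dup",
              "beta_hit", "P_bonferroni")], row.names = FALSE, digits = 3)
cat("\nExpected pattern: TARGET significant with beta_hit near the injected\n")
cat("0.7 and robust to dropping its best study; background sets null.\n")
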