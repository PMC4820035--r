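#!/usr/bin/env Rscript
# Step 4: hypothesis-free screen.
#
# Runs every simulated set through the screen rules (3-1500 genes, at
# least 10 gene hits in the total sample) and attaches Storey q-values.
# With only a handful of sets the q-values are illustrative; the screen
# machinery itself is validated in the test suite against a direct
# implementation of the formula and by null simulation.

suppressPackageStartupMessages(library(cnvenrich))

cn <- read_cnv_table("results/cohort/cnvs.tsv")$cnvs
cohorts <- read_cohort_table("results/cohort/cohorts.tsv")
genes <- read_interval_bed("results/cohort/genes.bed")$intervals
sets <- read_gmt("results/cohort/sets.gmt")$sets

cnvs <- qc_cnvs(cn, cohorts, min_length_bp = 5e5)$cnvs
index <- build_gene_index(genes)

sc <- pathway_screen(cnvs, index, sets)
write_results_tsv(sc$results[, c("set_id", "n_genes", "n_hits", "lrt_stat",
                                 "p_value", "beta_hit", "q_value")],
                  "results/screen.tsv")
cat(sprintf("Screen: %d sets tested, %d excluded, pi0 = %.3f\n",
            nrow(sc$results), nrow(sc$exclusions), sc$pi0))
print(sc$results[order(sc$results$p_value),
                 c("set_id", "n_genes", "n_hits", "p_value", "q_value")],
      row.names = FALSE, digits = 3)
if (nrow(sc$exclusions)) {
  cat("\nExcluded sets:\n")
  print(sc$exclusions, row.names = FALSE)
}
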