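#!/usr/bin/env Rscript
# Step 1: simulate the study cohort.
#
# Builds a five-study case-control CNV data set that mirrors the pooled
# ADHD analysis: the published cohort sizes, per-subject CNV rates near
# the published per-study values, each study's duplication share, and a
# target gene set carrying an injected case-enrichment of log-odds 0.7.
# Inputs for the later steps are written as plain text under
# results/cohort/ in the package's own formats.

suppressPackageStartupMessages(library(cnvenrich))

seed <- 20260921 %% 100000
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed,
                        enrichment = list(target_set_id = "TARGET",
                                          beta_hit = 0.7, applied_to = "ALL"))
sim <- simulate_genomic_dataset(cfg)

write_cnv_table(sim$cnvs, file.path(out, "cnvs.tsv"))
writeLines(sprintf("%s\t%d\t%d\t%s", sim$genes$chrom, as.integer(sim$genes$start),
                   as.integer(sim$genes$end), sim$genes$gene_id),
           file.path(out, "genes.bed"))
write_gmt(sim$sets, file.path(out, "sets.gmt"))
write_cohort_table(sim$cohorts, file.path(out, "cohorts.tsv"))

cat("Simulated cohort written to", out, "\n")
cat(sprintf("  %d CNVs across %d studies (%d cases, %d controls)\n",
            nrow(sim$cnvs), nrow(sim$cohorts),
            sum(sim$cohorts$n_cases), sum(sim$cohorts$n_controls)))
cat(sprintf("  %d genes on %d chromosomes; target set of %d genes, injected beta_hit = %.2f\n",
            nrow(sim$genes), length(unique(sim$genes$chrom)),
            length(sim$sets[["TARGET"]]), cfg$enrichment$beta_hit))
cat(sprintf("  baseline target-hit probability %.3f, relocation probability %.3f\n",
            sim$injection$q0, sim$injection$relocation_prob))
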