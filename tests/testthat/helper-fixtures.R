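# Shared fixtures, generated once per session in tempdir.

fixture_env <- new.env(parent = emptyenv())

fixture_suite <- function() {
  if (is.null(fixture_env$paths)) {
    dir <- file.path(tempdir(), "cnvenrich-fixtures")
    fixture_env$paths <- make_fixture_suite(dir, seed = 42)
  }
  fixture_env$paths
}

# Standard pipeline configuration over the fixture suite; used by both
# the pipeline tests and the frozen-bundle regression.
fixture_pipeline_config <- function(out_dir, ...) {
  fx <- fixture_suite()
  pipeline_config(
    cnv_file = fx[["cnvs"]], cohort_file = fx[["cohorts"]],
    gene_bed = fx[["genes"]], mask_beds = fx[["masks"]],
    hypothesis_gmt = fx[["gmt"]], screen_gmt = fx[["gmt"]],
    out_dir = out_dir,
    # toy scale: 450 subjects and a 18-Mb genome make recurrence common,
    # so the frequency cutoff is widened in proportion
    qc = list(min_length_bp = 2.5e5, max_freq = 0.05),
    screen = list(min_hits = 10),
    ...)
}

# Tiny hand-built world: one chromosome, three genes, explicit CNVs.
toy_genes <- function() {
  interval_table(chrom = c("1", "1", "1", "2"),
                 start = c(100, 400, 800, 100),
                 end = c(200, 600, 1000, 300),
                 gene_id = c("GA", "GB", "GC", "GD"))
}

toy_cnv <- function(sample_id, study_id, is_case, chrom, start, end, type) {
  cnv_table(sample_id, study_id, is_case, chrom, start, end, type)
}

# A toy cohort where enrichment is concentrated in case DUPs hitting
# gene GB (case DUPs hit with probability 0.8, everything else 0.1, so
# no stratum is fully separated and the DUP < ALL < DEL p ordering is
# strict); lengths/study mixed so covariates are estimable.
toy_cohort_dup_enriched <- function() {
  n <- 120
  set.seed(7)
  rows <- data.frame(
    sample_id = sprintf("s%03d", 1:n),
    study_id = rep(c("X", "X", "Y"), n / 3),
    is_case = rep(c(1L, 0L), each = n / 2),
    chrom = "1",
    cnv_type = rep(c("DUP", "DEL"), n / 2),
    stringsAsFactors = FALSE)
  p_hit <- ifelse(rows$is_case == 1L & rows$cnv_type == "DUP", 0.7, 0.25)
  on_gene <- runif(n) < p_hit
  rows$start <- ifelse(on_gene, 450, 1200)
  rows$end <- rows$start + sample(c(120, 150, 180), n, replace = TRUE)
  validate_cnv_table(rows)
}
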