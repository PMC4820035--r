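test_that("intercept-only fit reaches the closed-form deviance and drops aliased terms", {
  rows <- data.frame(y = c(1, 0, 1, 0), study_id = "A",
                     length_scaled = 5, n_genes_outside = 2L,
                     hit_in_set = 0L, cnv_type = "DEL")
  # constant covariates are aliased with the intercept and dropped
  expect_warning(fit <- fit_logistic(rows, include_hit_term = FALSE), "aliased")
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0, tolerance = 1e-8)
  expect_equal(fit$deviance, -2 * 4 * log(0.5), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_false(fit$separation_flag)
})

test_that("degenerate outcomes and constant hit indicators are handled per contract", {
  rows <- simulate_design_rows(30, seed = 5)
  allcase <- rows; allcase$y <- 1
  expect_error(fit_logistic(allcase), "degenerate outcome")
  const <- rows; const$hit_in_set <- 1L
  res <- lrt_enrichment(const)
  expect_equal(res$lrt_stat, 0)
  expect_equal(res$p_value, 1)
  expect_match(res$note, "constant")
})

test_that("deviances match a hand-coded Newton likelihood oracle on small designs", {
  # fixed 12-row design with all covariates
  d12 <- random_small_design(900, n = 12)
  for (s in 901:950) { if (!is.null(d12)) break; d12 <- random_small_design(s, n = 12) }
  expect_false(is.null(d12))
  f1 <- fit_logistic(d12, include_hit_term = TRUE)
  X1 <- model.matrix(~ factor(study_id) + length_scaled + n_genes_outside + hit_in_set, d12)
  expect_equal(f1$deviance, oracle_logistic_deviance(X1, d12$y), tolerance = 1e-6)

  # random designs: deviance-difference statistic vs the oracle
  designs <- collect_small_designs(8, seed0 = 300)
  for (d in designs) {
    got <- lrt_enrichment(d)
    expect_equal(got$lrt_stat, oracle_lrt(d), tolerance = 1e-6)
  }
})

test_that("quasi-separation is flagged and the Firth option tames it", {
  # hits occur only in cases -> ML estimate diverges
  rows <- data.frame(
    y = rep(c(1, 0), each = 12),
    study_id = rep(c("A", "B"), 12),
    length_scaled = rep(c(5, 6, 7), 8),
    n_genes_outside = rep(c(1L, 2L), 12),
    hit_in_set = c(rep(1L, 6), rep(0L, 18)),
    cnv_type = "DEL")
  fit <- fit_logistic(rows)
  expect_true(fit$separation_flag)
  firth <- fit_logistic(rows, firth = TRUE)
  expect_false(firth$separation_flag)
  expect_lt(abs(firth$coefficients["hit_in_set"]), 15)
})

test_that("stratified testing orders p-values as constructed and flags empty strata", {
  cnvs <- toy_cohort_dup_enriched()
  idx <- build_gene_index(toy_genes())
  res <- suppressWarnings(test_gene_set(cnvs, idx, "GB", set_id = "GB"))
  p <- setNames(res$p_value, res$stratum)
  # enrichment was injected only in case DUPs
  expect_lt(p[["DUP"]], p[["ALL"]])
  expect_lt(p[["ALL"]], p[["DEL"]])
  # ALL stratum is exactly lrt_enrichment on the full design
  rows <- build_design(cnvs, idx, "GB")
  direct <- suppressWarnings(lrt_enrichment(rows, set_id = "GB"))
  expect_equal(res$p_value[res$stratum == "ALL"], direct$p_value)
  expect_equal(res$lrt_stat[res$stratum == "ALL"], direct$lrt_stat)

  # a stratum lacking one outcome class is not estimable, not an error
  dels_gone <- cnvs[cnvs$cnv_type == "DUP" | cnvs$is_case == 1L, ]
  res2 <- suppressWarnings(test_gene_set(dels_gone, idx, "GB", set_id = "GB"))
  expect_false(res2$estimable[res2$stratum == "DEL"])
})

test_that("duplication-vs-deletion comparison recodes the outcome and reports direction", {
  idx <- build_gene_index(toy_genes())
  n <- 40
  set.seed(9)
  # place: DUPs on the gene, DELs off it; study varies independently of
  # type so the hit indicator is not collinear with the study term
  type <- rep(c("DUP", "DEL"), n / 2)
  start <- ifelse(type == "DUP", 450, 1200)
  cases <- cnv_table(sprintf("c%02d", 1:n), rep(c("X", "X", "Y", "Y"), n / 4), 1L, "1",
                     start, start + 150, type)
  res <- suppressWarnings(differential_dup_del(cases, idx, "GB"))
  expect_equal(res$stratum, "DUP_VS_DEL")
  expect_gt(res$beta_hit, 0)   # all set hits are duplications
  # identity with lrt_enrichment on recoded rows
  rows <- build_design(cases, idx, "GB")
  rows$y <- as.integer(cases$cnv_type == "DUP")
  expect_equal(res$p_value, suppressWarnings(lrt_enrichment(rows, stratum = "DUP_VS_DEL"))$p_value)
  # single-type input is a degenerate outcome
  expect_error(suppressWarnings(differential_dup_del(cases[cases$cnv_type == "DUP", ], idx, "GB")),
               "degenerate")
})

test_that("leave-one-study-out finds the driving study and weakens p without it", {
  idx <- build_gene_index(toy_genes())
  set.seed(13)
  mk <- function(study, n, hit_frac_case) {
    is_case <- rep(c(1L, 0L), each = n / 2)
    on_gene <- ifelse(is_case == 1L, runif(n) < hit_frac_case, runif(n) < 0.1)
    start <- ifelse(on_gene, 450, 1200)
    cnv_table(sprintf("%s%03d", study, 1:n), study, is_case, "1",
              start, start + sample(c(120, 160), n, replace = TRUE),
              sample(c("DEL", "DUP"), n, replace = TRUE))
  }
  # enrichment injected only in study A
  cnvs <- rbind(mk("A", 60, 0.8), mk("B", 60, 0.1), mk("C", 60, 0.1))
  cnvs <- validate_cnv_table(cnvs)
  lo <- suppressWarnings(leave_one_study_out(cnvs, idx, "GB", set_id = "GB"))
  expect_equal(lo$best_study, "A")
  full <- suppressWarnings(lrt_enrichment(build_design(cnvs, idx, "GB"), set_id = "GB"))
  expect_gt(lo$minus_best$p_value, full$p_value)
  expect_equal(nrow(lo$loso), 3)
  expect_error(suppressWarnings(leave_one_study_out(cnvs[cnvs$study_id == "A", ], idx, "GB")),
               "two studies")

  # two statistically identical studies: tie broken lexicographically
  dup2 <- mk("B", 60, 0.5)
  dup1 <- dup2
  dup1$study_id <- "A"
  dup1$sample_id <- sub("^B", "A", dup1$sample_id)
  tie <- validate_cnv_table(rbind(dup1, dup2))
  lo2 <- suppressWarnings(leave_one_study_out(tie, idx, "GB"))
  expect_equal(lo2$best_study, "A")
})

test_that("gene-wise scan equals singleton-set tests and skips unhit genes", {
  cnvs <- toy_cohort_dup_enriched()
  genes <- toy_genes()
  idx <- build_gene_index(genes)
  sc <- suppressWarnings(gene_wise_scan(cnvs, idx))
  # only GB is ever hit in this toy
  expect_equal(sc$results$set_id, "GB")
  expect_equal(sc$n_skipped, 3)
  expect_gt(sc$results$beta_hit, 0)
  direct <- suppressWarnings(test_gene_set(cnvs, idx, "GB", set_id = "GB", strata = "ALL"))
  expect_equal(sc$results$p_value, direct$p_value)
  expect_equal(sc$results$lrt_stat, direct$lrt_stat)
})

test_that("pathway screen applies size and min-hit rules before testing", {
  fx <- fixture_suite()
  cn <- read_cnv_table(fx[["cnvs"]])$cnvs
  genes <- read_interval_bed(fx[["genes"]])$intervals
  sets <- read_gmt(fx[["gmt"]])$sets
  idx <- build_gene_index(genes)
  sc <- pathway_screen(cn, idx, sets, min_set_genes = 3, max_set_genes = 1500,
                       min_hits = 10)
  # the 2-gene TINY set is excluded before testing
  expect_true("TINY" %in% sc$exclusions$set_id)
  expect_match(sc$exclusions$reason[sc$exclusions$set_id == "TINY"], "size")
  expect_false("TINY" %in% sc$results$set_id)
  expect_true(all(sc$results$q_value >= 0 & sc$results$q_value <= 1))

  # boundary: a set with exactly 9 incidence hits is excluded at min_hits = 10
  idx9 <- build_gene_index(toy_genes())
  one_gene_hits <- cnv_table(sprintf("h%02d", 1:9), "A", rep(c(1L, 0L), length.out = 9),
                             "1", 450, 600, "DEL")
  filler <- cnv_table(sprintf("f%02d", 1:6), "A", rep(c(1L, 0L), 3), "1", 1200, 1400, "DEL")
  toy <- validate_cnv_table(rbind(one_gene_hits, filler))
  sets9 <- gene_set_list(c("S9", "BGX"), list(c("GB", "GC", "GD"), c("GA", "GC", "GD")))
  sc9 <- suppressWarnings(pathway_screen(toy, idx9, sets9, min_hits = 10))
  expect_true("S9" %in% sc9$exclusions$set_id)
  expect_match(sc9$exclusions$reason[sc9$exclusions$set_id == "S9"], "9 gene hits")
  # at min_hits = 9 the same set is tested
  sc8 <- suppressWarnings(pathway_screen(toy, idx9, sets9, min_hits = 9))
  expect_true("S9" %in% sc8$results$set_id)
  # distinct-CNV counting mode counts 9 as well here (one set gene hit per CNV)
  scd <- suppressWarnings(pathway_screen(toy, idx9, sets9, min_hits = 10, hit_count_mode = "distinct_cnvs"))
  expect_true("S9" %in% scd$exclusions$set_id)
})

test_that("the LRT statistic is invariant to length rescaling, with reciprocal coefficient", {
  rows <- simulate_design_rows(400, beta = c(intercept = -0.5, study_B = 0.2,
                                             study_C = 0, length_scaled = 0.05,
                                             n_genes_outside = 0.02, hit_in_set = 0.5),
                               seed = 17)
  base <- lrt_enrichment(rows)
  fit <- fit_logistic(rows)
  scaled <- rows; scaled$length_scaled <- rows$length_scaled * 10
  got <- lrt_enrichment(scaled)
  fit2 <- fit_logistic(scaled)
  expect_equal(got$lrt_stat, base$lrt_stat, tolerance = 1e-8)
  expect_equal(unname(fit2$coefficients["length_scaled"]),
               unname(fit$coefficients["length_scaled"]) / 10, tolerance = 1e-6)
})

test_that("adding case-only set-hitting CNVs never weakens the enrichment p-value", {
  # covariate-flat toy: the test reduces to a 2x2 association
  base <- data.frame(y = rep(c(1, 0), each = 20), study_id = "A",
                     length_scaled = 6, n_genes_outside = 1L,
                     hit_in_set = rep(c(1L, 0L, 1L, 0L), c(6, 14, 3, 17)),
                     cnv_type = "DEL")
  p_prev <- suppressWarnings(lrt_enrichment(base)$p_value)
  for (k in 1:5) {
    base <- rbind(base, data.frame(y = 1, study_id = "A", length_scaled = 6,
                                   n_genes_outside = 1L, hit_in_set = 1L,
                                   cnv_type = "DEL"))
    p_now <- suppressWarnings(lrt_enrichment(base)$p_value)
    expect_lte(p_now, p_prev + 1e-12)
    p_prev <- p_now
  }
})
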