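test_that("design-row simulation is seed-deterministic and restores RNG state", {
  a <- simulate_design_rows(200, seed = 5)
  set.seed(999); before <- runif(3)
  set.seed(999)
  b <- simulate_design_rows(200, seed = 5)
  after <- runif(3)   # generator must not disturb the caller's stream
  expect_identical(a, b)
  expect_identical(before, after)
})

test_that("a null hit coefficient leaves hit rates equal across outcome classes", {
  rows <- simulate_design_rows(10000, seed = 19)   # default beta_hit = 0
  r1 <- mean(rows$hit_in_set[rows$y == 1])
  r0 <- mean(rows$hit_in_set[rows$y == 0])
  se <- sqrt(0.15 * 0.85 * (1 / sum(rows$y == 1) + 1 / sum(rows$y == 0)))
  expect_lt(abs(r1 - r0), 4 * se)
})

test_that("the fitted hit coefficient tracks the injected value", {
  beta <- c(intercept = -0.75, study_B = 0.1, study_C = -0.1,
            length_scaled = 0.02, n_genes_outside = 0.01, hit_in_set = 0.7)
  ests <- vapply(1:20, function(i) {
    rows <- simulate_design_rows(4000, beta = beta, seed = 1000 + i)
    unname(fit_logistic(rows)$coefficients["hit_in_set"])
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.7), 0.1)
})

test_that("genomic cohorts are deterministic and round-trip through the readers", {
  cfg <- synthetic_config(seed = 23)
  s1 <- simulate_genomic_dataset(cfg)
  s2 <- simulate_genomic_dataset(cfg)
  expect_identical(s1$cnvs, s2$cnvs)
  expect_identical(s1$genes, s2$genes)

  tmp <- withr::local_tempdir()
  write_cnv_table(s1$cnvs, file.path(tmp, "c.tsv"))
  back <- read_cnv_table(file.path(tmp, "c.tsv"))$cnvs
  expect_equal(as.data.frame(back), as.data.frame(s1$cnvs), ignore_attr = TRUE)
  # genes are non-overlapping within chromosomes
  for (ch in unique(s1$genes$chrom)) {
    g <- s1$genes[s1$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("simulated burden matches the configured study rates", {
  cfg <- synthetic_config(seed = 29)
  sim <- simulate_genomic_dataset(cfg)
  b <- burden_summary(sim$cnvs, sim$cohorts, stratum = "ALL", test = FALSE)
  for (k in seq_len(nrow(cfg$studies))) {
    s <- cfg$studies[k, ]
    row <- b[b$study_id == s$study_id, ]
    # Poisson counts: observed rate within 4 SE of the configured rate
    se_case <- sqrt(s$case_cnv_rate / s$n_cases)
    se_ctrl <- sqrt(s$control_cnv_rate / s$n_controls)
    expect_lt(abs(row$case_rate - s$case_cnv_rate), 4 * se_case)
    expect_lt(abs(row$control_rate - s$control_cnv_rate), 4 * se_ctrl)
  }
})

test_that("a zero-CNV study yields a valid dataset and not-estimable downstream results", {
  cfg <- synthetic_config(
    seed = 31,
    studies = data.frame(
      study_id = c("LIVE", "DEAD"),
      n_cases = c(200L, 5L), n_controls = c(300L, 5L),
      case_cnv_rate = c(0.5, 1e-9), control_cnv_rate = c(0.4, 1e-9),
      dup_fraction = c(0.6, 0.5), stringsAsFactors = FALSE))
  sim <- simulate_genomic_dataset(cfg)
  expect_false("DEAD" %in% sim$cnvs$study_id)
  idx <- build_gene_index(sim$genes)
  res <- test_gene_set(sim$cnvs, idx, sim$sets[["TARGET"]], set_id = "TARGET")
  expect_true(all(res$estimable | !res$estimable))  # no crash; rows present
  b <- burden_summary(sim$cnvs, sim$cohorts, stratum = "ALL", test = FALSE)
  dead <- b[b$study_id == "DEAD", ]
  expect_false(dead$ratio_defined)
})

test_that("fixture suite writes checksum-stable files that parse cleanly", {
  d1 <- file.path(withr::local_tempdir(), "f1")
  d2 <- file.path(withr::local_tempdir(), "f2")
  p1 <- make_fixture_suite(d1, seed = 42)
  p2 <- make_fixture_suite(d2, seed = 42)
  for (k in setdiff(names(p1), "manifest"))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  got <- read_cnv_table(p1[["cnvs"]])
  expect_gt(nrow(got$cnvs), 50)
  expect_equal(nrow(got$errors), 0)
  expect_equal(nrow(read_interval_bed(p1[["genes"]])$intervals), 90)
  expect_length(read_gmt(p1[["gmt"]])$sets, 4)
  expect_equal(nrow(read_cohort_table(p1[["cohorts"]])), 3)
})
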