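mk_cnvs <- function(starts, ends, type = "DEL", chrom = "1",
                    sample = NULL, study = "A", is_case = 1L) {
  n <- length(starts)
  if (is.null(sample)) sample <- sprintf("s%03d", seq_len(n))
  cnv_table(sample, study, is_case, chrom, starts, ends, rep_len(type, n))
}

test_that("size filter is strictly greater-than at the threshold", {
  cnvs <- mk_cnvs(c(0, 0, 0), c(500000, 500001, 250000))
  got <- filter_by_size(cnvs, 5e5)
  expect_equal(got$cnvs$end, 500001)          # exactly 500 kb removed
  expect_equal(got$n_removed, 2)
  # secondary 100 kb window keeps a 250 kb CNV
  got2 <- filter_by_size(cnvs, 1e5)
  expect_true(250000 %in% got2$cnvs$end)
  # idempotent
  expect_equal(filter_by_size(got$cnvs, 5e5)$cnvs, got$cnvs)
  # conservation
  expect_equal(nrow(got$cnvs) + nrow(got$excluded), nrow(cnvs))
})

test_that("mask filter uses union coverage and a strict 50% boundary", {
  masks <- interval_table(chrom = c("1", "1"), start = c(0, 200), end = c(300, 600))
  # CNV [0,1000): union [0,600) covers 0.6 -> excluded
  cnvs <- mk_cnvs(0, 1000)
  expect_equal(mask_coverage_fraction(cnvs, masks),
               oracle_union_coverage(0, 1000, masks))
  expect_equal(filter_common_overlap(cnvs, masks)$n_removed, 1)
  # fully inside a mask -> coverage 1 -> excluded
  inside <- mk_cnvs(100, 250)
  expect_equal(mask_coverage_fraction(inside, masks), 1)
  # coverage exactly 0.50 -> retained
  half <- mk_cnvs(0, 1200)  # union covers 600 of 1200
  expect_equal(mask_coverage_fraction(half, masks), 0.5)
  expect_equal(filter_common_overlap(half, masks)$n_removed, 0)
})

test_that("mask union coverage matches a base-by-base oracle on random toys", {
  set.seed(11)
  for (rep in 1:10) {
    masks <- interval_table(chrom = "1",
                            start = st <- sample(0:900, 5),
                            end = st + sample(50:300, 5, replace = TRUE))
    cnvs <- mk_cnvs(100, 1100)
    expect_equal(mask_coverage_fraction(cnvs, masks),
                 oracle_union_coverage(100, 1100, masks), tolerance = 1e-12)
  }
})

test_that("frequency filter clusters loci by single linkage and removes common ones", {
  cohorts <- cohort_table("A", 400, 600)   # 1000 subjects
  # chain A~B~C: A and C overlap only through B -> one locus of 3
  chain <- mk_cnvs(c(0, 400, 800), c(1000, 1400, 1800),
                   sample = c("x1", "x2", "x3"))
  expect_equal(cluster_cnv_loci(chain, 0.5), oracle_clusters(chain, 0.5))
  expect_equal(length(unique(cluster_cnv_loci(chain, 0.5))), 1)
  # different types never cluster
  mixed <- mk_cnvs(c(0, 100), c(1000, 1100), type = c("DEL", "DUP"))
  expect_equal(length(unique(cluster_cnv_loci(mixed, 0.5))), 2)

  # singleton among 1000 subjects: 0.001 -> retained
  single <- mk_cnvs(0, 1000, sample = "only")
  expect_equal(filter_by_frequency(single, cohorts)$n_removed, 0)
  # 15 carriers of one locus among 1000 subjects: 0.015 -> locus removed
  common <- mk_cnvs(rep(0, 15), rep(1000, 15), sample = sprintf("c%02d", 1:15))
  expect_equal(filter_by_frequency(common, cohorts)$n_removed, 15)
  # exactly 1%: 10 carriers / 1000 subjects -> removed (inclusive rule)
  atboundary <- mk_cnvs(rep(0, 10), rep(1000, 10), sample = sprintf("b%02d", 1:10))
  expect_equal(filter_by_frequency(atboundary, cohorts)$n_removed, 10)
  expect_error(filter_by_frequency(single, cohort_table(character(0), integer(0), integer(0))),
               "cohort")
})

test_that("locus clustering matches the brute-force oracle on random toys", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(4:10, 1)
    st <- sample(0:2000, n, replace = TRUE)
    cnvs <- mk_cnvs(st, st + sample(200:1200, n, replace = TRUE),
                    type = sample(c("DEL", "DUP"), n, replace = TRUE),
                    chrom = sample(c("1", "2"), n, replace = TRUE))
    expect_equal(cluster_cnv_loci(cnvs, 0.5), oracle_clusters(cnvs, 0.5))
  }
})

test_that("the QC cascade conserves records and filters are idempotent", {
  set.seed(31)
  n <- 60
  st <- sample(0:5e6, n)
  cnvs <- mk_cnvs(st, st + sample(c(3e5, 6e5, 9e5), n, replace = TRUE),
                  type = sample(c("DEL", "DUP"), n, replace = TRUE),
                  sample = sprintf("p%03d", 1:n))
  cohorts <- cohort_table("A", 100, 150)
  masks <- interval_table("1", c(1e6, 3e6), c(1.4e6, 3.2e6))
  got <- qc_cnvs(cnvs, cohorts, masks, min_length_bp = 5e5)
  expect_equal(nrow(got$cnvs) + nrow(got$excluded), n)
  # re-running QC on its own output removes nothing new except frequency
  # reclustering, which is computed on the already-filtered set
  again <- qc_cnvs(got$cnvs, cohorts, masks, min_length_bp = 5e5)
  expect_equal(nrow(again$cnvs), nrow(got$cnvs))
})
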