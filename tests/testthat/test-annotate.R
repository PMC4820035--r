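test_that("gene index queries agree with an all-pairs scan on random genomes", {
  set.seed(41)
  st <- sample(0:9e5, 200)
  genes <- interval_table(chrom = sample(c("1", "2", "3"), 200, replace = TRUE),
                          start = st, end = st + sample(1e3:5e4, 200, replace = TRUE),
                          gene_id = sprintf("g%03d", 1:200))
  idx <- build_gene_index(genes)
  qs <- sample(0:9e5, 50)
  queries <- cnv_table(sprintf("q%02d", 1:50), "A", 1L,
                       sample(c("1", "2", "3"), 50, replace = TRUE),
                       qs, qs + sample(1e3:2e5, 50, replace = TRUE), "DEL")
  got <- genes_hit(queries, idx)
  for (i in 1:50)
    expect_equal(sort(got[[i]]),
                 oracle_overlaps(queries$chrom[i], queries$start[i], queries$end[i], genes))
})

test_that("hits use half-open semantics; whole-chromosome CNVs hit everything", {
  genes <- toy_genes()
  idx <- build_gene_index(genes)
  hit <- function(s, e, chrom = "1")
    genes_hit(cnv_table("s", "A", 1L, chrom, s, e, "DEL"), idx)[[1]]
  expect_equal(hit(100, 200), "GA")       # CNV [100,200) x gene [100,200)
  expect_equal(hit(50, 101), "GA")        # 1-bp overlap counts
  expect_equal(hit(200, 300), character(0))  # abutment is not overlap
  expect_equal(hit(0, 2000), c("GA", "GB", "GC"))
  expect_equal(hit(0, 2000, chrom = "2"), "GD")
  expect_error(build_gene_index(genes[c(1, 1), ]), "duplicate gene_id")
})

test_that("design rows cover every CNV and count genes outside the set", {
  genes <- toy_genes()
  idx <- build_gene_index(genes)
  cnvs <- cnv_table(c("s1", "s2"), "A", c(1L, 0L), "1",
                    c(0, 1200), c(2000, 1500), c("DUP", "DEL"))
  rows <- build_design(cnvs, idx, set = "GB")
  # s1 hits GA,GB,GC; set {GB} -> hit 1, outside 2
  expect_equal(rows$hit_in_set, c(1L, 0L))
  expect_equal(rows$n_genes_outside, c(2L, 0L))
  # gene-desert CNV keeps its row with (0, 0)
  expect_equal(nrow(rows), 2)
  expect_equal(rows$length_scaled, (cnvs$end - cnvs$start) / 1e5)
})

test_that("design construction is invariant to CNV and gene order, and hit sums match brute force", {
  set.seed(43)
  st <- sample(0:5e5, 40)
  genes <- interval_table("1", st, st + sample(1e3:3e4, 40, replace = TRUE),
                          gene_id = sprintf("g%02d", 1:40))
  cs <- sample(0:5e5, 25)
  cnvs <- cnv_table(sprintf("s%02d", 1:25), "A", rep(c(1L, 0L), length.out = 25),
                    "1", cs, cs + sample(2e4:2e5, 25, replace = TRUE), "DEL")
  set <- sample(genes$gene_id, 8)
  idx <- build_gene_index(genes)
  rows <- build_design(cnvs, idx, set)

  # permuted genes and permuted CNVs give the same rows (up to CNV order)
  perm_g <- sample(40); perm_c <- sample(25)
  idx2 <- build_gene_index(genes[perm_g, ])
  rows2 <- build_design(cnvs[perm_c, ], idx2, set)
  expect_equal(rows2[order(perm_c), ], rows, ignore_attr = TRUE)

  # brute-force count of set-hitting CNVs
  brute <- sum(vapply(1:25, function(i) {
    hits <- oracle_overlaps(cnvs$chrom[i], cnvs$start[i], cnvs$end[i], genes)
    any(hits %in% set)
  }, logical(1)))
  expect_equal(sum(rows$hit_in_set), brute)

  # singleton-set identity: outside + inside = total genes hit, per row
  g1 <- genes$gene_id[1]
  rows1 <- build_design(cnvs, idx, g1)
  tot <- lengths(genes_hit(cnvs, idx))
  expect_equal(rows1$n_genes_outside + rows1$hit_in_set, tot)
})
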