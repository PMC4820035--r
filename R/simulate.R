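# Seeded generators: (a) regression rows drawn from the exact CNV-level
# logistic model, for calibration and parameter-recovery studies; (b)
# full genomic multi-study cohorts with enrichment injected at the
# CNV-placement level, for end-to-end pipeline validation. All
# randomness flows from the seed argument; the caller's RNG state is
# saved and restored.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

#' Simulate regression rows from the CNV-level logistic model
#'
#' Draws covariates — CNV length from a truncated log-normal (expressed
#' in 100-kb units), genes-hit-outside from a Poisson, and the set-hit
#' indicator from a study-specific Bernoulli — and then the case label
#' from `Bernoulli(plogis(x %*% beta))`. This is the exact model the
#' enrichment test fits, so it is the reference generator for type-I
#' error and coefficient-recovery studies.
#'
#' The default covariate mix mirrors a pooled rare-CNV case-control
#' data set in the >500 kb window: a roughly one-third case share of
#' CNVs, lengths centred near 700 kb with a heavy right tail truncated
#' at 5 Mb, a handful of genes per CNV, and a 15% baseline set-hit rate.
#'
#' @param n number of rows.
#' @param beta named coefficient vector: `intercept`, one `study_<id>`
#'   term per non-reference study, `length_scaled`, `n_genes_outside`,
#'   `hit_in_set`.
#' @param study_mix named probabilities over study labels (first label in
#'   sort order is the model's reference study).
#' @param hit_rate baseline set-hit probability; scalar or named per study.
#' @param length_meanlog,length_sdlog,length_range_bp truncated
#'   log-normal for CNV length in bp.
#' @param genes_lambda Poisson mean of genes hit outside the set.
#' @param seed RNG seed.
#' @return design-row data.frame as from [build_design()] (with
#'   `cnv_type` drawn independently, 50/50, for bookkeeping).
#' @export
simulate_design_rows <- function(n,
                                 beta = c(intercept = -0.75, study_B = 0.1,
                                          study_C = -0.1, length_scaled = 0.02,
                                          n_genes_outside = 0.01, hit_in_set = 0),
                                 study_mix = c(A = 0.4, B = 0.35, C = 0.25),
                                 hit_rate = 0.15,
                                 length_meanlog = log(7e5), length_sdlog = 0.45,
                                 length_range_bp = c(5e5, 5e6),
                                 genes_lambda = 3,
                                 seed = 1) {
  if (abs(sum(study_mix) - 1) > 1e-8 || any(study_mix < 0))
    stop("study_mix must be non-negative proportions summing to 1")
  studies <- sort(names(study_mix))
  with_seed(seed, {
    study <- sample(names(study_mix), n, replace = TRUE, prob = study_mix)
    len <- rlnorm_trunc(n, length_meanlog, length_sdlog,
                        length_range_bp[1], length_range_bp[2]) / 1e5
    genes_out <- stats::rpois(n, genes_lambda)
    hr <- if (length(hit_rate) == 1L) rep(hit_rate, length(studies))
          else hit_rate[studies]
    hit <- stats::rbinom(n, 1, hr[match(study, studies)])
    eta <- rep(unname(beta["intercept"]), n)
    for (s in studies[-1]) {
      b <- beta[paste0("study_", s)]
      if (!is.na(b)) eta <- eta + ifelse(study == s, unname(b), 0)
    }
    eta <- eta + unname(beta["length_scaled"]) * len +
      unname(beta["n_genes_outside"]) * genes_out +
      unname(beta["hit_in_set"]) * hit
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    data.frame(y = y, study_id = study, length_scaled = len,
               n_genes_outside = genes_out, hit_in_set = hit,
               cnv_type = sample(c("DEL", "DUP"), n, replace = TRUE),
               sample_id = sprintf("sim%06d", seq_len(n)),
               stringsAsFactors = FALSE)
  })
}

#' Configuration for a simulated multi-study CNV cohort
#'
#' Defaults emulate the pooled five-study ADHD case-control data set:
#' the published cohort sizes, per-subject CNV rates near the published
#' per-study values, and each study's duplication share, on a scaled-down
#' genome (CNV placement cares only about local gene density, so a
#' 100-Mb genome with ~1000 genes preserves the hit geometry at a
#' fraction of the cost).
#'
#' @param seed RNG seed; every downstream draw flows from it.
#' @param studies data.frame: `study_id, n_cases, n_controls,
#'   case_cnv_rate, control_cnv_rate, dup_fraction` (rates are expected
#'   CNVs per subject in the analysis window).
#' @param genome list: `n_chromosomes`, `chromosome_length_bp`,
#'   `n_genes`, `gene_length_meanlog`, `gene_length_sdlog`.
#' @param sets data.frame `set_id, n_genes`: gene sets sampled uniformly
#'   (and independently, so sets may overlap) from the simulated genes.
#' @param cnv_length list `meanlog, sdlog, min_bp, max_bp`: truncated
#'   log-normal CNV lengths with a heavy >500 kb tail.
#' @param enrichment list `target_set_id, beta_hit, applied_to`
#'   (`"ALL"`, `"DUP"` or `"DEL"`): case CNVs of the chosen type have
#'   their odds of hitting the target set multiplied by
#'   `exp(beta_hit)` relative to control CNVs.
#' @return classed list `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1,
    studies = data.frame(
      study_id = c("CANADA", "CARDIFF", "CHOP", "IMAGE2", "PUWMA"),
      n_cases = c(247L, 603L, 1013L, 732L, 692L),
      n_controls = c(2357L, 1047L, 4105L, 2010L, 1101L),
      case_cnv_rate = c(0.089, 0.108, 0.217, 0.122, 0.085),
      control_cnv_rate = c(0.092, 0.074, 0.093, 0.095, 0.078),
      dup_fraction = c(0.77, 0.82, 0.82, 0.75, 0.63),
      stringsAsFactors = FALSE),
    genome = list(n_chromosomes = 10L, chromosome_length_bp = 1e7,
                  n_genes = 1000L, gene_length_meanlog = log(3e4),
                  gene_length_sdlog = 0.8),
    sets = data.frame(set_id = c("TARGET", paste0("BG", 1:4)),
                      n_genes = c(60L, 40L, 80L, 25L, 120L),
                      stringsAsFactors = FALSE),
    cnv_length = list(meanlog = log(7e5), sdlog = 0.45,
                      min_bp = 5e5, max_bp = 5e6),
    enrichment = list(target_set_id = "TARGET", beta_hit = 0,
                      applied_to = "ALL")) {
  stopifnot(all(studies$case_cnv_rate > 0), all(studies$control_cnv_rate > 0),
            all(studies$dup_fraction >= 0 & studies$dup_fraction <= 1),
            is.finite(enrichment$beta_hit))
  structure(list(seed = seed, studies = studies, genome = genome, sets = sets,
                 cnv_length = cnv_length, enrichment = enrichment),
            class = "synthetic_config")
}

place_genes <- function(genome, rng_ok = TRUE) {
  n_chr <- genome$n_chromosomes
  chroms <- sprintf("S%02d", seq_len(n_chr))
  per_chr <- diff(round(seq(0, genome$n_genes, length.out = n_chr + 1)))
  rows <- list()
  gid <- 0L
  for (i in seq_len(n_chr)) {
    k <- per_chr[i]
    if (!k) next
    lens <- pmax(1000, round(stats::rlnorm(k, genome$gene_length_meanlog,
                                           genome$gene_length_sdlog)))
    slack <- genome$chromosome_length_bp - sum(lens)
    if (slack <= k) stop("genome too small for requested genes")
    gaps <- stats::rexp(k + 1)
    gaps <- floor(gaps / sum(gaps) * slack)
    start <- cumsum(gaps[seq_len(k)]) + c(0, cumsum(lens))[seq_len(k)]
    rows[[i]] <- data.frame(chrom = chroms[i], start = start, end = start + lens,
                            gene_id = sprintf("G%04d", gid + seq_len(k)),
                            stringsAsFactors = FALSE)
    gid <- gid + k
  }
  df <- do.call(rbind, rows)
  interval_table(df$chrom, df$start, df$end, gene_id = df$gene_id)
}

draw_cnv_interval <- function(cfg, chr_len, chroms) {
  len <- rlnorm_trunc(1, cfg$cnv_length$meanlog, cfg$cnv_length$sdlog,
                      cfg$cnv_length$min_bp, min(cfg$cnv_length$max_bp, chr_len))
  len <- round(len)
  chrom <- sample(chroms, 1)
  start <- floor(stats::runif(1, 0, chr_len - len))
  c(start = start, end = start + len, chrom = match(chrom, chroms))
}

#' Simulate a full genomic multi-study CNV cohort
#'
#' Places non-overlapping genes on the configured genome, samples gene
#' sets, then draws per-subject CNV counts from a Poisson with the
#' study's case or control rate, assigns DEL/DUP by the study's
#' duplication share, and places each CNV uniformly with a truncated
#' log-normal length. Enrichment is injected at placement: a case CNV of
#' the targeted type that misses the target set is, with the rejection
#' probability implied by `beta_hit`, relocated to overlap a uniformly
#' chosen target-set gene — so length and gene-density covariates stay
#' identically distributed between cases and controls and any recovered
#' hit coefficient is attributable to the injected enrichment.
#'
#' @param config a [synthetic_config()].
#' @return list: `cnvs` (`cnv_table`), `genes` (`interval_table`), `sets`
#'   (`gene_set_list`), `cohorts` (`cohort_table`), plus
#'   `injection` diagnostics (baseline hit probability `q0`, target hit
#'   probability `q1`, relocation probability).
#' @export
simulate_genomic_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    genes <- place_genes(cfg$genome)
    chroms <- unique(genes$chrom)
    chr_len <- cfg$genome$chromosome_length_bp
    ids <- lapply(seq_len(nrow(cfg$sets)), function(i)
      sort(sample(genes$gene_id, cfg$sets$n_genes[i])))
    sets <- gene_set_list(cfg$sets$set_id, ids, source = "synthetic")
    target <- sets[[cfg$enrichment$target_set_id]]
    tgenes <- genes[genes$gene_id %in% target, , drop = FALSE]
    index <- build_gene_index(genes)

    # baseline probability that a uniformly placed CNV hits the target
    # set, estimated by seeded Monte Carlo phantom placements
    m0 <- 400L
    phantom <- t(vapply(seq_len(m0), function(i) draw_cnv_interval(cfg, chr_len, chroms),
                        numeric(3)))
    ph <- cnv_table(sample_id = sprintf("ph%d", seq_len(m0)), study_id = "ph",
                    is_case = 0L, chrom = chroms[phantom[, 3]],
                    start = phantom[, 1], end = phantom[, 2], cnv_type = "DEL")
    q0 <- mean(vapply(genes_hit(ph, index), function(h) any(h %in% target), logical(1)))
    q0 <- min(max(q0, 1 / m0), 1 - 1 / m0)
    or <- exp(cfg$enrichment$beta_hit)
    q1 <- or * q0 / (1 - q0 + or * q0)
    rho <- max(0, (q1 - q0) / (1 - q0))

    rows <- list()
    for (k in seq_len(nrow(cfg$studies))) {
      st <- cfg$studies[k, ]
      for (grp in c("case", "control")) {
        n_subj <- if (grp == "case") st$n_cases else st$n_controls
        rate <- if (grp == "case") st$case_cnv_rate else st$control_cnv_rate
        counts <- stats::rpois(n_subj, rate)
        for (i in which(counts > 0)) {
          for (j in seq_len(counts[i])) {
            iv <- draw_cnv_interval(cfg, chr_len, chroms)
            type <- if (stats::runif(1) < st$dup_fraction) "DUP" else "DEL"
            chrom <- chroms[iv[["chrom"]]]
            start <- iv[["start"]]; end <- iv[["end"]]
            eligible <- grp == "case" && rho > 0 &&
              (cfg$enrichment$applied_to == "ALL" || cfg$enrichment$applied_to == type)
            if (eligible) {
              hit <- any(tgenes$chrom == chrom & tgenes$start < end & tgenes$end > start)
              if (!hit && stats::runif(1) < rho) {
                g <- tgenes[sample(nrow(tgenes), 1), ]
                len <- end - start
                lo <- max(0, g$start - len + 1)
                hi <- min(chr_len - len, g$end - 1)
                start <- floor(stats::runif(1, lo, max(lo, hi)))
                end <- start + len
                chrom <- g$chrom
              }
            }
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sprintf("%s_%s_%05d", st$study_id, grp, i),
              study_id = st$study_id, is_case = as.integer(grp == "case"),
              chrom = chrom, start = start, end = end, cnv_type = type,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    cnvs <- if (length(rows)) validate_cnv_table(do.call(rbind, rows))
            else empty_cnv_table()
    list(cnvs = cnvs, genes = genes, sets = sets,
         cohorts = cohort_table(cfg$studies$study_id, cfg$studies$n_cases,
                                cfg$studies$n_controls),
         injection = list(q0 = q0, q1 = q1, relocation_prob = rho))
  })
}

#' Write the small worked fixture suite
#'
#' Materialises the fixtures the test suite and the frozen pipeline
#' regression use: a 16-row design table, a 3-study toy cohort (CNV tsv,
#' gene BED, mask BED, GMT, cohort tsv), all parseable by the package's
#' own readers, plus an md5 checksum manifest. Identical seeds yield
#' identical files.
#'
#' @param out_dir writable directory (created if needed).
#' @param seed RNG seed.
#' @return named character vector of file paths (with the checksum
#'   manifest last), invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 42) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- synthetic_config(
    seed = seed,
    studies = data.frame(
      study_id = c("ALPHA", "BETA", "GAMMA"),
      n_cases = c(60L, 80L, 50L), n_controls = c(90L, 100L, 70L),
      case_cnv_rate = c(0.8, 0.7, 0.9), control_cnv_rate = c(0.5, 0.5, 0.5),
      dup_fraction = c(0.6, 0.7, 0.5), stringsAsFactors = FALSE),
    genome = list(n_chromosomes = 3L, chromosome_length_bp = 6e6,
                  n_genes = 90L, gene_length_meanlog = log(2e4),
                  gene_length_sdlog = 0.6),
    sets = data.frame(set_id = c("TARGET", "BG1", "BG2", "TINY"),
                      n_genes = c(18L, 25L, 12L, 2L), stringsAsFactors = FALSE),
    cnv_length = list(meanlog = log(4e5), sdlog = 0.4, min_bp = 2e5, max_bp = 2e6),
    enrichment = list(target_set_id = "TARGET", beta_hit = 1.2, applied_to = "ALL"))
  sim <- simulate_genomic_dataset(cfg)
  paths <- c(
    cnvs = file.path(out_dir, "cohort_cnvs.tsv"),
    genes = file.path(out_dir, "genes.bed"),
    masks = file.path(out_dir, "masks.bed"),
    gmt = file.path(out_dir, "sets.gmt"),
    cohorts = file.path(out_dir, "cohorts.tsv"),
    design = file.path(out_dir, "design16.tsv"))
  write_cnv_table(sim$cnvs, paths[["cnvs"]])
  writeLines(sprintf("%s\t%d\t%d\t%s", sim$genes$chrom, as.integer(sim$genes$start),
                     as.integer(sim$genes$end), sim$genes$gene_id), paths[["genes"]])
  # masks: two fixed common-CNV regions on the first chromosome
  writeLines(c("S01\t100000\t400000\tcommon1", "S01\t4500000\t4800000\tcommon2"),
             paths[["masks"]])
  write_gmt(sim$sets, paths[["gmt"]])
  write_cohort_table(sim$cohorts, paths[["cohorts"]])
  d16 <- simulate_design_rows(16, seed = seed + 1)
  utils::write.table(
    data.frame(y = d16$y, study_id = d16$study_id,
               length_scaled = sprintf("%.6f", d16$length_scaled),
               n_genes_outside = d16$n_genes_outside, hit_in_set = d16$hit_in_set,
               cnv_type = d16$cnv_type),
    paths[["design"]], sep = "\t", quote = FALSE, row.names = FALSE)
  sums <- tools::md5sum(unname(paths))
  manifest <- file.path(out_dir, "checksums.txt")
  writeLines(sprintf("%s  %s", unname(sums), basename(names(sums))), manifest)
  invisible(c(paths, manifest = manifest))
}
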