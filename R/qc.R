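# Rare-CNV quality filters: size threshold, overlap with common-CNV /
# segmental-duplication masks, and population frequency. Each filter
# returns the retained table plus an exclusion ledger so the pipeline can
# prove conservation (input = retained + excluded).

#' Filter CNVs by size
#'
#' Retains CNVs strictly longer than `min_length_bp`. The primary analysis
#' window uses 500 kb (large CNVs are the most reliably called across
#' genotyping platforms); 100 kb is the conventional secondary window. The
#' inequality is strict: a CNV of exactly `min_length_bp` is removed.
#'
#' @param cnvs a `cnv_table`.
#' @param min_length_bp positive length threshold in bp (default 500000).
#' @return list with `cnvs` (retained), `excluded` (removed rows plus a
#'   `reason` column), `n_removed`.
#' @export
filter_by_size <- function(cnvs, min_length_bp = 5e5) {
  stopifnot(min_length_bp > 0)
  keep <- cnv_length(cnvs) > min_length_bp
  finish_filter(cnvs, keep, sprintf("length <= %d bp", as.integer(min_length_bp)))
}

finish_filter <- function(cnvs, keep, reason) {
  excl <- cnvs[!keep, , drop = FALSE]
  if (nrow(excl)) excl$reason <- reason
  else excl$reason <- character(0)
  out <- cnvs[keep, , drop = FALSE]
  rownames(out) <- NULL; rownames(excl) <- NULL
  list(cnvs = validate_cnv_table(out), excluded = excl, n_removed = sum(!keep))
}

#' Filter CNVs by overlap with mask regions
#'
#' Removes CNVs whose length is covered more than `max_fraction` (default
#' 0.5) by the *union* of mask intervals (known common-CNV sites,
#' segmental duplications) on the same chromosome. Masks may overlap each
#' other; coverage is computed on their union so double-counting cannot
#' inflate the fraction. Exactly 50% coverage is retained (strict >).
#'
#' @param cnvs a `cnv_table`.
#' @param masks an `interval_table` of mask regions.
#' @param max_fraction maximum tolerated covered fraction, default 0.5.
#' @return list with `cnvs`, `excluded`, `n_removed` as [filter_by_size()].
#' @export
filter_common_overlap <- function(cnvs, masks, max_fraction = 0.5) {
  frac <- mask_coverage_fraction(cnvs, masks)
  keep <- frac <= max_fraction
  finish_filter(cnvs, keep, sprintf("mask overlap > %g of length", max_fraction))
}

#' Fraction of each CNV covered by the union of mask intervals
#'
#' @param cnvs a `cnv_table`.
#' @param masks an `interval_table`.
#' @return numeric vector in \[0, 1\], one value per CNV.
#' @export
mask_coverage_fraction <- function(cnvs, masks) {
  if (!nrow(cnvs)) return(numeric(0))
  if (is.null(masks) || !nrow(masks)) return(rep(0, nrow(cnvs)))
  cg <- cnv_granges(cnvs)
  mg <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seqnames = masks$chrom,
    ranges = IRanges::IRanges(start = masks$start + 1, end = masks$end)))
  cov <- rep(0, nrow(cnvs))
  ov <- GenomicRanges::findOverlaps(cg, mg)
  if (length(ov)) {
    inter <- IRanges::pintersect(cg[S4Vectors::queryHits(ov)], mg[S4Vectors::subjectHits(ov)])
    w <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
    cov[as.integer(names(w))] <- as.numeric(w)
  }
  cov / cnv_length(cnvs)
}

cnv_granges <- function(cnvs) {
  GenomicRanges::GRanges(seqnames = cnvs$chrom,
                         ranges = IRanges::IRanges(start = cnvs$start + 1, end = cnvs$end))
}

#' Filter CNVs by population frequency
#'
#' CNVs are grouped into loci by single-linkage clustering at
#' `recip_overlap` reciprocal overlap among CNVs of the same type (DEL
#' with DEL, DUP with DUP), the field's conventional CNV-matching rule.
#' A locus whose distinct carriers amount to at least `max_freq` of the
#' subject denominator is removed entirely (the "<1%" rare-variant rule:
#' exactly 1% is common and removed).
#'
#' @param cnvs a `cnv_table`.
#' @param cohorts a `cohort_table`; the denominator is all subjects pooled
#'   (`per_study = FALSE`) or per contributing study (`per_study = TRUE`).
#' @param max_freq carrier-frequency cutoff, default 0.01.
#' @param recip_overlap reciprocal-overlap threshold for locus matching,
#'   default 0.5.
#' @param per_study apply the frequency within each study instead of pooled.
#' @return list with `cnvs`, `excluded`, `n_removed`, and `locus_id`
#'   (integer locus assignment of the *input* CNVs).
#' @export
filter_by_frequency <- function(cnvs, cohorts, max_freq = 0.01,
                                recip_overlap = 0.5, per_study = FALSE) {
  if (is.null(cohorts) || !nrow(cohorts)) stop("frequency filter requires a cohort table")
  n_total <- sum(cohorts$n_cases + cohorts$n_controls)
  if (n_total <= 0) stop("no subjects in cohort table")
  locus <- cluster_cnv_loci(cnvs, recip_overlap)
  keep <- rep(TRUE, nrow(cnvs))
  for (l in unique(locus)) {
    idx <- which(locus == l)
    if (per_study) {
      for (s in unique(cnvs$study_id[idx])) {
        j <- idx[cnvs$study_id[idx] == s]
        k <- match(s, cohorts$study_id)
        if (is.na(k)) stop("study '", s, "' absent from cohort table")
        denom <- cohorts$n_cases[k] + cohorts$n_controls[k]
        if (length(unique(cnvs$sample_id[j])) / denom >= max_freq) keep[j] <- FALSE
      }
    } else {
      carriers <- length(unique(cnvs$sample_id[idx]))
      if (carriers / n_total >= max_freq) keep[idx] <- FALSE
    }
  }
  res <- finish_filter(cnvs, keep, sprintf("locus frequency >= %g", max_freq))
  res$locus_id <- locus
  res
}

#' Single-linkage CNV locus clustering
#'
#' Two CNVs are linked when they are the same type, on the same
#' chromosome, and their overlap is at least `recip_overlap` of *both*
#' lengths (reciprocal overlap). Loci are the connected components of
#' this graph, so a chain A~B~C is one locus even if A and C do not
#' themselves overlap.
#'
#' @param cnvs a `cnv_table`.
#' @param recip_overlap reciprocal-overlap threshold.
#' @return integer vector of locus labels, one per CNV.
#' @export
cluster_cnv_loci <- function(cnvs, recip_overlap = 0.5) {
  n <- nrow(cnvs)
  if (!n) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  cg <- cnv_granges(cnvs)
  ov <- GenomicRanges::findOverlaps(cg, drop.self = TRUE, drop.redundant = TRUE)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  if (length(q)) {
    w <- IRanges::width(IRanges::pintersect(cg[q], cg[s]))
    len <- cnv_length(cnvs)
    ok <- cnvs$cnv_type[q] == cnvs$cnv_type[s] &
      w >= recip_overlap * len[q] & w >= recip_overlap * len[s]
    for (k in which(ok)) unite(q[k], s[k])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Apply the full QC cascade
#'
#' Size, then mask overlap, then frequency, with a combined exclusion
#' ledger. The frequency clustering runs on the CNVs that survive the
#' first two filters.
#'
#' @param cnvs a `cnv_table`.
#' @param cohorts a `cohort_table` (required when `max_freq < 1`).
#' @param masks optional `interval_table` of mask regions.
#' @param min_length_bp,mask_max_fraction,max_freq,recip_overlap filter
#'   parameters (defaults 500000, 0.5, 0.01, 0.5).
#' @param per_study_freq frequency denominator per study instead of pooled.
#' @return list with `cnvs` (retained), `excluded` (ledger with `reason`),
#'   and `counts` (records in/out at each stage).
#' @export
qc_cnvs <- function(cnvs, cohorts = NULL, masks = NULL,
                    min_length_bp = 5e5, mask_max_fraction = 0.5,
                    max_freq = 0.01, recip_overlap = 0.5,
                    per_study_freq = FALSE) {
  n_in <- nrow(cnvs)
  s1 <- filter_by_size(cnvs, min_length_bp)
  s2 <- if (!is.null(masks)) filter_common_overlap(s1$cnvs, masks, mask_max_fraction)
        else list(cnvs = s1$cnvs, excluded = s1$excluded[0, , drop = FALSE], n_removed = 0L)
  s3 <- if (!is.null(cohorts) && max_freq < 1)
          filter_by_frequency(s2$cnvs, cohorts, max_freq, recip_overlap, per_study_freq)
        else list(cnvs = s2$cnvs, excluded = s2$excluded[0, , drop = FALSE], n_removed = 0L)
  excluded <- rbind(s1$excluded, s2$excluded, s3$excluded)
  counts <- data.frame(
    stage = c("input", "size", "mask_overlap", "frequency", "retained"),
    n = c(n_in, nrow(s1$cnvs), nrow(s2$cnvs), nrow(s3$cnvs), nrow(s3$cnvs)))
  list(cnvs = s3$cnvs, excluded = excluded, counts = counts)
}
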