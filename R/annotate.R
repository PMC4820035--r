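# CNV-to-gene annotation and construction of the per-CNV regression
# design. A CNV "hits" a gene when their footprints share at least one
# base (half-open semantics; abutting intervals do not overlap). The
# design carries, per CNV: case/control outcome, study, length in 100-kb
# units, the number of genes hit outside the tested set, and a binary
# indicator for hitting any set gene.

#' Build a queryable gene interval index
#'
#' Wraps the gene footprints in a `GRanges` (per-chromosome interval
#' index) for overlap queries. Gene IDs must be unique.
#'
#' @param genes an `interval_table` of gene footprints.
#' @param min_overlap_fraction minimum fraction of the *gene* footprint a
#'   CNV must cover to count as a hit; 0 (the default) means any 1-bp
#'   overlap, the permissive standard for large CNVs.
#' @return an opaque index object for [genes_hit()] / [build_design()].
#' @export
build_gene_index <- function(genes, min_overlap_fraction = 0) {
  if (!nrow(genes)) stop("gene index requires at least one gene")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene table: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end))
  structure(list(gr = gr, gene_id = genes$gene_id,
                 min_overlap_fraction = min_overlap_fraction,
                 n_genes = nrow(genes)),
            class = "gene_index")
}

#' Genes hit by each CNV
#'
#' @param cnvs a `cnv_table` (one or more rows).
#' @param index a `gene_index`.
#' @return a list, one character vector of gene IDs per CNV, in stable
#'   (index) order.
#' @export
genes_hit <- function(cnvs, index) {
  stopifnot(inherits(index, "gene_index"))
  out <- rep(list(character(0)), nrow(cnvs))
  if (!nrow(cnvs)) return(out)
  cg <- cnv_granges(cnvs)
  ov <- GenomicRanges::findOverlaps(cg, index$gr)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  if (index$min_overlap_fraction > 0 && length(q)) {
    w <- IRanges::width(IRanges::pintersect(cg[q], index$gr[s]))
    keep <- w >= index$min_overlap_fraction * IRanges::width(index$gr[s])
    q <- q[keep]; s <- s[keep]
  }
  if (length(q)) {
    sp <- split(s, q)
    for (nm in names(sp)) out[[as.integer(nm)]] <- index$gene_id[sort(sp[[nm]])]
  }
  out
}

#' Build the regression design for a gene set
#'
#' Exactly one row per CNV — CNVs hitting no genes stay in the sample
#' (the models are fitted to all CNVs; gene-desert CNVs inform the
#' covariate effects). `hit_in_set` is 1 iff the CNV hits at least one
#' set gene; `n_genes_outside` counts hit genes not in the set. The
#' length covariate is scaled to 100-kb units for numeric conditioning
#' of the GLM (the deviance test is invariant to this scaling).
#'
#' @param cnvs a `cnv_table`.
#' @param index a `gene_index`.
#' @param set character vector of gene IDs (a `gene_set_list` element),
#'   or a single-element subset of a `gene_set_list`.
#' @param hits optional precomputed [genes_hit()] list (saves recomputing
#'   the overlap when testing many sets on the same CNVs).
#' @return data.frame with columns `y, study_id, length_scaled,
#'   n_genes_outside, hit_in_set, cnv_type, sample_id`.
#' @export
build_design <- function(cnvs, index, set, hits = NULL) {
  set <- as.character(unlist(set, use.names = FALSE))
  if (is.null(hits)) hits <- genes_hit(cnvs, index)
  n_in <- vapply(hits, function(g) sum(g %in% set), integer(1))
  n_tot <- lengths(hits)
  data.frame(
    y = cnvs$is_case,
    study_id = cnvs$study_id,
    length_scaled = cnv_length(cnvs) / 1e5,
    n_genes_outside = n_tot - n_in,
    hit_in_set = as.integer(n_in >= 1L),
    cnv_type = cnvs$cnv_type,
    sample_id = cnvs$sample_id,
    stringsAsFactors = FALSE)
}
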