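#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based half-open [start, end), BED-style,
# on chromosome labels with any leading "chr" stripped. All interval
# arithmetic in the package assumes this convention.

#' Normalise chromosome labels
#'
#' Strips an optional `chr`/`CHR` prefix so mixed-source inputs compare
#' equal (`"chr1"` and `"1"` are the same chromosome).
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector without the `chr` prefix.
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

#' Construct a CNV record table
#'
#' The package's central container: one row per rare CNV call, with the
#' carrier's case/control status and study of origin. Coordinates are
#' 0-based half-open; `length_bp = end - start`.
#'
#' @param sample_id,study_id character vectors identifying carrier and cohort.
#' @param is_case integer 0/1 case status of the carrier.
#' @param chrom chromosome label (leading `chr` stripped).
#' @param start,end 0-based half-open interval, `end > start >= 0`.
#' @param cnv_type `"DEL"` or `"DUP"`.
#' @return a `data.frame` with class `cnv_table`.
#' @export
cnv_table <- function(sample_id, study_id, is_case, chrom, start, end, cnv_type) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    study_id = as.character(study_id),
    is_case = as.integer(is_case),
    chrom = normalize_chrom(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    cnv_type = as.character(cnv_type),
    stringsAsFactors = FALSE
  )
  validate_cnv_table(df)
}

#' Validate a CNV record table
#'
#' @param df data.frame with the `cnv_table` columns.
#' @return the validated data.frame, classed `cnv_table`.
#' @export
validate_cnv_table <- function(df) {
  req <- c("sample_id", "study_id", "is_case", "chrom", "start", "end", "cnv_type")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cnv_table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (any(!df$cnv_type %in% c("DEL", "DUP")))
      stop("cnv_type must be DEL or DUP")
    if (any(df$start < 0)) stop("negative start coordinate")
    if (any(df$end <= df$start)) stop("end must exceed start")
    if (any(!df$is_case %in% c(0L, 1L))) stop("is_case must be 0 or 1")
  }
  class(df) <- unique(c("cnv_table", class(df)))
  df
}

#' CNV lengths in base pairs
#' @param cnvs a `cnv_table`.
#' @return numeric vector `end - start`.
#' @export
cnv_length <- function(cnvs) cnvs$end - cnvs$start

#' Construct a study cohort table
#'
#' Subject denominators per study, used for burden rates and the
#' population-frequency filter.
#'
#' @param study_id cohort labels.
#' @param n_cases,n_controls positive subject counts.
#' @return data.frame with class `cohort_table`.
#' @export
cohort_table <- function(study_id, n_cases, n_controls) {
  df <- data.frame(
    study_id = as.character(study_id),
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    stringsAsFactors = FALSE
  )
  if (any(df$n_cases <= 0L) || any(df$n_controls <= 0L))
    stop("cohort sizes must be positive")
  if (anyDuplicated(df$study_id)) stop("duplicate study_id in cohort table")
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Construct a gene (or mask) interval table
#'
#' @param chrom chromosome labels.
#' @param start,end 0-based half-open footprint.
#' @param gene_id unique identifiers; synthesised as `chrom:start-end` when
#'   missing.
#' @param symbol display names (defaults to `gene_id`).
#' @return data.frame with class `interval_table`.
#' @export
interval_table <- function(chrom, start, end, gene_id = NULL, symbol = NULL) {
  chrom <- normalize_chrom(chrom)
  if (is.null(gene_id)) gene_id <- sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
  if (is.null(symbol)) symbol <- gene_id
  df <- data.frame(
    gene_id = as.character(gene_id),
    symbol = as.character(symbol),
    chrom = chrom,
    start = as.numeric(start),
    end = as.numeric(end),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(df$start < 0)) stop("negative start coordinate")
    if (any(df$end <= df$start)) stop("end must exceed start")
  }
  class(df) <- unique(c("interval_table", class(df)))
  df
}

#' Construct a gene-set collection
#'
#' @param ids set identifiers (unique after deterministic `.k` suffixing).
#' @param genes list of character vectors of gene IDs (duplicates removed).
#' @param names_ human-readable labels (default: the ids).
#' @param source collection tag, e.g. `"GO"`, `"custom"`.
#' @return a named list of character vectors with class `gene_set_list`;
#'   each element carries `name` and `source` attributes.
#' @export
gene_set_list <- function(ids, genes, names_ = NULL, source = "custom") {
  stopifnot(length(ids) == length(genes))
  if (is.null(names_)) names_ <- ids
  source <- rep_len(source, length(ids))
  ids <- make_unique_set_ids(as.character(ids))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- unique(as.character(genes[[i]]))
    if (!length(g)) stop("gene set '", ids[i], "' is empty")
    attr(g, "name") <- names_[i]
    attr(g, "source") <- source[i]
    out[[i]] <- g
  }
  names(out) <- ids
  class(out) <- "gene_set_list"
  out
}

# Deterministic ".k" suffixes for duplicate set names (public GMT
# collections contain collisions; erroring would be hostile).
make_unique_set_ids <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  out <- ids
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(ids)) {
    id <- ids[i]
    k <- if (is.null(seen[[id]])) 0L else seen[[id]]
    if (k > 0L) {
      out[i] <- paste0(id, ".", k + 1L)
      warning("duplicate gene-set id '", id, "' renamed to '", out[i], "'")
    }
    seen[[id]] <- k + 1L
  }
  out
}

#' Sizes of gene sets
#' @param sets a `gene_set_list`.
#' @return named integer vector of gene counts.
#' @export
gene_set_sizes <- function(sets) vapply(sets, length, integer(1))
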