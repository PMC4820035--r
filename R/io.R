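# Readers and writers for the plain-text formats the pipeline consumes:
# tab-delimited CNV tables (with a PLINK .cnv dialect), BED intervals for
# gene footprints and masks, GMT gene sets, and tab-delimited results.
#
# Error contract: malformed *records* are collected with their line numbers
# and returned alongside the parsed records (never silently dropped);
# malformed *files* (missing columns, wrong field count) are errors.

read_lines_nocomment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a CNV table
#'
#' Two dialects are supported. `tsv`: a tab-delimited file with a header
#' naming `sample_id, study_id, is_case, chrom, start, end, cnv_type`
#' (0/1 case coding, DEL/DUP types, 0-based half-open coordinates,
#' `#` comments). `plink_cnv`: the PLINK `.cnv` column order
#' (`FID IID CHR BP1 BP2 TYPE SCORE SITES`) where TYPE is the copy number
#' (<2 is a deletion, >2 a duplication, =2 is rejected as a non-variant);
#' because `.cnv` files carry no phenotype or cohort label, a companion
#' cohort map supplies `is_case` and `study_id` per sample.
#'
#' PLINK `BP1`/`BP2` are 1-based inclusive and are converted to the
#' internal 0-based half-open convention (`start = BP1 - 1`, `end = BP2`).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"plink_cnv"`.
#' @param sample_info for `plink_cnv`: a data.frame with columns
#'   `sample_id, study_id, is_case` mapping IID to cohort and status.
#' @param cohorts optional `cohort_table`; when `NULL`, cohort totals are
#'   inferred from distinct sample IDs per study (every subject assumed to
#'   appear; real denominators should be supplied for rate work).
#' @return list with elements `cnvs` (a `cnv_table`), `cohorts`
#'   (a `cohort_table` or `NULL`) and `errors` (data.frame `line, message`
#'   of rejected records).
#' @export
read_cnv_table <- function(path, dialect = c("tsv", "plink_cnv"),
                           sample_info = NULL, cohorts = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") parse_cnv_tsv(path, cohorts) else parse_plink_cnv(path, sample_info, cohorts)
}

parse_cnv_tsv <- function(path, cohorts) {
  lc <- read_lines_nocomment(path)
  if (!length(lc$lines)) {
    warning("empty CNV file: ", path)
    return(list(cnvs = empty_cnv_table(), cohorts = cohorts, errors = empty_errors()))
  }
  header <- strsplit(lc$lines[1], "\t", fixed = TRUE)[[1]]
  req <- c("sample_id", "study_id", "is_case", "chrom", "start", "end", "cnv_type")
  miss <- setdiff(req, header)
  if (length(miss)) stop("CNV table missing required column(s): ", paste(miss, collapse = ", "))
  idx <- match(req, header)
  rows <- lapply(lc$lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  linenos <- lc$lineno[-1]
  recs <- list(); errs <- list()
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < length(header)) {
      errs[[length(errs) + 1L]] <- data.frame(line = linenos[i], message = "too few fields")
      next
    }
    v <- f[idx]
    start <- suppressWarnings(as.numeric(v[5])); end <- suppressWarnings(as.numeric(v[6]))
    type <- toupper(v[7])
    msg <- NULL
    if (is.na(start) || is.na(end)) msg <- "non-numeric coordinate"
    else if (start < 0) msg <- "negative start"
    else if (end <= start) msg <- "end <= start"
    else if (!type %in% c("DEL", "DUP")) msg <- paste0("unknown cnv_type '", v[7], "'")
    if (!is.null(msg)) {
      errs[[length(errs) + 1L]] <- data.frame(line = linenos[i], message = msg)
    } else {
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = v[1], study_id = v[2], is_case = as.integer(v[3]),
        chrom = normalize_chrom(v[4]), start = start, end = end, cnv_type = type,
        stringsAsFactors = FALSE)
    }
  }
  cnvs <- if (length(recs)) validate_cnv_table(do.call(rbind, recs)) else empty_cnv_table()
  list(cnvs = cnvs, cohorts = cohorts,
       errors = if (length(errs)) do.call(rbind, errs) else empty_errors())
}

parse_plink_cnv <- function(path, sample_info, cohorts) {
  if (is.null(sample_info))
    stop("plink_cnv dialect requires a sample_info map (sample_id, study_id, is_case)")
  lc <- read_lines_nocomment(path)
  # PLINK .cnv ships a header line starting with FID
  body <- lc$lines; linenos <- lc$lineno
  if (length(body) && grepl("^\\s*FID\\b", body[1])) { body <- body[-1]; linenos <- linenos[-1] }
  recs <- list(); errs <- list()
  for (i in seq_along(body)) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 6) {
      errs[[length(errs) + 1L]] <- data.frame(line = linenos[i], message = "too few fields")
      next
    }
    iid <- f[2]; bp1 <- suppressWarnings(as.numeric(f[4])); bp2 <- suppressWarnings(as.numeric(f[5]))
    cn <- suppressWarnings(as.numeric(f[6]))
    j <- match(iid, sample_info$sample_id)
    msg <- NULL
    if (is.na(j)) msg <- paste0("sample '", iid, "' not in sample_info")
    else if (is.na(bp1) || is.na(bp2)) msg <- "non-numeric coordinate"
    else if (bp2 < bp1) msg <- "end <= start"
    else if (is.na(cn)) msg <- "non-numeric TYPE"
    else if (cn == 2) msg <- "copy number 2 is not a variant"
    if (!is.null(msg)) {
      errs[[length(errs) + 1L]] <- data.frame(line = linenos[i], message = msg)
    } else {
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = iid, study_id = sample_info$study_id[j],
        is_case = as.integer(sample_info$is_case[j]),
        chrom = normalize_chrom(f[3]), start = bp1 - 1, end = bp2,
        cnv_type = if (cn < 2) "DEL" else "DUP", stringsAsFactors = FALSE)
    }
  }
  cnvs <- if (length(recs)) validate_cnv_table(do.call(rbind, recs)) else empty_cnv_table()
  list(cnvs = cnvs, cohorts = cohorts,
       errors = if (length(errs)) do.call(rbind, errs) else empty_errors())
}

empty_cnv_table <- function() {
  validate_cnv_table(data.frame(
    sample_id = character(), study_id = character(), is_case = integer(),
    chrom = character(), start = numeric(), end = numeric(), cnv_type = character(),
    stringsAsFactors = FALSE))
}

empty_errors <- function() data.frame(line = integer(), message = character())

#' Write a CNV table in the tsv dialect
#'
#' Round-trips through [read_cnv_table()] field-for-field.
#'
#' @param cnvs a `cnv_table`.
#' @param path output path.
#' @export
write_cnv_table <- function(cnvs, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# 0-based half-open coordinates", con)
  writeLines(paste(c("sample_id", "study_id", "is_case", "chrom", "start", "end", "cnv_type"),
                   collapse = "\t"), con)
  if (nrow(cnvs))
    writeLines(sprintf("%s\t%s\t%d\t%s\t%d\t%d\t%s", cnvs$sample_id, cnvs$study_id,
                       cnvs$is_case, cnvs$chrom, as.integer(cnvs$start),
                       as.integer(cnvs$end), cnvs$cnv_type), con)
  invisible(path)
}

#' Read a BED file of gene footprints or mask regions
#'
#' Accepts BED3 (mask regions) or BED4+ where the 4th column is the gene
#' ID/symbol. Coordinates are 0-based half-open as in the BED standard and
#' are preserved exactly; IDs are synthesised as `chrom:start-end` when
#' absent.
#'
#' @param path file path.
#' @return list with `intervals` (an `interval_table`) and `errors`
#'   (data.frame `line, message`).
#' @export
read_interval_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lc <- read_lines_nocomment(path)
  lc$lines <- lc$lines[!grepl("^(track|browser)\\b", lc$lines)]
  if (!length(lc$lines)) {
    warning("empty BED file: ", path)
    return(list(intervals = interval_table(character(), numeric(), numeric()),
                errors = empty_errors()))
  }
  recs <- list(); errs <- list()
  for (i in seq_along(lc$lines)) {
    f <- strsplit(lc$lines[i], "[ \t]+")[[1]]
    if (length(f) < 3) {
      errs[[length(errs) + 1L]] <- data.frame(line = lc$lineno[i], message = "too few fields")
      next
    }
    start <- suppressWarnings(as.numeric(f[2])); end <- suppressWarnings(as.numeric(f[3]))
    msg <- NULL
    if (is.na(start) || is.na(end)) msg <- "non-numeric coordinate"
    else if (start < 0) msg <- "negative start"
    else if (end <= start) msg <- "end <= start"
    if (!is.null(msg)) {
      errs[[length(errs) + 1L]] <- data.frame(line = lc$lineno[i], message = msg)
    } else {
      id <- if (length(f) >= 4 && nzchar(f[4])) f[4] else NA_character_
      recs[[length(recs) + 1L]] <- data.frame(chrom = f[1], start = start, end = end,
                                              id = id, stringsAsFactors = FALSE)
    }
  }
  if (length(recs)) {
    df <- do.call(rbind, recs)
    iv <- interval_table(df$chrom, df$start, df$end,
                         gene_id = ifelse(is.na(df$id),
                                          sprintf("%s:%d-%d", normalize_chrom(df$chrom),
                                                  as.integer(df$start), as.integer(df$end)),
                                          df$id))
  } else iv <- interval_table(character(), numeric(), numeric())
  list(intervals = iv, errors = if (length(errs)) do.call(rbind, errs) else empty_errors())
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: per line, set name, description, then one or more gene
#' IDs, all tab-delimited. Duplicate gene IDs within a set are removed
#' with a warning; duplicate set names get deterministic `.k` suffixes.
#' Size filtering (e.g. the 3-1500-gene screen window) happens later, at
#' test time, not here.
#'
#' @param path file path.
#' @param source collection tag stored on every set.
#' @return list with `sets` (a `gene_set_list`) and `errors`.
#' @export
read_gmt <- function(path, source = "gmt") {
  if (!file.exists(path)) stop("no such file: ", path)
  lc <- read_lines_nocomment(path)
  ids <- character(); nms <- character(); genes <- list(); errs <- list()
  for (i in seq_along(lc$lines)) {
    f <- strsplit(lc$lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3) {
      errs[[length(errs) + 1L]] <- data.frame(line = lc$lineno[i],
                                              message = "fewer than 3 fields")
      next
    }
    g <- f[-(1:2)]
    if (anyDuplicated(g)) {
      warning("duplicate gene IDs in set '", f[1], "' deduplicated")
      g <- unique(g)
    }
    ids <- c(ids, f[1]); nms <- c(nms, f[2]); genes <- c(genes, list(g))
  }
  sets <- if (length(ids)) gene_set_list(ids, genes, names_ = nms, source = source)
          else structure(list(), class = "gene_set_list")
  list(sets = sets, errors = if (length(errs)) do.call(rbind, errs) else empty_errors())
}

#' Write gene sets as GMT
#' @param sets a `gene_set_list`.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    nm <- attr(sets[[id]], "name"); if (is.null(nm)) nm <- id
    paste(c(id, nm, as.character(sets[[id]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Deterministic numeric formatting for result tables: fixed significant
# digits so that reruns are byte-identical across platforms.
fmt_num <- function(x, digits = 6) {
  out <- ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "g"), x))
  out
}

#' Write a results table as tsv
#'
#' Numeric columns are rendered at 6 significant digits so repeated runs
#' of the same analysis are byte-identical.
#'
#' @param df results data.frame.
#' @param path output path.
#' @export
write_results_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
    out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a cohort table (study_id, n_cases, n_controls) from tsv
#' @param path file path.
#' @return a `cohort_table`.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("study_id", "n_cases", "n_controls")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort table missing column(s): ", paste(miss, collapse = ", "))
  cohort_table(df$study_id, df$n_cases, df$n_controls)
}

#' Write a cohort table as tsv
#' @param cohorts a `cohort_table`.
#' @param path output path.
#' @export
write_cohort_table <- function(cohorts, path) {
  utils::write.table(as.data.frame(cohorts)[, c("study_id", "n_cases", "n_controls")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
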