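# Config-driven end-to-end runner: parse -> QC -> annotate -> hypothesis
# sets (Bonferroni) -> hypothesis-free screen (q-values) -> burden, with
# an exclusion ledger and a machine-readable log. Outputs are
# deterministic given config + inputs; wall-clock timestamps are
# confined to the log.

#' Default pipeline configuration
#'
#' @param ... overrides merged over the defaults (shallow for scalars,
#'   per-key for the nested `qc`, `screen` lists).
#' @return config list understood by [run_pipeline()].
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cnv_file = NULL, cohort_file = NULL, gene_bed = NULL,
    mask_beds = character(0), hypothesis_gmt = NULL, screen_gmt = NULL,
    out_dir = NULL, seed = 1,
    qc = list(min_length_bp = 5e5, mask_max_fraction = 0.5, max_freq = 0.01,
              recip_overlap = 0.5, per_study_freq = FALSE),
    strata = TRUE, loso = TRUE, dup_vs_del = TRUE,
    bonferroni_m = NULL,
    screen = list(enabled = TRUE, min_set_genes = 3, max_set_genes = 1500,
                  min_hits = 10, hit_count_mode = "incidence", lambda = 0.5),
    firth = FALSE)
  ov <- list(...)
  for (i in seq_along(ov)) {   # by index: repeated names apply in order
    k <- names(ov)[i]
    if (k %in% c("qc", "screen") && is.list(ov[[i]])) {
      for (kk in names(ov[[i]])) cfg[[k]][[kk]] <- ov[[i]][[kk]]
    } else cfg[[k]] <- ov[[i]]
  }
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys follow [pipeline_config()].
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full enrichment pipeline
#'
#' Stages, in fixed order: read inputs; QC (size, mask-overlap,
#' frequency filters); gene annotation; hypothesis-driven set tests
#' (ALL/DEL/DUP strata, leave-one-study-out "minus best", optional
#' duplication-vs-deletion differential test, Bonferroni over the
#' declared family); hypothesis-free screen with Storey q-values; and
#' per-study burden. Every excluded CNV and screened-out set is written
#' to the exclusion ledger with a reason; the JSON-lines log records
#' thresholds and record counts at each stage, so input = retained +
#' excluded is checkable. Partial outputs are removed on failure.
#'
#' @param config list from [pipeline_config()] or a YAML path.
#' @return invisible list: `outputs` (paths), `results` (in-memory
#'   tables), `counts` (stage conservation table).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  stopifnot(!is.null(cfg$cnv_file), !is.null(cfg$cohort_file),
            !is.null(cfg$gene_bed), !is.null(cfg$out_dir))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  made <- character(0)
  logf <- file.path(cfg$out_dir, "run_log.jsonl")
  note <- function(stage, ...) {
    rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = logf, append = TRUE)
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(made))
  unlink(logf); made <- c(made, logf)
  note("start", package_version = as.character(utils::packageVersion("cnvenrich")),
       qc = cfg$qc, seed = cfg$seed)

  # --- read -----------------------------------------------------------
  parsed <- read_cnv_table(cfg$cnv_file, dialect = "tsv")
  cohorts <- read_cohort_table(cfg$cohort_file)
  genes <- read_interval_bed(cfg$gene_bed)$intervals
  masks <- NULL
  if (length(cfg$mask_beds)) {
    ml <- lapply(cfg$mask_beds, function(p) read_interval_bed(p)$intervals)
    masks <- do.call(rbind, ml)
  }
  note("read", n_cnvs = nrow(parsed$cnvs), n_parse_errors = nrow(parsed$errors),
       n_genes = nrow(genes), n_masks = if (is.null(masks)) 0L else nrow(masks))

  # --- qc -------------------------------------------------------------
  qc <- qc_cnvs(parsed$cnvs, cohorts = cohorts, masks = masks,
                min_length_bp = cfg$qc$min_length_bp,
                mask_max_fraction = cfg$qc$mask_max_fraction,
                max_freq = cfg$qc$max_freq, recip_overlap = cfg$qc$recip_overlap,
                per_study_freq = cfg$qc$per_study_freq)
  cnvs <- qc$cnvs
  note("qc", counts = stats::setNames(as.list(qc$counts$n), qc$counts$stage),
       n_excluded = nrow(qc$excluded))
  index <- build_gene_index(genes)
  hits <- genes_hit(cnvs, index)

  outputs <- list()
  results <- list()

  # --- hypothesis-driven sets ----------------------------------------
  if (!is.null(cfg$hypothesis_gmt)) {
    sets <- read_gmt(cfg$hypothesis_gmt, source = "hypothesis")$sets
    m <- if (is.null(cfg$bonferroni_m)) length(sets) else cfg$bonferroni_m
    rows <- lapply(names(sets), function(id) {
      tg <- test_gene_set(cnvs, index, sets[[id]], set_id = id,
                          strata = if (isTRUE(cfg$strata)) c("ALL", "DEL", "DUP") else "ALL",
                          hits = hits, firth = cfg$firth)
      all_row <- tg[tg$stratum == "ALL", ]
      p_del <- if ("DEL" %in% tg$stratum) tg$p_value[tg$stratum == "DEL"] else NA_real_
      p_dup <- if ("DUP" %in% tg$stratum) tg$p_value[tg$stratum == "DUP"] else NA_real_
      p_mb <- NA_real_
      if (isTRUE(cfg$loso) && length(unique(cnvs$study_id)) >= 2) {
        lo <- leave_one_study_out(cnvs, index, sets[[id]], set_id = id,
                                  hits = hits, firth = cfg$firth)
        p_mb <- lo$minus_best$p_value
      }
      p_dvd <- NA_real_
      if (isTRUE(cfg$dup_vs_del)) {
        ccnv <- cnvs[cnvs$is_case == 1L, , drop = FALSE]
        if (length(unique(ccnv$cnv_type)) == 2L) {
          dvd <- differential_dup_del(ccnv, index, sets[[id]], set_id = id,
                                      hits = hits[cnvs$is_case == 1L],
                                      firth = cfg$firth)
          p_dvd <- dvd$p_value
        }
      }
      data.frame(set_id = id, n_genes = length(sets[[id]]),
                 P = all_row$p_value, P_minus_best = p_mb,
                 P_del = p_del, P_dup = p_dup, P_dup_vs_del = p_dvd,
                 beta_hit = all_row$beta_hit,
                 n_case_hits = all_row$n_case_hits,
                 n_control_hits = all_row$n_control_hits,
                 stringsAsFactors = FALSE)
    })
    hyp <- do.call(rbind, rows)
    hyp$P_bonferroni <- bonferroni_adjust(hyp$P, m = max(m, nrow(hyp)))
    outputs$hypothesis_sets <- file.path(cfg$out_dir, "hypothesis_sets.tsv")
    write_results_tsv(hyp, outputs$hypothesis_sets)
    made <- c(made, outputs$hypothesis_sets)
    results$hypothesis_sets <- hyp
    note("hypothesis_sets", n_sets = nrow(hyp), bonferroni_m = max(m, nrow(hyp)))
  }

  # --- hypothesis-free screen ----------------------------------------
  set_exclusions <- data.frame(set_id = character(), reason = character())
  if (isTRUE(cfg$screen$enabled) && !is.null(cfg$screen_gmt)) {
    ssets <- read_gmt(cfg$screen_gmt, source = "screen")$sets
    sc <- pathway_screen(cnvs, index, ssets,
                         min_set_genes = cfg$screen$min_set_genes,
                         max_set_genes = cfg$screen$max_set_genes,
                         min_hits = cfg$screen$min_hits,
                         hit_count_mode = cfg$screen$hit_count_mode,
                         lambda = cfg$screen$lambda, hits = hits,
                         firth = cfg$firth)
    set_exclusions <- sc$exclusions
    if (!is.null(sc$results)) {
      scr <- sc$results[order(sc$results$p_value, sc$results$set_id),
                        c("set_id", "n_genes", "n_hits", "lrt_stat", "p_value",
                          "beta_hit", "n_case_hits", "n_control_hits", "q_value")]
      outputs$screen <- file.path(cfg$out_dir, "screen.tsv")
      write_results_tsv(scr, outputs$screen)
      made <- c(made, outputs$screen)
      results$screen <- scr
    }
    note("screen", n_tested = if (is.null(sc$results)) 0L else nrow(sc$results),
         n_excluded = nrow(sc$exclusions), pi0 = sc$pi0)
  }

  # --- burden ---------------------------------------------------------
  bur <- burden_summary(cnvs, cohorts, stratum = c("ALL", "DEL", "DUP"))
  outputs$burden <- file.path(cfg$out_dir, "burden.tsv")
  write_results_tsv(bur[, c("study_id", "stratum", "n_case_cnvs", "n_control_cnvs",
                            "case_rate", "control_rate", "ratio", "p_value")],
                    outputs$burden)
  made <- c(made, outputs$burden)
  results$burden <- bur
  note("burden", n_rows = nrow(bur))

  # --- exclusion ledger ----------------------------------------------
  ledger <- rbind(
    if (nrow(parsed$errors))
      data.frame(kind = "cnv_parse", id = paste0("line:", parsed$errors$line),
                 reason = parsed$errors$message, stringsAsFactors = FALSE),
    if (nrow(qc$excluded))
      data.frame(kind = "cnv_qc",
                 id = sprintf("%s:%s:%d-%d", qc$excluded$sample_id,
                              qc$excluded$chrom, as.integer(qc$excluded$start),
                              as.integer(qc$excluded$end)),
                 reason = qc$excluded$reason, stringsAsFactors = FALSE),
    if (nrow(set_exclusions))
      data.frame(kind = "screen_set", id = set_exclusions$set_id,
                 reason = set_exclusions$reason, stringsAsFactors = FALSE))
  if (is.null(ledger)) ledger <- data.frame(kind = character(), id = character(),
                                            reason = character())
  outputs$exclusions <- file.path(cfg$out_dir, "exclusions.tsv")
  utils::write.table(ledger, outputs$exclusions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  made <- c(made, outputs$exclusions)
  results$exclusions <- ledger

  counts <- qc$counts
  note("done", outputs = lapply(outputs, basename))
  ok <- TRUE
  invisible(list(outputs = outputs, results = results, counts = counts))
}
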