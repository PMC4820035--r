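# The core statistic: a nested logistic-regression deviance test for
# gene-set enrichment. Each CNV is labelled case/control after its
# carrier; the null model explains that label with study of origin, CNV
# length and the number of genes hit outside the tested set, and the full
# model adds a binary indicator for hitting a set gene. Under no
# enrichment the deviance difference is asymptotically chi-squared on one
# degree of freedom. The sign of the hit coefficient distinguishes
# enrichment (positive) from depletion.

# Reference-cell model matrix: intercept, study indicators (first study
# in sort order is the reference; a single-study design carries no study
# term), length in 100-kb units, genes hit outside the set, and
# optionally the set-hit indicator (entered last, so it is the first
# dropped under aliasing).
design_matrix <- function(rows, include_hit_term = TRUE) {
  n <- nrow(rows)
  studies <- sort(unique(rows$study_id))
  cols <- list("(Intercept)" = rep(1, n))
  if (length(studies) > 1)
    for (s in studies[-1]) cols[[paste0("study_", s)]] <- as.numeric(rows$study_id == s)
  cols[["length_scaled"]] <- rows$length_scaled
  cols[["n_genes_outside"]] <- as.numeric(rows$n_genes_outside)
  if (include_hit_term) cols[["hit_in_set"]] <- as.numeric(rows$hit_in_set)
  do.call(cbind, cols)
}

#' Fit the CNV-level logistic regression
#'
#' Maximum-likelihood logistic regression of the case/control label on
#' study, length and genes-outside covariates, optionally with the
#' set-hit indicator. Fitting is by iteratively reweighted least squares
#' (relative deviance-change tolerance 1e-10, at most 100 iterations).
#' Aliased (rank-deficient) columns are dropped in reverse entry order
#' with a warning; quasi-separation is flagged when any coefficient
#' exceeds 15 in absolute value on the scaled design.
#'
#' @param rows design rows from [build_design()].
#' @param include_hit_term include the `hit_in_set` column.
#' @param firth use Firth's bias-reduced penalized likelihood instead of
#'   plain ML (an option for separated designs; default off, so the
#'   primary path is plain ML).
#' @return object of class `logistic_fit`: `coefficients` (named; dropped
#'   terms absent), `deviance` (-2 max log-likelihood), `converged`,
#'   `n_iter`, `separation_flag`, `dropped`, `n`.
#' @export
fit_logistic <- function(rows, include_hit_term = TRUE, firth = FALSE) {
  y <- as.numeric(rows$y)
  if (length(y) < 2L || all(y == 1) || all(y == 0))
    stop("degenerate outcome: need at least one case and one control row")
  X <- design_matrix(rows, include_hit_term)
  # drop constant non-intercept columns (aliased with the intercept),
  # then any remaining exact collinearity, in reverse entry order
  dropped <- character(0)
  repeat {
    r <- qr(X)$rank
    if (r == ncol(X)) break
    # drop the last-entered column that is redundant given the others
    for (j in rev(seq_len(ncol(X)))) {
      if (qr(X[, -j, drop = FALSE])$rank == r) {
        dropped <- c(dropped, colnames(X)[j])
        X <- X[, -j, drop = FALSE]
        break
      }
    }
  }
  if (length(dropped))
    warning("aliased term(s) dropped: ", paste(dropped, collapse = ", "))
  if (firth) {
    fit <- firth_fit(X, y)
  } else {
    ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
    g <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(), control = ctrl))
    fit <- list(coefficients = g$coefficients, deviance = g$deviance,
                converged = g$converged, n_iter = g$iter)
  }
  coefs <- fit$coefficients
  structure(list(coefficients = coefs,
                 deviance = fit$deviance,
                 converged = fit$converged,
                 n_iter = fit$n_iter,
                 separation_flag = any(abs(coefs[!is.na(coefs)]) > 15),
                 dropped = dropped,
                 n = length(y),
                 vcov = fisher_vcov(X, coefs)),
            class = "logistic_fit")
}

fisher_vcov <- function(X, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- p * (1 - p)
  info <- crossprod(X * sqrt(w))
  V <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

# Firth's penalized-likelihood logistic regression: Newton iterations on
# the modified score U*(b) = X'(y - p + h (1/2 - p)), h the hat diagonal.
firth_fit <- function(X, y, maxit = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  dev_old <- Inf; converged <- FALSE; it <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta); p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    h <- rowSums((XW %*% solve(info)) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    beta <- beta + drop(solve(info, U))
    eta <- drop(X %*% beta); p <- stats::plogis(eta)
    dev <- -2 * sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
    pen <- determinant(crossprod(X * sqrt(pmax(p * (1 - p), 1e-12))))$modulus
    dev_pen <- dev - as.numeric(pen)
    if (abs(dev_pen - dev_old) / (abs(dev_pen) + 0.1) < tol) { converged <- TRUE; break }
    dev_old <- dev_pen
  }
  names(beta) <- colnames(X)
  list(coefficients = beta,
       deviance = -2 * sum(y * log(pmax(stats::plogis(drop(X %*% beta)), 1e-300)) +
                           (1 - y) * log(pmax(1 - stats::plogis(drop(X %*% beta)), 1e-300))),
       converged = converged, n_iter = it)
}

enrichment_result <- function(set_id, stratum, analysis, n_rows,
                              lrt_stat = NA_real_, p_value = NA_real_,
                              beta_hit = NA_real_, n_case_hits = NA_integer_,
                              n_control_hits = NA_integer_,
                              estimable = TRUE, separation_flag = FALSE,
                              note = "") {
  data.frame(set_id = set_id, stratum = stratum, analysis = analysis,
             n_cnvs = n_rows, lrt_stat = lrt_stat, df = 1L, p_value = p_value,
             beta_hit = beta_hit, n_case_hits = n_case_hits,
             n_control_hits = n_control_hits, estimable = estimable,
             separation_flag = separation_flag, note = note,
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio enrichment test on a prepared design
#'
#' Fits the null (study + length + genes outside) and full (+ set-hit)
#' models and reports the deviance difference against the chi-squared
#' distribution on one degree of freedom (upper tail; negative
#' differences from numerical noise are clamped to zero). If the hit
#' indicator is constant there is nothing to test: the statistic is 0 and
#' the p-value 1, flagged in `note`.
#'
#' @param rows design rows from [build_design()].
#' @param set_id,stratum,analysis labels carried into the result.
#' @param firth use the Firth-penalized fit for both models.
#' @return a one-row `data.frame` (an enrichment result): `set_id,
#'   stratum, analysis, n_cnvs, lrt_stat, df, p_value, beta_hit,
#'   n_case_hits, n_control_hits, estimable, separation_flag, note`.
#' @export
lrt_enrichment <- function(rows, set_id = "set", stratum = "ALL",
                           analysis = "FULL", firth = FALSE) {
  nch <- sum(rows$hit_in_set == 1 & rows$y == 1)
  nco <- sum(rows$hit_in_set == 1 & rows$y == 0)
  if (length(unique(rows$hit_in_set)) == 1L)
    return(enrichment_result(set_id, stratum, analysis, nrow(rows),
                             lrt_stat = 0, p_value = 1,
                             n_case_hits = nch, n_control_hits = nco,
                             note = "hit indicator constant"))
  f0 <- fit_logistic(rows, include_hit_term = FALSE, firth = firth)
  f1 <- fit_logistic(rows, include_hit_term = TRUE, firth = firth)
  lrt <- max(0, f0$deviance - f1$deviance)
  enrichment_result(set_id, stratum, analysis, nrow(rows),
                    lrt_stat = lrt,
                    p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                    beta_hit = unname(f1$coefficients["hit_in_set"]),
                    n_case_hits = nch, n_control_hits = nco,
                    separation_flag = f1$separation_flag)
}

#' Test a gene set for enrichment, overall and by CNV type
#'
#' `ALL` uses every CNV; `DEL` and `DUP` restrict the design to that CNV
#' type before fitting. A stratum with no case or no control rows yields
#' a not-estimable row (flagged, not an error).
#'
#' @param cnvs a `cnv_table`.
#' @param index a `gene_index`.
#' @param set character vector of set gene IDs.
#' @param set_id label for the output.
#' @param strata subset of `c("ALL", "DEL", "DUP")`.
#' @param hits optional precomputed [genes_hit()] list.
#' @param firth use Firth-penalized fits.
#' @return data.frame of enrichment results, one row per stratum.
#' @export
test_gene_set <- function(cnvs, index, set, set_id = "set",
                          strata = c("ALL", "DEL", "DUP"), hits = NULL,
                          firth = FALSE) {
  strata <- match.arg(strata, several.ok = TRUE)
  rows <- build_design(cnvs, index, set, hits = hits)
  out <- lapply(strata, function(st) {
    sub <- if (st == "ALL") rows else rows[rows$cnv_type == st, , drop = FALSE]
    if (!nrow(sub) || all(sub$y == 1) || all(sub$y == 0))
      return(enrichment_result(set_id, st, "FULL", nrow(sub), estimable = FALSE,
                               n_case_hits = sum(sub$hit_in_set & sub$y == 1),
                               n_control_hits = sum(sub$hit_in_set & sub$y == 0),
                               note = "stratum lacks both outcome classes"))
    lrt_enrichment(sub, set_id = set_id, stratum = st, firth = firth)
  })
  do.call(rbind, out)
}

#' Differential duplication-versus-deletion enrichment among case CNVs
#'
#' Asks whether case duplications hit the set at a different rate from
#' case deletions: the outcome is recoded to 1 = DUP, 0 = DEL on case
#' CNVs only, with the same covariates, and the usual one-degree LRT is
#' applied to the set-hit indicator. `beta_hit > 0` means duplications
#' carry the excess.
#'
#' @param case_cnvs a `cnv_table` of case CNVs (rows with `is_case == 0`
#'   are dropped with a warning).
#' @param index a `gene_index`.
#' @param set character vector of set gene IDs.
#' @param set_id label.
#' @param hits optional precomputed hits for `case_cnvs`.
#' @param firth use Firth-penalized fits.
#' @return one-row enrichment result with stratum `DUP_VS_DEL`.
#' @export
differential_dup_del <- function(case_cnvs, index, set, set_id = "set",
                                 hits = NULL, firth = FALSE) {
  if (any(case_cnvs$is_case == 0L)) {
    warning("control CNVs dropped from duplication-vs-deletion comparison")
    keep <- case_cnvs$is_case == 1L
    case_cnvs <- case_cnvs[keep, , drop = FALSE]
    if (!is.null(hits)) hits <- hits[keep]
  }
  if (length(unique(case_cnvs$cnv_type)) < 2L)
    stop("degenerate outcome: need both DEL and DUP case CNVs")
  rows <- build_design(case_cnvs, index, set, hits = hits)
  rows$y <- as.integer(case_cnvs$cnv_type == "DUP")
  lrt_enrichment(rows, set_id = set_id, stratum = "DUP_VS_DEL", firth = firth)
}

#' Leave-one-study-out sensitivity analysis
#'
#' Refits the enrichment test once per omitted study, identifies the
#' "most significant sample" — the study with the smallest *single-study*
#' enrichment p-value (fit on that study alone, so the study covariate
#' drops out), ties broken by lexicographic study ID — and reports the
#' refit without it as the `MINUS_BEST` analysis.
#'
#' @param cnvs a `cnv_table` covering at least two studies.
#' @param index a `gene_index`.
#' @param set character vector of set gene IDs.
#' @param set_id label.
#' @param hits optional precomputed hits.
#' @param firth use Firth-penalized fits.
#' @return list: `loso` (one result row per omitted study, analysis
#'   `LOSO:<study>`), `single_study` (per-study standalone results),
#'   `best_study`, `minus_best` (one result row, analysis `MINUS_BEST`).
#' @export
leave_one_study_out <- function(cnvs, index, set, set_id = "set",
                                hits = NULL, firth = FALSE) {
  studies <- sort(unique(cnvs$study_id))
  if (length(studies) < 2L) stop("leave-one-study-out requires at least two studies")
  if (is.null(hits)) hits <- genes_hit(cnvs, index)
  rows <- build_design(cnvs, index, set, hits = hits)
  one <- function(sub, stratum, analysis) {
    if (!nrow(sub) || all(sub$y == 1) || all(sub$y == 0))
      return(enrichment_result(set_id, stratum, analysis, nrow(sub), estimable = FALSE,
                               note = "subset lacks both outcome classes"))
    lrt_enrichment(sub, set_id = set_id, stratum = stratum, analysis = analysis,
                   firth = firth)
  }
  loso <- do.call(rbind, lapply(studies, function(s)
    one(rows[rows$study_id != s, , drop = FALSE], "ALL", paste0("LOSO:", s))))
  single <- do.call(rbind, lapply(studies, function(s)
    one(rows[rows$study_id == s, , drop = FALSE], "ALL", paste0("SINGLE:", s))))
  p <- ifelse(single$estimable, single$p_value, Inf)
  best <- studies[order(p, studies)][1]
  minus_best <- loso[match(paste0("LOSO:", best), loso$analysis), , drop = FALSE]
  minus_best$analysis <- "MINUS_BEST"
  minus_best$note <- paste0("omitted study ", best)
  rownames(minus_best) <- NULL
  list(loso = loso, single_study = single, best_study = best, minus_best = minus_best)
}

#' Gene-wise enrichment scan
#'
#' Runs the set test with each gene as its own "pathway": for every gene
#' hit by at least one CNV in the total sample, the singleton set `{g}`
#' is tested; genes never hit are skipped (and counted).
#'
#' @param cnvs a `cnv_table`.
#' @param index a `gene_index`.
#' @param hits optional precomputed hits.
#' @param firth use Firth-penalized fits.
#' @return list: `results` (one row per tested gene, `set_id` = gene ID),
#'   `n_skipped` (genes with zero hits).
#' @export
gene_wise_scan <- function(cnvs, index, hits = NULL, firth = FALSE) {
  if (is.null(hits)) hits <- genes_hit(cnvs, index)
  hit_genes <- sort(unique(unlist(hits)))
  n_tot <- lengths(hits)
  base <- data.frame(
    y = cnvs$is_case, study_id = cnvs$study_id,
    length_scaled = cnv_length(cnvs) / 1e5,
    cnv_type = cnvs$cnv_type, stringsAsFactors = FALSE)
  res <- lapply(hit_genes, function(g) {
    inset <- vapply(hits, function(h) g %in% h, logical(1))
    rows <- base
    rows$hit_in_set <- as.integer(inset)
    rows$n_genes_outside <- n_tot - rows$hit_in_set
    lrt_enrichment(rows, set_id = g, stratum = "ALL", firth = firth)
  })
  list(results = if (length(res)) do.call(rbind, res) else NULL,
       n_skipped = index$n_genes - length(hit_genes))
}

#' Hypothesis-free pathway screen with q-values
#'
#' Applies the screen's inclusion rules before testing: set size within
#' `[min_set_genes, max_set_genes]` genes, and at least `min_hits` gene
#' hits in the total sample (cases and controls pooled). "Gene hits" are
#' counted as (CNV, set-gene) incidence pairs by default — a CNV hitting
#' three set genes contributes three — or as distinct set-hitting CNVs
#' with `hit_count_mode = "distinct_cnvs"`. Sets with exactly
#' `min_hits - 1` hits are excluded (the rule is at-least). Surviving
#' sets are tested on the `ALL` stratum and Storey q-values attached.
#'
#' @param cnvs a `cnv_table`.
#' @param index a `gene_index`.
#' @param sets a `gene_set_list`.
#' @param min_set_genes,max_set_genes set-size window (defaults 3, 1500).
#' @param min_hits minimum gene hits in the total sample (default 10).
#' @param hit_count_mode `"incidence"` (default) or `"distinct_cnvs"`.
#' @param lambda Storey pi0 tuning value (default 0.5).
#' @param hits optional precomputed hits.
#' @param firth use Firth-penalized fits.
#' @return list: `results` (tested sets with `n_genes`, `n_hits`, the
#'   test columns and `q_value`), `exclusions` (set_id, reason),
#'   `pi0` (estimated null proportion).
#' @export
pathway_screen <- function(cnvs, index, sets, min_set_genes = 3,
                           max_set_genes = 1500, min_hits = 10,
                           hit_count_mode = c("incidence", "distinct_cnvs"),
                           lambda = 0.5, hits = NULL, firth = FALSE) {
  hit_count_mode <- match.arg(hit_count_mode)
  if (is.null(hits)) hits <- genes_hit(cnvs, index)
  sizes <- gene_set_sizes(sets)
  excl <- list(); keep_ids <- character(0); n_hits_kept <- integer(0)
  for (id in names(sets)) {
    sz <- sizes[[id]]
    if (sz < min_set_genes || sz > max_set_genes) {
      excl[[length(excl) + 1L]] <- data.frame(
        set_id = id, reason = sprintf("set size %d outside [%d, %d]", sz,
                                      as.integer(min_set_genes), as.integer(max_set_genes)))
      next
    }
    nh <- if (hit_count_mode == "incidence")
      sum(vapply(hits, function(h) sum(h %in% sets[[id]]), integer(1)))
    else sum(vapply(hits, function(h) any(h %in% sets[[id]]), logical(1)))
    if (nh < min_hits) {
      excl[[length(excl) + 1L]] <- data.frame(
        set_id = id, reason = sprintf("%d gene hits < %d", nh, as.integer(min_hits)))
      next
    }
    keep_ids <- c(keep_ids, id); n_hits_kept <- c(n_hits_kept, nh)
  }
  exclusions <- if (length(excl)) do.call(rbind, excl)
                else data.frame(set_id = character(), reason = character())
  if (!length(keep_ids))
    return(list(results = NULL, exclusions = exclusions, pi0 = NA_real_))
  res <- do.call(rbind, lapply(keep_ids, function(id)
    lrt_enrichment(build_design(cnvs, index, sets[[id]], hits = hits),
                   set_id = id, stratum = "ALL", firth = firth)))
  res$n_genes <- as.integer(sizes[keep_ids])
  res$n_hits <- n_hits_kept
  if (nrow(res) >= 2L) {
    qv <- storey_qvalues(res$p_value, lambda = lambda)
    res$q_value <- qv$q_values
    pi0 <- qv$pi0
  } else {
    # a single surviving test: the step-up formula degenerates to q = p
    res$q_value <- res$p_value
    pi0 <- 1
  }
  list(results = res, exclusions = exclusions, pi0 = pi0)
}
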