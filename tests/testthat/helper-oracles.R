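# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: the logistic oracle hand-codes Newton
# ascent on the Bernoulli log-likelihood over a model.matrix() design,
# interval oracles are O(n*m) scans or base-by-base masks, and the
# q-value oracle is a direct transcription of the step-up formula.

# Maximized deviance (-2 log-likelihood) by damped Newton ascent.
oracle_logistic_deviance <- function(X, y, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    p <- plogis(drop(X %*% beta))
    g <- crossprod(X, y - p)
    if (max(abs(g)) < 1e-11) break
    H <- crossprod(X * (p * (1 - p)))
    step <- solve(H + diag(1e-12, ncol(X)), g)
    # halve the step until the likelihood does not decrease
    ll <- sum(dbinom(y, 1, p, log = TRUE))
    for (h in 0:30) {
      cand <- beta + drop(step) / 2^h
      llc <- sum(dbinom(y, 1, plogis(drop(X %*% cand)), log = TRUE))
      if (llc >= ll - 1e-12) { beta <- cand; break }
    }
  }
  -2 * sum(dbinom(y, 1, plogis(drop(X %*% beta)), log = TRUE))
}

# Deviance difference (null vs +hit term) via the Newton oracle on
# model matrices built independently with stats::model.matrix.
oracle_lrt <- function(rows) {
  rows$study_id <- factor(rows$study_id)
  X0 <- model.matrix(~ study_id + length_scaled + n_genes_outside, rows)
  X1 <- model.matrix(~ study_id + length_scaled + n_genes_outside + hit_in_set, rows)
  oracle_logistic_deviance(X0, rows$y) - oracle_logistic_deviance(X1, rows$y)
}

# All-pairs interval overlap scan (0-based half-open).
oracle_overlaps <- function(q_chrom, q_start, q_end, genes) {
  hits <- genes$gene_id[genes$chrom == q_chrom &
                          genes$start < q_end & genes$end > q_start]
  sort(hits)
}

# Base-by-base union coverage of [start, end) by mask intervals.
oracle_union_coverage <- function(start, end, masks) {
  pos <- start:(end - 1)
  covered <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(masks)))
    covered <- covered | (pos >= masks$start[i] & pos < masks$end[i])
  mean(covered)
}

# Brute-force single-linkage clustering by repeated sweep.
oracle_clusters <- function(cnvs, recip = 0.5) {
  n <- nrow(cnvs)
  lab <- seq_len(n)
  linked <- function(i, j) {
    if (cnvs$cnv_type[i] != cnvs$cnv_type[j] || cnvs$chrom[i] != cnvs$chrom[j])
      return(FALSE)
    ov <- min(cnvs$end[i], cnvs$end[j]) - max(cnvs$start[i], cnvs$start[j])
    ov >= recip * (cnvs$end[i] - cnvs$start[i]) &&
      ov >= recip * (cnvs$end[j] - cnvs$start[j])
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && linked(i, j) && lab[j] != lab[i]) {
        lab[lab == lab[j]] <- lab[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# Direct transcription of the fixed-lambda q-value formula.
oracle_qvalues <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  pi0 <- max(pi0, 1 / m)
  ord <- order(p)
  q_sorted <- pi0 * m * p[ord] / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Exact two-sided binomial tail by enumeration.
oracle_binom_two_sided <- function(x, N, p0) {
  probs <- dbinom(0:N, N, p0)
  lower <- sum(probs[0:x + 1])
  upper <- sum(probs[(x:N) + 1])
  min(1, 2 * min(lower, upper))
}

# Random small regression designs without separation, for the LRT
# oracle-equivalence checks.
random_small_design <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(12:30, 1)
  rows <- data.frame(
    y = rbinom(n, 1, 0.5),
    study_id = sample(c("A", "B"), n, replace = TRUE),
    length_scaled = round(runif(n, 5, 15), 3),
    n_genes_outside = rpois(n, 2),
    hit_in_set = rbinom(n, 1, 0.4),
    cnv_type = sample(c("DEL", "DUP"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  ok <- length(unique(rows$y)) == 2 && length(unique(rows$hit_in_set)) == 2 &&
    all(table(rows$y, rows$hit_in_set) > 0) &&
    all(table(rows$y, rows$study_id) > 0)
  if (!ok) return(NULL)
  fit <- tryCatch(suppressWarnings(fit_logistic(rows)), error = function(e) NULL)
  if (is.null(fit) || !fit$converged || fit$separation_flag) return(NULL)
  rows
}

collect_small_designs <- function(k, seed0 = 100) {
  out <- list(); s <- seed0
  while (length(out) < k) {
    d <- random_small_design(s)
    if (!is.null(d)) out[[length(out) + 1L]] <- d
    s <- s + 1
  }
  out
}
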