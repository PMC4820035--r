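# Multiple-testing corrections: Bonferroni for small families of
# hypothesis-driven sets, Storey q-values for the hypothesis-free screen.

#' Bonferroni adjustment
#'
#' `min(1, p * m)`. `m` may exceed the number of p-values supplied (a
#' family can declare tests beyond those computed here).
#'
#' @param p p-values in \[0, 1\].
#' @param m family size, at least `length(p)`.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be at least length(p)")
  pmin(1, p * m)
}

#' Storey q-values with a fixed lambda
#'
#' Estimates the null proportion as
#' `pi0 = min(1, #\{p > lambda\} / (m (1 - lambda)))` and converts sorted
#' p-values to q-values by the step-up running minimum
#' `q(i) = min_\{j >= i\} pi0 m p(j) / j`, mapped back to input order.
#' A fixed `lambda` (default 0.5) keeps the estimate deterministic; the
#' spline-smoothed pi0 of some q-value software is deliberately not
#' implemented. When no p-value exceeds `lambda` the raw estimate is 0;
#' it is floored at `1/m` so q-values stay defined and positive.
#' Ties in `p` are ranked in stable input order.
#'
#' @param p vector of at least two p-values in \[0, 1\].
#' @param lambda tuning value in (0, 1), default 0.5.
#' @return list of class `qvalue_result`: `p_values`, `pi0`, `q_values`
#'   (input order), `lambda`.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  if (length(p) < 2L) stop("need at least two p-values")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (length(lambda) != 1L || lambda <= 0 || lambda >= 1)
    stop("lambda must lie strictly within (0, 1)")
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  pi0 <- max(pi0, 1 / m)
  ord <- order(p)                       # stable: ties keep input order
  ps <- p[ord]
  q <- pi0 * m * ps / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  structure(list(p_values = p, pi0 = pi0, q_values = out, lambda = lambda),
            class = "qvalue_result")
}
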