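# Ranking evaluation: global AUC over admission pairs, per-admission
# reciprocal-rank and top-k accuracy, and cross-metric correlation.

#' Global AUC over admission-pair records
#'
#' Probability that a randomly chosen shared-diagnosis pair scores above a
#' randomly chosen non-shared pair, with ties counted one half (the
#' Mann-Whitney formulation, computed via average ranks). The 95%
#' confidence interval uses the Hanley-McNeil parametric standard error
#' with `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`, clipped to
#' \[0, 1\].
#'
#' @param records data frame from [build_pair_records()] (columns `score`,
#'   `shared`).
#' @return List with `auc`, `ci_lo`, `ci_hi`, `n_pos`, `n_neg`.
#' @export
evaluate_auc <- function(records) {
  stopifnot(is.data.frame(records), all(c("score", "shared") %in% names(records)))
  pos <- records$shared
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: need at least one shared and one non-shared pair")
  r <- rank(records$score)           # average ranks handle ties with weight 1/2
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
               (n1 * n0))
  list(auc = auc,
       ci_lo = max(0, auc - 1.96 * se),
       ci_hi = min(1, auc + 1.96 * se),
       n_pos = n1, n_neg = n0)
}

#' Per-admission ranking metrics: MRR and top-k accuracy
#'
#' For each admission, all other admissions are ranked by similarity
#' (descending). The reciprocal rank is `1 / rank` of the highest-ranked
#' admission sharing its primary diagnosis, or 0 when no other admission
#' shares it. `mrr0` averages reciprocal ranks over all admissions;
#' `mrrna` averages over the matchable admissions only (those with at
#' least one same-diagnosis partner), so
#' `mrr0 = mrrna * n_matchable / n` holds identically. `a_at_k` is the
#' fraction of admissions (out of all n) whose first same-diagnosis
#' partner appears within the top `min(k, n - 1)`, with a Wald 95%
#' confidence interval.
#'
#' Tie policies for equal similarity scores:
#' * `"id"` (default): ties broken by ascending admission id — fully
#'   deterministic;
#' * `"mid"`: a tied match takes the average rank of its tie group;
#' * `"optimistic"` / `"pessimistic"`: a tied match takes the best / worst
#'   rank in its tie group.
#'
#' @param S similarity matrix from [compute_similarity_matrix()].
#' @param admissions the matching [labeled_admissions()].
#' @param k ranking cutoff (>= 1), default 10.
#' @param tie_policy one of `"id"`, `"mid"`, `"optimistic"`,
#'   `"pessimistic"`.
#' @return List with `mrr0`, `mrrna`, `a_at_k`, `a_ci_lo`, `a_ci_hi`,
#'   `n`, `n_matchable`. `mrrna` errors when no admission is matchable.
#' @export
evaluate_rankings <- function(S, admissions, k = 10,
                              tie_policy = c("id", "mid", "optimistic", "pessimistic")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(inherits(admissions, "labeled_admissions"))
  n <- length(admissions$ids)
  if (n < 2) stop("need at least two admissions to rank")
  if (!is.numeric(k) || length(k) != 1 || k < 1) stop("k must be >= 1")
  if (!is.matrix(S) || nrow(S) != n || ncol(S) != n)
    stop("similarity matrix dimensions do not match the admissions")

  kk <- min(k, n - 1)
  first_rank <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- S[i, -i]
    lab <- admissions$diagnoses[-i] == admissions$diagnoses[i]
    if (!any(lab)) next
    rk <- switch(tie_policy,
      id = {
        ord <- order(-s, admissions$ids[-i])
        pos <- integer(length(s)); pos[ord] <- seq_along(s)
        pos
      },
      mid = rank(-s, ties.method = "average"),
      optimistic = rank(-s, ties.method = "min"),
      pessimistic = rank(-s, ties.method = "max"))
    first_rank[i] <- min(rk[lab])
  }
  matchable <- !is.na(first_rank)
  n_matchable <- sum(matchable)
  rr <- ifelse(matchable, 1 / first_rank, 0)
  mrr0 <- mean(rr)
  if (n_matchable == 0)
    stop("MRR-NA undefined: no admission has a same-diagnosis partner")
  mrrna <- sum(rr) / n_matchable
  hit <- matchable & first_rank <= kk
  a_at_k <- mean(hit)
  se <- sqrt(a_at_k * (1 - a_at_k) / n)
  list(mrr0 = mrr0, mrrna = mrrna, a_at_k = a_at_k,
       a_ci_lo = max(0, a_at_k - 1.96 * se),
       a_ci_hi = min(1, a_at_k + 1.96 * se),
       n = n, n_matchable = n_matchable)
}

#' Pearson correlation between two evaluation metrics across configurations
#'
#' @param results data frame from [run_benchmark()] (only rows with
#'   `status == "ok"` are used).
#' @param metric_a,metric_b column names, e.g. `"auc"`, `"a10"`, `"mrr0"`.
#' @return List with `r` (Pearson correlation) and `p` (two-sided p-value
#'   from the t transform).
#' @export
correlate_metrics <- function(results, metric_a, metric_b) {
  ok <- results[results$status == "ok", , drop = FALSE]
  x <- ok[[metric_a]]; y <- ok[[metric_b]]
  if (is.null(x) || is.null(y)) stop("unknown metric column")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least three configurations to correlate")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("metric has zero variance across configurations")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
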