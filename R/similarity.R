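# Pairwise term-term and groupwise profile-profile similarity measures.
# Profiles are plain character vectors of term ids (a phenotype profile).

#' Rada path similarity between two terms
#'
#' `1 / (dist(x, y) + 1)` where `dist` is the shortest undirected `is_a`
#' path. Symmetric, in (0, 1], and 1 iff `x == y`.
#'
#' @param g an [ontology()].
#' @param x,y term ids.
#' @return Similarity in (0, 1].
#' @export
sim_rada <- function(g, x, y) {
  1 / (shortest_path_length(g, x, y) + 1)
}

#' Resnik pairwise similarity
#'
#' The information content of the most informative common ancestor of the
#' two terms. Symmetric and non-negative; equals `ic[x]` when `x == y`
#' (provided IC is monotone along subsumption, as all shipped measures
#' are).
#'
#' @param g an [ontology()].
#' @param x,y term ids.
#' @param ic an [ic_table] or named numeric vector.
#' @return Non-negative similarity.
#' @export
sim_resnik_pw <- function(g, x, y, ic) {
  mica(g, x, y, ic)$ic
}

#' Ancestor-overlap pairwise similarity (Jaccard / Dice)
#'
#' With X and Y the inclusive ancestor closures of the two terms:
#' `jaccard = |X n Y| / |X u Y|` and `dice = 2|X n Y| / (|X| + |Y|)`.
#' Both are symmetric, lie in \[0, 1\] and equal 1 iff the closures
#' coincide. The Dice variant is registered as the node-based pairwise
#' measure `node_sim`.
#'
#' @param g an [ontology()].
#' @param x,y term ids.
#' @param variant `"jaccard"` or `"dice"`.
#' @return Similarity in \[0, 1\].
#' @export
sim_ancestor_overlap <- function(g, x, y, variant = c("jaccard", "dice")) {
  variant <- match.arg(variant)
  i <- term_index(g, x); j <- term_index(g, y)
  X <- g$anc[[i]]; Y <- g$anc[[j]]
  inter <- length(intersect(X, Y))
  if (variant == "jaccard") inter / (length(X) + length(Y) - inter)
  else 2 * inter / (length(X) + length(Y))
}

check_profiles <- function(a, b) {
  if (length(a) == 0 && length(b) == 0)
    stop("cannot compare two empty phenotype profiles")
  if (length(a) == 0 || length(b) == 0) {
    message("comparison against an empty phenotype profile; returning 0")
    return(FALSE)
  }
  TRUE
}

#' Groupwise Jaccard similarity of two phenotype profiles
#'
#' Jaccard index `|A n B| / |A u B|` over the raw annotated term sets,
#' with no ancestor closure; see [gw_ui()] for the closure variant.
#'
#' @param a,b character vectors of term ids (phenotype profiles).
#' @return Similarity in \[0, 1\]; 0 when one profile is empty.
#' @export
gw_jaccard <- function(a, b) {
  if (!check_profiles(a, b)) return(0)
  a <- unique(a); b <- unique(b)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

profile_closure <- function(g, a) {
  unique(unlist(g$anc[term_index(g, unique(a))]))
}

#' Graph information content (GIC) similarity
#'
#' Ratio of summed IC over the intersection versus the union of the two
#' profiles' inclusive ancestor closures. Equals 1 when the closures are
#' identical; 0 when the shared closure (or, degenerately, the whole
#' union) carries zero total IC.
#'
#' @param g an [ontology()].
#' @param a,b phenotype profiles (character vectors of term ids).
#' @param ic an [ic_table] or named numeric vector covering the closures.
#' @return Similarity in \[0, 1\].
#' @export
gw_gic <- function(g, a, b, ic) {
  if (!check_profiles(a, b)) return(0)
  icv <- as_ic_values(ic)
  A <- profile_closure(g, a); B <- profile_closure(g, b)
  w <- unname(icv[g$terms])
  if (anyNA(w[union(A, B)])) stop("ic does not cover the profile closures")
  num <- sum(w[intersect(A, B)])
  den <- sum(w[union(A, B)])
  if (den == 0) {
    # degenerate zero-IC union: fall back to closure identity
    message("profile-closure union carries zero total IC")
    return(as.numeric(setequal(A, B)))
  }
  num / den
}

#' Union-intersection (closure Jaccard) similarity
#'
#' Unweighted counterpart of [gw_gic()]: Jaccard index over the two
#' profiles' inclusive ancestor closures.
#'
#' @inheritParams gw_gic
#' @return Similarity in \[0, 1\].
#' @export
gw_ui <- function(g, a, b) {
  if (!check_profiles(a, b)) return(0)
  A <- profile_closure(g, a); B <- profile_closure(g, b)
  inter <- length(intersect(A, B))
  inter / (length(A) + length(B) - inter)
}

#' Pairwise similarity matrix over a set of terms
#'
#' Computes the full term-term similarity matrix for one pairwise measure
#' over a term subset, the workhorse behind indirect groupwise measures.
#' The Resnik route exploits that the IC of the most informative common
#' ancestor of every pair can be filled by sweeping ancestors in order of
#' increasing IC and overwriting their descendant blocks.
#'
#' @param g an [ontology()].
#' @param terms character vector of term ids (deduplicated).
#' @param pairwise one of `"rada"`, `"jaccard_pw"`, `"node_sim"`,
#'   `"resnik"`.
#' @param ic IC values, required for `"resnik"`.
#' @return A symmetric numeric matrix with `terms` as dimnames.
#' @export
term_sim_matrix <- function(g, terms, pairwise, ic = NULL) {
  terms <- unique(terms)
  idx <- term_index(g, terms)
  m <- length(terms)
  M <- switch(pairwise,
    rada = {
      D <- igraph::distances(g$graph, v = idx, to = idx)
      1 / (D + 1)
    },
    jaccard_pw = ,
    node_sim = {
      A <- matrix(0, m, length(g$terms))
      for (v in seq_len(m)) A[v, g$anc[[idx[v]]]] <- 1
      inter <- tcrossprod(A)
      sz <- rowSums(A)
      if (pairwise == "jaccard_pw") inter / (outer(sz, sz, "+") - inter)
      else 2 * inter / outer(sz, sz, "+")
    },
    resnik = {
      if (is.null(ic)) stop("pairwise measure 'resnik' requires an IC table")
      icv <- as_ic_values(ic)
      w <- unname(icv[g$terms])
      if (anyNA(w)) stop("ic does not cover all ontology terms")
      members <- vector("list", length(g$terms))
      for (v in seq_len(m)) for (a in g$anc[[idx[v]]])
        members[[a]] <- c(members[[a]], v)
      M <- matrix(0, m, m)
      for (a in order(w)) {
        mem <- members[[a]]
        if (length(mem)) M[mem, mem] <- w[a]
      }
      M
    },
    stop("unknown pairwise measure: ", pairwise))
  dimnames(M) <- list(terms, terms)
  M
}

#' Indirect groupwise similarity
#'
#' Aggregates the m x n matrix S of pairwise term similarities between
#' profiles A (rows) and B (columns):
#'
#' * `MAX` / `MIN`: extreme entry of S;
#' * `AVG`: mean over all m*n entries;
#' * `BMA` (best-match average): mean of per-row maxima averaged with the
#'   mean of per-column maxima;
#' * `BMM` (best-match maximum): the larger of those two means.
#'
#' All are symmetric whenever the pairwise measure is.
#'
#' @param g an [ontology()].
#' @param a,b phenotype profiles (character vectors of term ids).
#' @param pairwise pairwise measure id (see [term_sim_matrix()]).
#' @param aggregator one of `"max"`, `"min"`, `"avg"`, `"bma"`, `"bmm"`.
#' @param ic IC values, required when the pairwise measure needs them.
#' @return Aggregated similarity; 0 when one profile is empty.
#' @export
gw_indirect <- function(g, a, b, pairwise, aggregator = c("max", "min", "avg", "bma", "bmm"),
                        ic = NULL) {
  aggregator <- match.arg(aggregator)
  if (!check_profiles(a, b)) return(0)
  if (pairwise == "resnik" && is.null(ic))
    stop("configuration ", aggregator, "+", pairwise, " requires an IC table")
  a <- unique(a); b <- unique(b)
  M <- term_sim_matrix(g, union(a, b), pairwise, ic = ic)
  S <- M[a, b, drop = FALSE]
  aggregate_pair_matrix(S, aggregator)
}

aggregate_pair_matrix <- function(S, aggregator) {
  switch(aggregator,
    max = max(S),
    min = min(S),
    avg = mean(S),
    bma = (mean(apply(S, 1, max)) + mean(apply(S, 2, max))) / 2,
    bmm = max(mean(apply(S, 1, max)), mean(apply(S, 2, max))),
    stop("unknown aggregator: ", aggregator))
}
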