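# Shared fixtures and independent brute-force oracles. The oracles work
# on a bare named parents list (term -> character vector of parents) so
# they share no code with the package internals they check.

# Toy DAG T: root r; a,b <- r; c,d <- a; e <- b; f <- c.
toy_parents <- function() {
  list(r = character(), a = "r", b = "r", c = "a", d = "a", e = "b", f = "c")
}
toy_ontology <- function() ontology(toy_parents())

# Toy corpus C over T.
toy_corpus <- function() {
  annotation_corpus(list(P1 = "f", P2 = "d", P3 = "e", P4 = c("c", "e")))
}

# Inclusive ancestor closure by repeated parent expansion.
oracle_closure <- function(parents, t) {
  seen <- t
  frontier <- t
  while (length(frontier)) {
    up <- unique(unlist(parents[frontier]))
    frontier <- setdiff(up, seen)
    seen <- union(seen, frontier)
  }
  sort(seen)
}

# Inclusive descendant set: terms whose closure contains t.
oracle_descendants <- function(parents, t) {
  ids <- names(parents)
  sort(ids[vapply(ids, function(x) t %in% oracle_closure(parents, x), logical(1))])
}

# Breadth-first search over the undirected is_a edge set.
oracle_bfs_dist <- function(parents, x, y) {
  ids <- names(parents)
  nb <- setNames(lapply(ids, function(t) {
    down <- ids[vapply(ids, function(c) t %in% parents[[c]], logical(1))]
    union(parents[[t]], down)
  }), ids)
  dist <- setNames(rep(Inf, length(ids)), ids)
  dist[x] <- 0
  frontier <- x
  while (length(frontier) && is.infinite(dist[y])) {
    nxt <- setdiff(unique(unlist(nb[frontier])), ids[is.finite(dist)])
    dist[nxt] <- min(dist[frontier]) + 1
    frontier <- nxt
  }
  unname(dist[y])
}

# Corpus IC by direct descendant-closure counting (annotation pairs).
oracle_corpus_ic <- function(parents, annotations) {
  all_terms <- unlist(annotations, use.names = FALSE)
  total <- length(all_terms)
  ids <- names(parents)
  setNames(vapply(ids, function(x) {
    desc <- oracle_descendants(parents, x)
    cnt <- sum(all_terms %in% desc)
    if (cnt > 0) -log(cnt / total) else -log(1 / (total + 1))
  }, numeric(1)), ids)
}

# Max-IC common ancestor by exhaustive enumeration.
oracle_mica_ic <- function(parents, x, y, icv) {
  common <- intersect(oracle_closure(parents, x), oracle_closure(parents, y))
  max(icv[common])
}

# AUC by brute force over every (shared, non-shared) comparison.
oracle_auc <- function(scores, shared) {
  pos <- scores[shared]; neg <- scores[!shared]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Random rooted DAG as a parents list (independent of the synthetic module:
# different id scheme and wiring rule).
oracle_random_dag <- function(n, seed, p_extra = 0.3) {
  set.seed(seed)
  ids <- sprintf("t%02d", seq_len(n))
  parents <- setNames(vector("list", n), ids)
  parents[[1]] <- character()
  for (i in seq_len(n)[-1]) {
    k <- if (i > 2 && runif(1) < p_extra) 2 else 1
    parents[[i]] <- sample(ids[seq_len(i - 1)], min(k, i - 1))
  }
  parents
}

# Random profile over an ontology's terms.
random_profile <- function(g, size) sample(g$terms, size)
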