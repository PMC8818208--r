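# Information-content measures: corpus-based (annotation frequency) and
# structural (term specificity from the taxonomy alone).

#' Information-content table
#'
#' A per-term specificity weight in nats, together with the id of the
#' method that produced it.
#'
#' @param method method id (e.g. `"resnik"`, `"seco"`).
#' @param values named numeric vector, term id -> IC; finite, >= 0.
#' @return An object of class `ic_table`.
#' @export
ic_table <- function(method, values) {
  stopifnot(is.character(method), length(method) == 1,
            is.numeric(values), !is.null(names(values)))
  if (any(!is.finite(values)) || any(values < 0))
    stop("IC values must be finite and non-negative")
  structure(list(method = method, values = values), class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat("ic_table [", x$method, "]: ", length(x$values), " terms, range ",
      sprintf("%.4g..%.4g", min(x$values), max(x$values)), "\n", sep = "")
  invisible(x)
}

# Accept either an ic_table or a bare named numeric vector.
as_ic_values <- function(ic) {
  if (inherits(ic, "ic_table")) return(ic$values)
  if (is.numeric(ic) && !is.null(names(ic))) return(ic)
  stop("expected an ic_table or a named numeric vector")
}

#' Annotation corpus
#'
#' An entity -> term-set map, the basis of corpus (annotation-frequency)
#' information content. Entities are typically patients or hospital
#' admissions; terms are phenotype classes.
#'
#' @param annotations named list; names are entity ids, elements character
#'   vectors of term ids. Term sets are deduplicated.
#' @return An object of class `annotation_corpus`.
#' @export
annotation_corpus <- function(annotations) {
  stopifnot(is.list(annotations))
  if (length(annotations) &&
      (is.null(names(annotations)) || any(names(annotations) == "")))
    stop("every entity needs an id")
  if (anyDuplicated(names(annotations)))
    stop("duplicated entity ids")
  structure(lapply(annotations, function(x) unique(as.character(x))),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("annotation_corpus: ", length(x), " entities, ",
      sum(lengths(x)), " annotations\n", sep = "")
  invisible(x)
}

#' Corpus (annotation-frequency) information content
#'
#' For each term x, counts the annotations attached to x or any of its
#' descendants, converts to a probability `p(x) = |I(x)| / |I|` over the
#' full annotation set I, and returns `IC(x) = -ln p(x)`. Terms whose
#' descendant closure carries no annotation receive the pseudocount value
#' `-ln(1 / (|I| + 1))`, slightly above the largest observed
#' single-annotation IC, so values stay finite while unseen terms remain
#' the most informative.
#'
#' @param g an [ontology()].
#' @param corpus an [annotation_corpus()]; all annotated terms must exist
#'   in `g`.
#' @param count `"pairs"` (default) counts (entity, term) annotation
#'   pairs; `"entities"` counts distinct entities per term closure.
#' @return An [ic_table] with method id `"resnik"`.
#' @export
corpus_ic <- function(g, corpus, count = c("pairs", "entities")) {
  count <- match.arg(count)
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (length(corpus) == 0 || sum(lengths(corpus)) == 0)
    stop("empty annotation corpus")
  n <- length(g$terms)
  idx <- lapply(corpus, function(ts) term_index(g, ts))

  closed <- numeric(n)
  if (count == "pairs") {
    total <- sum(lengths(idx))
    for (ts in idx) for (t in ts) {
      a <- g$anc[[t]]
      closed[a] <- closed[a] + 1
    }
  } else {
    total <- length(idx)
    for (ts in idx) {
      a <- unique(unlist(g$anc[ts]))
      closed[a] <- closed[a] + 1
    }
  }
  p <- closed / total
  icv <- ifelse(closed > 0, -log(p), -log(1 / (total + 1)))
  names(icv) <- g$terms
  ic_table("resnik", icv)
}

#' Structural information content
#'
#' Term specificity computed from the taxonomy alone. With N the number of
#' terms, `hypo(x)` the exclusive descendant count, D the maximum depth of
#' the ontology, `leaves(x)` the leaf-descendant count (a leaf counts
#' itself), `subs(x)` the inclusive ancestor count and L the total number
#' of leaves:
#'
#' * `seco`: `1 - ln(hypo(x) + 1) / ln N`
#' * `zhou`: `k * seco(x) + (1 - k) * ln(max_depth(x) + 1) / ln(D + 1)`
#' * `sanchez`: `-ln( (leaves(x)/subs(x) + 1) / (L + 1) )`
#' * `depth_max`: `ln(max_depth(x) + 1) / ln(D + 1)`
#' * `depth_min`: `ln(min_depth(x) + 1) / ln(D + 1)`
#'
#' `seco`, `zhou` and the depth variants lie in \[0, 1\]; `sanchez` is
#' non-negative and unbounded.
#'
#' @param g an [ontology()].
#' @param method one of `"seco"`, `"zhou"`, `"sanchez"`, `"depth_max"`,
#'   `"depth_min"`.
#' @param k depth/descendant mixing weight for `zhou`, in \[0, 1\].
#' @param stats optional precomputed [term_stats()] table.
#' @return An [ic_table] with the method id.
#' @export
structural_ic <- function(g, method, k = 0.5, stats = NULL) {
  valid <- c("seco", "zhou", "sanchez", "depth_max", "depth_min")
  if (!is.character(method) || length(method) != 1 || !method %in% valid)
    stop("unknown structural IC method; valid ids: ", paste(valid, collapse = ", "))
  if (is.null(stats)) stats <- term_stats(g)
  n <- nrow(stats)
  D <- max(stats$max_depth)
  L <- sum(lengths(g$children) == 0)

  seco <- if (n > 1) 1 - log(stats$n_descendants + 1) / log(n) else rep(1, n)
  dmax <- if (D > 0) log(stats$max_depth + 1) / log(D + 1) else rep(0, n)
  dmin <- if (D > 0) log(stats$min_depth + 1) / log(D + 1) else rep(0, n)

  icv <- switch(method,
    seco = seco,
    zhou = {
      stopifnot(k >= 0, k <= 1)
      k * seco + (1 - k) * dmax
    },
    sanchez = -log((stats$n_leaves_below / stats$n_subsumers + 1) / (L + 1)),
    depth_max = dmax,
    depth_min = dmin)
  icv <- pmax(icv, 0)   # guard tiny negative rounding
  names(icv) <- stats$term
  ic_table(method, icv)
}

#' Structural IC method ids
#'
#' @return Character vector of the structural IC method ids understood by
#'   [structural_ic()].
#' @export
structural_ic_methods <- function() c("seco", "zhou", "sanchez", "depth_max", "depth_min")

#' IC method ids available to the benchmark
#'
#' `"resnik"` is the corpus (annotation-frequency) measure; the rest are
#' structural.
#'
#' @return Character vector of IC method ids.
#' @export
default_ic_methods <- function() c("resnik", structural_ic_methods())

# Resolve an IC id to an ic_table, caching in `cache` (an environment).
resolve_ic <- function(g, corpus, ic_id, cache = NULL, stats = NULL) {
  if (!is.null(cache) && !is.null(cache[[ic_id]])) return(cache[[ic_id]])
  tab <- if (ic_id == "resnik") {
    if (is.null(corpus)) stop("IC method 'resnik' needs an annotation corpus")
    corpus_ic(g, corpus)
  } else {
    structural_ic(g, ic_id, stats = stats)
  }
  if (!is.null(cache)) cache[[ic_id]] <- tab
  tab
}
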