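# Subsumption taxonomy: construction, OBO parsing, and graph queries.

#' Construct an ontology from term ids and is_a parent lists
#'
#' Builds a rooted, acyclic subsumption taxonomy from explicit `is_a`
#' edges. Exactly one term must be parentless (the root) unless
#' `virtual_root = TRUE`, in which case a synthetic root is inserted
#' above every parentless term.
#'
#' @param parents named list; names are term ids, each element a character
#'   vector of direct `is_a` parent ids (empty for the root).
#' @param virtual_root if `TRUE` and several terms are parentless, a
#'   synthetic root (id `"VIRTUAL:ROOT"`) is added above all of them.
#' @return An object of class `ontology` with elements `terms` (character
#'   vector of ids), `parents` / `children` / `anc` (lists of integer
#'   indices; `anc` is the inclusive ancestor closure), `root` (index) and
#'   `graph` (the undirected \pkg{igraph} view used for path queries).
#' @examples
#' g <- ontology(list(r = character(), a = "r", b = "r"))
#' ancestors(g, "a")
#' @export
ontology <- function(parents, virtual_root = FALSE) {
  stopifnot(is.list(parents), length(parents) >= 1)
  ids <- names(parents)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every term needs a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicated term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))

  parents <- lapply(parents, function(p) unique(as.character(p)))
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown))
    stop("is_a parents not present as terms: ", paste(unknown, collapse = ", "))

  parentless <- ids[lengths(parents) == 0]
  if (length(parentless) == 0)
    stop("no parentless term: the taxonomy has no root (is_a cycle?)")
  if (length(parentless) > 1) {
    if (!virtual_root)
      stop("multiple parentless terms (", paste(parentless, collapse = ", "),
           "); supply virtual_root = TRUE to insert a synthetic root")
    vroot <- "VIRTUAL:ROOT"
    if (vroot %in% ids) stop("id clash with synthetic root id ", vroot)
    parents[parentless] <- list(vroot)
    parents[[vroot]] <- character()
    ids <- names(parents)
    parentless <- vroot
  }

  n <- length(ids)
  idx <- seq_len(n)
  names(idx) <- ids
  par_idx <- lapply(parents, function(p) unname(idx[p]))
  chi_idx <- vector("list", n)
  for (i in idx) for (p in par_idx[[i]]) chi_idx[[p]] <- c(chi_idx[[p]], i)
  chi_idx <- lapply(chi_idx, function(v) if (is.null(v)) integer() else v)

  # Kahn topological order (parents before children); detects cycles.
  indeg <- lengths(par_idx)
  queue <- which(indeg == 0L)
  topo <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    topo <- c(topo, v)
    for (c in chi_idx[[v]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(topo) < n) {
    cyc <- ids[indeg > 0]
    stop("is_a cycle involving: ", paste(utils::head(cyc, 10), collapse = ", "))
  }

  # Inclusive ancestor closure in topological order.
  anc <- vector("list", n)
  for (v in topo) {
    up <- par_idx[[v]]
    anc[[v]] <- if (length(up)) sort(unique(c(v, unlist(anc[up])))) else v
  }
  root <- unname(idx[parentless])
  bad <- which(!vapply(anc, function(a) root %in% a, logical(1)))
  if (length(bad))
    stop("terms not reaching the root: ", paste(ids[bad], collapse = ", "))

  edges <- cbind(rep.int(idx, lengths(par_idx)), unlist(par_idx))
  gr <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) gr <- igraph::add_edges(gr, t(edges))

  structure(list(terms = ids, parents = par_idx, children = chi_idx,
                 anc = anc, topo = topo, root = root, graph = gr),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology: ", length(x$terms), " terms, ",
      sum(lengths(x$parents)), " is_a edges, root ", x$terms[x$root],
      "\n", sep = "")
  invisible(x)
}

term_index <- function(g, t) {
  i <- match(t, g$terms)
  if (anyNA(i)) stop("unknown term(s): ", paste(t[is.na(i)], collapse = ", "))
  i
}

#' Read an OBO flat file into an ontology
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file, keeping `id:`, `is_a:`
#' (with trailing `!` comments stripped) and `is_obsolete:`. Obsolete
#' terms are dropped; a term whose parents are all obsolete is re-rooted
#' under its nearest non-obsolete ancestor reachable through obsolete
#' `is_a` chains, or attached to the root when none exists. All other
#' stanza types, tags and header metadata are ignored, so only the
#' asserted subsumptive (`is_a`) hierarchy is loaded.
#'
#' @param path path to an OBO file, or a character vector of its lines.
#' @param virtual_root passed to [ontology()]: insert a synthetic root
#'   when the file has several parentless terms.
#' @return An [ontology()] object over the non-obsolete terms.
#' @export
read_obo <- function(path, virtual_root = FALSE) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- sub("\\s+$", "", lines)

  stanza <- NULL
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list(id = NULL, is_a = character(), obsolete = FALSE)
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "is_a:")) {
      v <- sub("!.*$", "", sub("^is_a:", "", ln))
      cur$is_a <- c(cur$is_a, trimws(v))
    } else if (startsWith(ln, "is_obsolete:")) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    }
  }
  flush()
  if (!length(terms)) stop("no [Term] stanzas found")

  obsolete <- vapply(terms, `[[`, logical(1), "obsolete")
  raw_parents <- lapply(terms, `[[`, "is_a")
  keep <- names(terms)[!obsolete]
  if (!length(keep)) stop("all terms are obsolete")

  # Resolve parents through obsolete chains to the nearest live ancestor.
  resolve <- function(pids, seen = character()) {
    out <- character()
    for (p in pids) {
      if (p %in% seen) next            # obsolete cycle: drop the edge
      if (!p %in% names(terms)) next   # dangling reference: drop
      if (!obsolete[[p]]) out <- c(out, p)
      else out <- c(out, resolve(raw_parents[[p]], c(seen, p)))
    }
    unique(out)
  }
  parents <- lapply(keep, function(id) {
    had <- length(raw_parents[[id]]) > 0
    res <- resolve(raw_parents[[id]])
    attr(res, "orphaned") <- had && length(res) == 0
    res
  })
  names(parents) <- keep

  orphaned <- keep[vapply(parents, function(p) isTRUE(attr(p, "orphaned")), logical(1))]
  parents <- lapply(parents, function(p) { attributes(p) <- NULL; p })
  roots <- setdiff(keep[lengths(parents) == 0], orphaned)
  if (length(roots) == 1 && length(orphaned)) {
    # terms whose every parent chain was obsolete hang off the root
    parents[orphaned] <- list(roots)
  }
  ontology(parents, virtual_root = virtual_root)
}

#' Ancestors and descendants of a term
#'
#' The transitive closure of `is_a` edges. `ancestors()` always contains
#' the root; with `include_self = TRUE` (default) the term itself is a
#' member of either closure.
#'
#' @param g an [ontology()].
#' @param t a term id.
#' @param include_self include `t` itself in the returned set.
#' @return Character vector of term ids.
#' @export
ancestors <- function(g, t, include_self = TRUE) {
  i <- term_index(g, t)
  a <- g$terms[g$anc[[i]]]
  if (!include_self) a <- setdiff(a, t)
  a
}

#' @rdname ancestors
#' @export
descendants <- function(g, t, include_self = TRUE) {
  i <- term_index(g, t)
  d <- g$terms[vapply(g$anc, function(a) i %in% a, logical(1))]
  if (!include_self) d <- setdiff(d, t)
  d
}

#' Per-term structural statistics
#'
#' Support values for structural information-content measures: root-relative
#' depths (edge counts; shortest and longest root path), exclusive descendant
#' count, leaf-descendant count (a leaf counts itself), and inclusive
#' subsumer (ancestor) count.
#'
#' @param g an [ontology()].
#' @return A data frame with one row per term and columns `term`,
#'   `min_depth`, `max_depth`, `n_descendants`, `n_leaves_below`,
#'   `n_subsumers`.
#' @export
term_stats <- function(g) {
  n <- length(g$terms)
  min_d <- rep(NA_integer_, n); max_d <- rep(NA_integer_, n)
  min_d[g$root] <- 0L; max_d[g$root] <- 0L
  for (v in g$topo) {
    up <- g$parents[[v]]
    if (length(up)) {
      min_d[v] <- min(min_d[up]) + 1L
      max_d[v] <- max(max_d[up]) + 1L
    }
  }
  n_desc <- integer(n); n_leaf <- integer(n)
  is_leaf <- lengths(g$children) == 0
  for (v in seq_len(n)) {
    a <- g$anc[[v]]
    n_desc[a] <- n_desc[a] + 1L           # inclusive for now
    if (is_leaf[v]) n_leaf[a] <- n_leaf[a] + 1L
  }
  data.frame(term = g$terms,
             min_depth = min_d,
             max_depth = max_d,
             n_descendants = n_desc - 1L,  # exclusive
             n_leaves_below = n_leaf,
             n_subsumers = lengths(g$anc),
             row.names = g$terms,
             stringsAsFactors = FALSE)
}

#' Shortest undirected is_a path between two terms
#'
#' Minimum number of `is_a` edges connecting `x` and `y`, edges traversed
#' in either direction (the distance underlying the Rada path measure).
#'
#' @param g an [ontology()].
#' @param x,y term ids.
#' @return Non-negative integer edge count.
#' @export
shortest_path_length <- function(g, x, y) {
  i <- term_index(g, x); j <- term_index(g, y)
  as.integer(igraph::distances(g$graph, v = i, to = j)[1, 1])
}

#' Most informative common ancestor of two terms
#'
#' Among the common inclusive ancestors of `x` and `y`, returns a term of
#' maximal information content. Ties are broken by the lexicographically
#' smallest term id so the result is deterministic.
#'
#' @param g an [ontology()].
#' @param x,y term ids.
#' @param ic an [ic_table] or named numeric vector of IC values covering
#'   all common ancestors.
#' @return A list with elements `term` and `ic`.
#' @export
mica <- function(g, x, y, ic) {
  icv <- as_ic_values(ic)
  i <- term_index(g, x); j <- term_index(g, y)
  common <- g$terms[intersect(g$anc[[i]], g$anc[[j]])]
  vals <- icv[common]
  if (anyNA(vals)) stop("ic does not cover common ancestors: ",
                        paste(common[is.na(vals)], collapse = ", "))
  best <- vals == max(vals)
  pick <- sort(common[best])[1]
  list(term = pick, ic = unname(vals[[pick]]))
}
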