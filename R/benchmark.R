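# Configuration sweep: enumerate measure combinations, build all-pairs
# similarity matrices over labeled admissions, and evaluate each setting.

#' Labeled admissions
#'
#' A set of hospital admissions, each carrying a phenotype profile and a
#' primary diagnosis code (an opaque string such as an ICD-9 code).
#'
#' @param ids character vector of unique admission ids.
#' @param profiles list of character vectors (term ids), parallel to `ids`.
#' @param diagnoses character vector of non-empty diagnosis codes,
#'   parallel to `ids`.
#' @return An object of class `labeled_admissions` with elements `ids`,
#'   `profiles`, `diagnoses`.
#' @export
labeled_admissions <- function(ids, profiles, diagnoses) {
  ids <- as.character(ids); diagnoses <- as.character(diagnoses)
  stopifnot(length(ids) == length(profiles), length(ids) == length(diagnoses))
  if (anyDuplicated(ids)) stop("duplicated admission ids")
  if (any(is.na(diagnoses) | diagnoses == "")) stop("every admission needs a diagnosis code")
  profiles <- lapply(profiles, function(p) unique(as.character(p)))
  names(profiles) <- ids
  structure(list(ids = ids, profiles = profiles, diagnoses = diagnoses),
            class = "labeled_admissions")
}

#' @export
print.labeled_admissions <- function(x, ...) {
  cat("labeled_admissions: ", length(x$ids), " admissions, ",
      length(unique(x$diagnoses)), " distinct diagnoses, mean profile size ",
      sprintf("%.1f", mean(lengths(x$profiles))), "\n", sep = "")
  invisible(x)
}

#' @export
length.labeled_admissions <- function(x) length(x$ids)

#' Enumerate similarity configurations
#'
#' Expands a measure registry and an IC roster into the full set of
#' experimental settings, deterministically ordered (lexicographic over
#' groupwise, pairwise, IC):
#'
#' 1. each direct groupwise measure, crossed with every IC measure when it
#'    requires one;
#' 2. each indirect groupwise measure crossed with every non-IC pairwise
#'    measure;
#' 3. each indirect groupwise measure crossed with every IC-using pairwise
#'    measure and every IC measure.
#'
#' @param registry a measure registry (see [default_registry()]).
#' @param ics character vector of IC method ids (see
#'   [default_ic_methods()]).
#' @return A data frame with columns `config_id`, `groupwise`, `pairwise`,
#'   `ic` (`NA` where a component does not apply). Config ids are stable
#'   across runs.
#' @export
enumerate_configs <- function(registry = default_registry(),
                              ics = default_ic_methods()) {
  validate_registry(registry)
  ics <- sort(unique(as.character(ics)))
  direct <- registry[registry$level == "groupwise-direct", ]
  indirect <- registry[registry$level == "groupwise-indirect", ]
  pw <- registry[registry$level == "pairwise", ]

  rows <- list()
  for (i in seq_len(nrow(direct))) {
    gwid <- direct$id[i]
    if (direct$needs_ic[i]) {
      for (ic in ics) rows[[length(rows) + 1]] <- c(gwid, NA, ic)
    } else rows[[length(rows) + 1]] <- c(gwid, NA, NA)
  }
  for (i in seq_len(nrow(indirect))) {
    gwid <- indirect$id[i]
    for (j in seq_len(nrow(pw))) {
      pwid <- pw$id[j]
      if (pw$needs_ic[j]) {
        for (ic in ics) rows[[length(rows) + 1]] <- c(gwid, pwid, ic)
      } else rows[[length(rows) + 1]] <- c(gwid, pwid, NA)
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (nrow(out) == 0)
    return(data.frame(config_id = character(), groupwise = character(),
                      pairwise = character(), ic = character(),
                      stringsAsFactors = FALSE))
  names(out) <- c("groupwise", "pairwise", "ic")
  key <- function(v) ifelse(is.na(v), "", v)
  out <- out[order(out$groupwise, key(out$pairwise), key(out$ic)), , drop = FALSE]
  out$config_id <- apply(out, 1, function(r) paste(r[!is.na(r)], collapse = "+"))
  rownames(out) <- NULL
  out[, c("config_id", "groupwise", "pairwise", "ic")]
}

# Resolve one config row (list or one-row data frame) against the registry.
config_components <- function(config, registry = default_registry()) {
  cfg <- as.list(config)
  gw <- as.character(cfg$groupwise)
  pwid <- if (is.null(cfg$pairwise) || is.na(cfg$pairwise)) NA_character_ else as.character(cfg$pairwise)
  icid <- if (is.null(cfg$ic) || is.na(cfg$ic)) NA_character_ else as.character(cfg$ic)
  row <- registry[registry$id == gw & grepl("^groupwise", registry$level), ]
  if (nrow(row) != 1) stop("unknown groupwise measure: ", gw)
  indirect <- row$level == "groupwise-indirect"
  if (indirect && is.na(pwid))
    stop("indirect groupwise measure '", gw, "' needs a pairwise measure")
  needs_ic <- row$needs_ic
  if (!is.na(pwid)) {
    prow <- registry[registry$id == pwid & registry$level == "pairwise", ]
    if (nrow(prow) != 1) stop("unknown pairwise measure: ", pwid)
    needs_ic <- needs_ic || prow$needs_ic
  }
  if (needs_ic && is.na(icid))
    stop("configuration ", gw,
         if (!is.na(pwid)) paste0("+", pwid) else "", " needs an IC measure")
  list(groupwise = gw, pairwise = pwid, ic = icid, indirect = indirect)
}

#' All-pairs similarity matrix for one configuration
#'
#' Applies the configured groupwise measure to every unordered pair of
#' admission profiles (computed once and mirrored), including the
#' diagonal self-similarities.
#'
#' @param g an [ontology()].
#' @param corpus an [annotation_corpus()] (used when the configuration
#'   involves corpus IC; may be `NULL` otherwise).
#' @param admissions a [labeled_admissions()].
#' @param config one row of [enumerate_configs()] (or a list with
#'   `groupwise`, optionally `pairwise` and `ic`).
#' @param registry the measure registry the config refers to.
#' @param ic_cache optional environment caching IC tables across configs.
#' @param verbose log per-config progress.
#' @return A symmetric numeric matrix with admission ids as dimnames.
#' @export
compute_similarity_matrix <- function(g, corpus, admissions, config,
                                      registry = default_registry(),
                                      ic_cache = NULL, verbose = FALSE) {
  stopifnot(inherits(admissions, "labeled_admissions"))
  cmp <- config_components(config, registry)
  n <- length(admissions$ids)
  profs <- admissions$profiles
  icv <- NULL
  if (!is.na(cmp$ic)) icv <- resolve_ic(g, corpus, cmp$ic, cache = ic_cache)
  if (verbose)
    message("computing similarity matrix: ", paste(unlist(cmp[1:3])[!is.na(unlist(cmp[1:3]))], collapse = "+"),
            " over ", n, " admissions")

  if (!cmp$indirect) {
    S <- direct_gw_matrix(g, profs, cmp$groupwise, icv)
  } else {
    S <- indirect_gw_matrix(g, profs, cmp$pairwise, cmp$groupwise, icv)
  }
  dimnames(S) <- list(admissions$ids, admissions$ids)
  S
}

# Direct groupwise matrices via incidence-matrix algebra.
direct_gw_matrix <- function(g, profs, gw, icv) {
  n <- length(profs)
  nt <- length(g$terms)
  if (any(lengths(profs) == 0)) {
    empties <- sum(lengths(profs) == 0)
    if (empties == n) stop("cannot compare two empty phenotype profiles")
    message(empties, " empty profile(s); their similarities are 0")
  }
  P <- matrix(0, n, nt)
  for (i in seq_len(n)) {
    if (!length(profs[[i]])) next
    ti <- term_index(g, profs[[i]])
    if (gw == "jaccard") P[i, ti] <- 1
    else P[i, unique(unlist(g$anc[ti]))] <- 1
  }
  if (gw == "gic") {
    w <- unname(as_ic_values(icv)[g$terms])
    if (anyNA(w)) stop("ic does not cover all ontology terms")
    inter <- tcrossprod(P * rep(w, each = n), P)
    sz <- drop(P %*% w)
  } else {
    inter <- tcrossprod(P)
    sz <- rowSums(P)
  }
  den <- outer(sz, sz, "+") - inter
  S <- ifelse(den > 0, inter / den, 0)
  if (gw == "gic" && any(den <= 0)) {
    # zero-IC unions between nonempty profiles: fall back to closure identity
    inter0 <- tcrossprod(P)
    sz0 <- rowSums(P)
    identical_cl <- (inter0 == outer(sz0, sz0, pmax)) & outer(sz0 > 0, sz0 > 0, "&")
    S[den <= 0 & identical_cl] <- 1
  }
  diag(S) <- ifelse(lengths(profs) > 0, 1, 0)
  # exact symmetry regardless of floating-point summation order
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}

# Indirect groupwise matrices: one pairwise term matrix, then per-pair
# aggregation (AVG has a closed matrix form).
indirect_gw_matrix <- function(g, profs, pw, agg, icv) {
  n <- length(profs)
  if (any(lengths(profs) == 0)) {
    if (all(lengths(profs) == 0)) stop("cannot compare two empty phenotype profiles")
    message(sum(lengths(profs) == 0), " empty profile(s); their similarities are 0")
  }
  terms <- unique(unlist(profs))
  M <- term_sim_matrix(g, terms, pw, ic = icv)
  tidx <- lapply(profs, function(p) match(p, terms))
  S <- matrix(0, n, n)
  if (agg == "avg") {
    P <- matrix(0, n, length(terms))
    for (i in seq_len(n)) P[i, tidx[[i]]] <- 1
    sz <- rowSums(P)
    num <- P %*% M %*% t(P)
    den <- outer(sz, sz)
    S <- ifelse(den > 0, num / den, 0)
  } else {
    for (i in seq_len(n)) {
      ai <- tidx[[i]]
      if (!length(ai)) next
      for (j in i:n) {
        bj <- tidx[[j]]
        if (!length(bj)) next
        S[i, j] <- aggregate_pair_matrix(M[ai, bj, drop = FALSE], agg)
      }
    }
  }
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}

#' Pair records from a similarity matrix
#'
#' Flattens the upper triangle (i < j in the matrix's admission order)
#' into one record per unordered admission pair, with the similarity
#' score and whether the two admissions share a primary diagnosis.
#'
#' @param S similarity matrix from [compute_similarity_matrix()].
#' @param admissions the matching [labeled_admissions()].
#' @return A data frame with columns `admission_i`, `admission_j`,
#'   `score`, `shared`; `n * (n - 1) / 2` rows.
#' @export
build_pair_records <- function(S, admissions) {
  stopifnot(inherits(admissions, "labeled_admissions"))
  n <- length(admissions$ids)
  if (!is.matrix(S) || nrow(S) != n || ncol(S) != n)
    stop("similarity matrix dimensions do not match the admissions")
  if (anyDuplicated(admissions$ids)) stop("duplicated admission ids")
  ut <- which(upper.tri(S), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  data.frame(
    admission_i = admissions$ids[ut[, 1]],
    admission_j = admissions$ids[ut[, 2]],
    score = S[ut],
    shared = admissions$diagnoses[ut[, 1]] == admissions$diagnoses[ut[, 2]],
    stringsAsFactors = FALSE)
}

#' Run the full benchmark sweep
#'
#' For each configuration: similarity matrix, pair records, global AUC
#' ([evaluate_auc()]) and per-admission ranking metrics
#' ([evaluate_rankings()]). Failures in one configuration are caught,
#' recorded in the `status` column and do not stop the sweep. When
#' `out_dir` is given, results are appended to `results.tsv` after every
#' configuration (so a partial sweep survives interruption) and summary
#' tables grouped by groupwise measure and by IC measure are written at
#' the end.
#'
#' @param g an [ontology()].
#' @param corpus an [annotation_corpus()] (needed by corpus-IC configs).
#' @param admissions a [labeled_admissions()].
#' @param configs data frame from [enumerate_configs()].
#' @param registry the measure registry.
#' @param k ranking cutoff for top-k accuracy (default 10).
#' @param tie_policy ranking tie policy, see [evaluate_rankings()].
#' @param out_dir optional output directory for incremental TSV results.
#' @param verbose log progress per configuration.
#' @return A data frame with one row per configuration and columns
#'   `config_id`, `groupwise`, `pairwise`, `ic`, `auc`, `auc_lo`,
#'   `auc_hi`, `mrr0`, `mrrna`, `a10`, `a10_lo`, `a10_hi`, `n`,
#'   `n_matchable`, `status`.
#' @export
run_benchmark <- function(g, corpus, admissions, configs,
                          registry = default_registry(), k = 10,
                          tie_policy = "id", out_dir = NULL,
                          verbose = FALSE) {
  stopifnot(is.data.frame(configs))
  cols <- c("config_id", "groupwise", "pairwise", "ic",
            "auc", "auc_lo", "auc_hi", "mrr0", "mrrna",
            "a10", "a10_lo", "a10_hi", "n", "n_matchable", "status")
  results_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    results_path <- file.path(out_dir, "results.tsv")
    utils::write.table(as.data.frame(setNames(rep(list(character(0)), length(cols)), cols)),
                       results_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ic_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(configs))
  for (ci in seq_len(nrow(configs))) {
    cfg <- configs[ci, ]
    row <- data.frame(config_id = cfg$config_id, groupwise = cfg$groupwise,
                      pairwise = cfg$pairwise, ic = cfg$ic,
                      auc = NA_real_, auc_lo = NA_real_, auc_hi = NA_real_,
                      mrr0 = NA_real_, mrrna = NA_real_,
                      a10 = NA_real_, a10_lo = NA_real_, a10_hi = NA_real_,
                      n = length(admissions$ids), n_matchable = NA_integer_,
                      status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch({
      S <- compute_similarity_matrix(g, corpus, admissions, cfg,
                                     registry = registry, ic_cache = ic_cache,
                                     verbose = verbose)
      rec <- build_pair_records(S, admissions)
      auc <- evaluate_auc(rec)
      rk <- evaluate_rankings(S, admissions, k = k, tie_policy = tie_policy)
      row$auc <- auc$auc; row$auc_lo <- auc$ci_lo; row$auc_hi <- auc$ci_hi
      row$mrr0 <- rk$mrr0; row$mrrna <- rk$mrrna
      row$a10 <- rk$a_at_k; row$a10_lo <- rk$a_ci_lo; row$a10_hi <- rk$a_ci_hi
      row$n_matchable <- rk$n_matchable
      row
    }, error = function(e) {
      if (verbose) message("config ", cfg$config_id, " failed: ", conditionMessage(e))
      row$status <- paste0("failed: ", conditionMessage(e))
      row
    })
    rows[[ci]] <- res
    if (!is.null(results_path))
      utils::write.table(res, results_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE, append = TRUE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  rownames(results) <- NULL
  if (!is.null(out_dir) && nrow(results)) {
    ok <- results[results$status == "ok", , drop = FALSE]
    utils::write.table(summarize_results(ok, "groupwise"),
                       file.path(out_dir, "summary_groupwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summarize_results(ok, "ic"),
                       file.path(out_dir, "summary_ic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  results
}

#' Mean metrics grouped by one configuration component
#'
#' Averages AUC, MRR and top-k accuracy across configurations sharing a
#' component, e.g. per groupwise measure or per IC measure. Configurations
#' without the component (for `by = "ic"`, the non-IC settings) are pooled
#' under `"none"`.
#'
#' @param results data frame from [run_benchmark()].
#' @param by `"groupwise"`, `"pairwise"` or `"ic"`.
#' @return A data frame with the component id, `n_configs`, and mean
#'   `auc`, `mrr0`, `mrrna`, `a10`.
#' @export
summarize_results <- function(results, by = c("groupwise", "pairwise", "ic")) {
  by <- match.arg(by)
  ok <- results[results$status == "ok", , drop = FALSE]
  grp <- ok[[by]]
  grp[is.na(grp)] <- "none"
  if (!nrow(ok))
    return(data.frame(component = character(), n_configs = integer(),
                      auc = numeric(), mrr0 = numeric(), mrrna = numeric(),
                      a10 = numeric(), stringsAsFactors = FALSE))
  agg <- function(v) tapply(v, grp, mean)
  out <- data.frame(component = sort(unique(grp)),
                    n_configs = as.integer(table(grp)[sort(unique(grp))]),
                    auc = agg(ok$auc)[sort(unique(grp))],
                    mrr0 = agg(ok$mrr0)[sort(unique(grp))],
                    mrrna = agg(ok$mrrna)[sort(unique(grp))],
                    a10 = agg(ok$a10)[sort(unique(grp))],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
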