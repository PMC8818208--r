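# Readers and writers for the plain-text interchange formats: long-format
# profile/diagnosis/corpus TSVs, IC tables, OBO output, and roster files.

read_two_col_tsv <- function(path, col1, col2) {
  first <- readLines(path, n = 1)
  has_header <- identical(strsplit(first, "\t", fixed = TRUE)[[1]][1], col1)
  df <- utils::read.delim(path, header = has_header, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expected two tab-separated columns in ", path)
  df <- df[, 1:2]
  names(df) <- c(col1, col2)
  df
}

#' Read / write phenotype profiles as long-format TSV
#'
#' One row per annotation: `admission_id<TAB>term_id` (header optional on
#' read, written on write).
#'
#' @param path file path.
#' @return `read_profiles_tsv` returns a named list admission id ->
#'   character vector of term ids.
#' @export
read_profiles_tsv <- function(path) {
  df <- read_two_col_tsv(path, "admission_id", "term_id")
  lapply(split(df$term_id, df$admission_id), unique)
}

#' @rdname read_profiles_tsv
#' @param admissions a [labeled_admissions()] (or named list of profiles).
#' @export
write_profiles_tsv <- function(admissions, path) {
  profs <- if (inherits(admissions, "labeled_admissions")) admissions$profiles else admissions
  df <- data.frame(admission_id = rep(names(profs), lengths(profs)),
                   term_id = unlist(profs, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write primary-diagnosis labels as TSV
#'
#' One row per admission: `admission_id<TAB>code`.
#'
#' @param path file path.
#' @return `read_diagnoses_tsv` returns a named character vector
#'   admission id -> diagnosis code.
#' @export
read_diagnoses_tsv <- function(path) {
  df <- read_two_col_tsv(path, "admission_id", "code")
  if (anyDuplicated(df$admission_id)) stop("duplicated admission ids in ", path)
  stats::setNames(df$code, df$admission_id)
}

#' @rdname read_diagnoses_tsv
#' @param admissions a [labeled_admissions()].
#' @export
write_diagnoses_tsv <- function(admissions, path) {
  stopifnot(inherits(admissions, "labeled_admissions"))
  df <- data.frame(admission_id = admissions$ids, code = admissions$diagnoses,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble labeled admissions from profile and diagnosis TSVs
#'
#' @param profiles_path long-format profiles TSV
#'   (`admission_id<TAB>term_id`).
#' @param diagnoses_path diagnosis TSV (`admission_id<TAB>code`).
#' @return A [labeled_admissions()]; admissions present in only one file
#'   are an error.
#' @export
read_labeled_admissions <- function(profiles_path, diagnoses_path) {
  profs <- read_profiles_tsv(profiles_path)
  diag <- read_diagnoses_tsv(diagnoses_path)
  missing_diag <- setdiff(names(profs), names(diag))
  missing_prof <- setdiff(names(diag), names(profs))
  if (length(missing_diag))
    stop("admissions without a diagnosis: ", paste(utils::head(missing_diag, 5), collapse = ", "))
  if (length(missing_prof))
    stop("diagnoses without a profile: ", paste(utils::head(missing_prof, 5), collapse = ", "))
  ids <- names(profs)
  labeled_admissions(ids, profs[ids], unname(diag[ids]))
}

#' Read / write an annotation corpus as TSV
#'
#' One row per annotation: `entity_id<TAB>term_id` (header optional on
#' read).
#'
#' @param path file path.
#' @return `read_corpus_tsv` returns an [annotation_corpus()].
#' @export
read_corpus_tsv <- function(path) {
  df <- read_two_col_tsv(path, "entity_id", "term_id")
  annotation_corpus(split(df$term_id, df$entity_id))
}

#' @rdname read_corpus_tsv
#' @param corpus an [annotation_corpus()].
#' @export
write_corpus_tsv <- function(corpus, path) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  df <- data.frame(entity_id = rep(names(corpus), lengths(corpus)),
                   term_id = unlist(corpus, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an IC table as TSV
#'
#' Columns `term_id`, `method`, `ic`.
#'
#' @param ic an [ic_table].
#' @param path file path.
#' @export
write_ic_tsv <- function(ic, path) {
  stopifnot(inherits(ic, "ic_table"))
  df <- data.frame(term_id = names(ic$values), method = ic$method,
                   ic = unname(ic$values), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an ontology as a minimal OBO flat file
#'
#' Emits one `[Term]` stanza per term with its `id:` and `is_a:` lines —
#' sufficient to round-trip through [read_obo()].
#'
#' @param g an [ontology()].
#' @param path file path.
#' @export
write_obo <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_along(g$terms)) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", g$terms[i]), con)
    for (p in g$parents[[i]]) writeLines(paste0("is_a: ", g$terms[p]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read / write a measure roster file
#'
#' A plain-text key-value format listing the measure ids per category,
#' one category per line, ids separated by whitespace:
#'
#' ```
#' groupwise_direct: jaccard ui gic
#' groupwise_indirect: avg bma
#' pairwise: rada resnik
#' ic: resnik seco
#' ```
#'
#' Lines starting with `#` are ignored. Ids are validated against the
#' supplied registry (and [default_ic_methods()] for `ic:`).
#'
#' @param path file path.
#' @param registry registry to subset (default [default_registry()]).
#' @return `read_roster` returns a list with `registry` (the subset
#'   registry data frame) and `ics` (character vector of IC ids), ready
#'   for [enumerate_configs()].
#' @export
read_roster <- function(path, registry = default_registry()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed roster line: ", ln)
    key <- trimws(parts[1])
    vals <- strsplit(trimws(paste(parts[-1], collapse = ":")), "\\s+")[[1]]
    kv[[key]] <- vals[nzchar(vals)]
  }
  valid_keys <- c("groupwise_direct", "groupwise_indirect", "pairwise", "ic")
  bad <- setdiff(names(kv), valid_keys)
  if (length(bad)) stop("unknown roster categories: ", paste(bad, collapse = ", "))
  level_of <- c(groupwise_direct = "groupwise-direct",
                groupwise_indirect = "groupwise-indirect",
                pairwise = "pairwise")
  keep <- logical(nrow(registry))
  for (key in intersect(names(kv), names(level_of))) {
    ids <- kv[[key]]
    found <- registry$id %in% ids & registry$level == level_of[[key]]
    missing <- setdiff(ids, registry$id[found])
    if (length(missing))
      stop("unknown ", key, " measure id(s): ", paste(missing, collapse = ", "))
    keep <- keep | found
  }
  ics <- kv[["ic"]] %||% character()
  bad_ic <- setdiff(ics, default_ic_methods())
  if (length(bad_ic)) stop("unknown ic method id(s): ", paste(bad_ic, collapse = ", "))
  list(registry = registry[keep, , drop = FALSE], ics = ics)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_roster
#' @param roster a list with elements `registry` and `ics`.
#' @export
write_roster <- function(roster, path) {
  reg <- roster$registry
  lines <- c(
    paste("groupwise_direct:", paste(reg$id[reg$level == "groupwise-direct"], collapse = " ")),
    paste("groupwise_indirect:", paste(reg$id[reg$level == "groupwise-indirect"], collapse = " ")),
    paste("pairwise:", paste(reg$id[reg$level == "pairwise"], collapse = " ")),
    paste("ic:", paste(roster$ics, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
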