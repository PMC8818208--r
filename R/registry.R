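# Measure registry: the machine-readable roster of pairwise and groupwise
# measures the benchmark can sweep over.

#' The default measure registry
#'
#' One row per measure with its category and requirements:
#'
#' * pairwise: `rada` (path), `jaccard_pw` and `node_sim` (ancestor-set
#'   Jaccard / Dice), `resnik` (IC of the most informative common
#'   ancestor; needs an IC measure);
#' * direct groupwise: `jaccard` (raw term sets), `ui` (closure Jaccard),
#'   `gic` (IC-weighted closure ratio; needs an IC measure);
#' * indirect groupwise: `max`, `min`, `avg`, `bma`, `bmm`, each needing a
#'   pairwise measure.
#'
#' The registry is extensible: [enumerate_configs()] accepts any data
#' frame with these columns, so further measures can be swept without
#' touching the benchmark engine.
#'
#' @return A data frame with columns `id`, `level` (one of `"pairwise"`,
#'   `"groupwise-direct"`, `"groupwise-indirect"`), `needs_ic`,
#'   `needs_pairwise`.
#' @export
default_registry <- function() {
  data.frame(
    id = c("rada", "jaccard_pw", "node_sim", "resnik",
           "jaccard", "ui", "gic",
           "max", "min", "avg", "bma", "bmm"),
    level = c(rep("pairwise", 4),
              rep("groupwise-direct", 3),
              rep("groupwise-indirect", 5)),
    needs_ic = c(FALSE, FALSE, FALSE, TRUE,
                 FALSE, FALSE, TRUE,
                 rep(FALSE, 5)),
    needs_pairwise = c(rep(FALSE, 7), rep(TRUE, 5)),
    stringsAsFactors = FALSE)
}

validate_registry <- function(registry) {
  need <- c("id", "level", "needs_ic", "needs_pairwise")
  if (!is.data.frame(registry) || !all(need %in% names(registry)))
    stop("registry must be a data frame with columns ", paste(need, collapse = ", "))
  if (anyDuplicated(registry$id))
    stop("registry ids must be unique")
  ok_lv <- c("pairwise", "groupwise-direct", "groupwise-indirect")
  if (!all(registry$level %in% ok_lv))
    stop("registry level must be one of ", paste(ok_lv, collapse = ", "))
  bad <- registry$needs_pairwise & registry$level != "groupwise-indirect"
  if (any(bad))
    stop("needs_pairwise set outside groupwise-indirect: ",
         paste(registry$id[bad], collapse = ", "))
  bad <- registry$level == "groupwise-indirect" & !registry$needs_pairwise
  if (any(bad))
    stop("indirect groupwise measures must declare needs_pairwise: ",
         paste(registry$id[bad], collapse = ", "))
  invisible(registry)
}

#' Write / read the measure registry as TSV
#'
#' Columns `id`, `level`, `needs_ic`, `needs_pairwise`.
#'
#' @param registry a registry data frame (see [default_registry()]).
#' @param path file path.
#' @return `write_registry_tsv` returns `path` invisibly;
#'   `read_registry_tsv` returns the registry data frame.
#' @export
write_registry_tsv <- function(registry, path) {
  validate_registry(registry)
  utils::write.table(registry, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry_tsv
#' @export
read_registry_tsv <- function(path) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  reg$needs_ic <- as.logical(reg$needs_ic)
  reg$needs_pairwise <- as.logical(reg$needs_pairwise)
  validate_registry(reg)
  reg
}
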