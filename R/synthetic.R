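# Synthetic data generation: ontologies, disease-phenotype maps, and noisy
# admission profiles emulating uncurated text-derived phenotype data.

#' Specification for the synthetic benchmark data generator
#'
#' All generators are fully determined by `seed`. The defaults describe a
#' desk-scale cohort of text-derived admission profiles: a mid-sized
#' single-rooted taxonomy, tens of diseases with realistic phenotype
#' profiles, and admissions carrying on average 44 annotated terms of
#' which a fraction is uninformative high-frequency noise (the synthetic
#' analogue of ubiquitous clinical-text terms such as "pain").
#'
#' @param seed integer RNG seed.
#' @param n_terms number of ontology terms (including the root).
#' @param max_children preferred cap on children per term during
#'   ontology generation (soft: exceeded only when no parent has spare
#'   capacity).
#' @param multi_parent_prob probability that a term receives a second
#'   parent, making the taxonomy a DAG rather than a tree.
#' @param n_diseases number of diseases.
#' @param disease_profile_size terms per disease phenotype profile.
#' @param n_admissions number of admissions to simulate.
#' @param mean_terms_per_admission mean profile size (truncated-Poisson
#'   mean), default 44.
#' @param noise_fraction fraction of each profile drawn from the noise
#'   pool rather than the admission's disease profile, in \[0, 1\].
#' @param n_common_noise_terms number of reserved high-frequency noise
#'   terms (never used in disease profiles).
#' @param noise_skew Zipf exponent of the noise-term frequency weights
#'   (larger = a few terms dominate).
#' @param min_admissions_per_diagnosis guaranteed admissions per disease;
#'   1 leaves room for diagnoses occurring only once (unmatchable
#'   admissions).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_terms = 500L,
                           max_children = 8L,
                           multi_parent_prob = 0.1,
                           n_diseases = 40L,
                           disease_profile_size = 60L,
                           n_admissions = 1000L,
                           mean_terms_per_admission = 44,
                           noise_fraction = 0.3,
                           n_common_noise_terms = 20L,
                           noise_skew = 1.5,
                           min_admissions_per_diagnosis = 1L) {
  spec <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
               max_children = as.integer(max_children),
               multi_parent_prob = multi_parent_prob,
               n_diseases = as.integer(n_diseases),
               disease_profile_size = as.integer(disease_profile_size),
               n_admissions = as.integer(n_admissions),
               mean_terms_per_admission = mean_terms_per_admission,
               noise_fraction = noise_fraction,
               n_common_noise_terms = as.integer(n_common_noise_terms),
               noise_skew = noise_skew,
               min_admissions_per_diagnosis = as.integer(min_admissions_per_diagnosis))
  counts <- c("n_terms", "max_children", "n_diseases", "disease_profile_size",
              "n_admissions", "n_common_noise_terms", "min_admissions_per_diagnosis")
  for (f in counts) if (is.na(spec[[f]]) || spec[[f]] < 1)
    stop(f, " must be a positive count")
  if (spec$mean_terms_per_admission <= 0) stop("mean_terms_per_admission must be positive")
  if (spec$noise_fraction < 0 || spec$noise_fraction > 1)
    stop("noise_fraction must lie in [0, 1]")
  if (spec$multi_parent_prob < 0 || spec$multi_parent_prob > 1)
    stop("multi_parent_prob must lie in [0, 1]")
  if (spec$noise_skew < 0) stop("noise_skew must be non-negative")
  structure(spec, class = "synthetic_spec")
}

synthetic_term_ids <- function(n) sprintf("ST:%07d", seq_len(n))

# Reserved high-frequency noise terms: the last ids in generation order,
# excluded from every disease profile so noise carries no diagnosis signal.
common_noise_terms <- function(spec) {
  n <- spec$n_terms
  h <- min(spec$n_common_noise_terms, n - 1)
  synthetic_term_ids(n)[seq.int(n - h + 1, n)]
}

#' Generate a synthetic single-rooted ontology
#'
#' Term 1 is the root; every later term attaches to one earlier term
#' (preferring parents with fewer than `max_children` children) and, with
#' probability `multi_parent_prob`, to a second earlier term. The result
#' is acyclic and single-rooted by construction, and byte-identical
#' across runs with the same spec.
#'
#' @param spec a [synthetic_spec()].
#' @return An [ontology()].
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_terms
  ids <- synthetic_term_ids(n)
  parents <- vector("list", n)
  names(parents) <- ids
  parents[[1]] <- character()
  n_children <- integer(n)
  for (i in seq_len(n)[-1]) {
    pool <- which(n_children[seq_len(i - 1)] < spec$max_children)
    if (!length(pool)) pool <- seq_len(i - 1)
    p <- if (length(pool) == 1) pool else sample(pool, 1)
    ps <- p
    if (i > 2 && stats::runif(1) < spec$multi_parent_prob) {
      extra <- setdiff(seq_len(i - 1), p)
      p2 <- if (length(extra) == 1) extra else sample(extra, 1)
      ps <- c(ps, p2)
    }
    n_children[ps] <- n_children[ps] + 1L
    parents[[i]] <- ids[ps]
  }
  ontology(parents)
}

#' Generate disease phenotype profiles
#'
#' Samples `n_diseases` term sets of size `disease_profile_size` without
#' replacement from the non-root, non-noise terms of the ontology. With
#' `disjoint = TRUE` the profiles are pairwise disjoint (useful for
#' perfect-signal fixtures).
#'
#' @param g the [ontology()] generated from the same spec.
#' @param spec a [synthetic_spec()].
#' @param disjoint force pairwise-disjoint profiles.
#' @return Named list disease id (`"DIS:001"`, ...) -> character vector
#'   of term ids.
#' @export
generate_disease_profiles <- function(g, spec, disjoint = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  candidates <- setdiff(g$terms, c(g$terms[g$root], common_noise_terms(spec)))
  sz <- spec$disease_profile_size
  if (sz > length(candidates))
    stop("disease_profile_size exceeds the number of available terms")
  dis_ids <- sprintf("DIS:%03d", seq_len(spec$n_diseases))
  if (disjoint) {
    need <- sz * spec$n_diseases
    if (need > length(candidates))
      stop("disjoint disease profiles infeasible: need ", need,
           " terms, have ", length(candidates))
    picked <- sample(candidates, need)
    profiles <- split(picked, rep(seq_len(spec$n_diseases), each = sz))
  } else {
    profiles <- lapply(seq_len(spec$n_diseases), function(i) sample(candidates, sz))
  }
  names(profiles) <- dis_ids
  lapply(profiles, sort)
}

# Poisson truncated at >= 1, mean approximately lambda.
rtpois <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  while (any(x == 0)) x[x == 0] <- stats::rpois(sum(x == 0), lambda)
  x
}

#' Generate labeled admissions and their annotation corpus
#'
#' Each admission draws a primary diagnosis (every disease is guaranteed
#' `min_admissions_per_diagnosis` admissions; the remainder follow a
#' Zipf-skewed prevalence over diseases, so rare diagnoses can occur only
#' once), a profile size from a truncated Poisson with the spec mean, and
#' fills the profile with signal terms sampled from its disease profile
#' plus noise terms sampled (without replacement per profile) from a
#' Zipf-weighted noise pool headed by the reserved common noise terms.
#' The returned corpus maps every admission to its own profile, so corpus
#' IC estimated from it down-weights the ubiquitous noise terms.
#'
#' @param g the [ontology()] generated from the same spec.
#' @param diseases disease profiles from [generate_disease_profiles()].
#' @param spec a [synthetic_spec()].
#' @return List with elements `admissions` (a [labeled_admissions()]) and
#'   `corpus` (an [annotation_corpus()]).
#' @export
generate_admissions <- function(g, diseases, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!length(diseases)) stop("empty disease map")
  set.seed(spec$seed + 2L)
  n <- spec$n_admissions
  dis_ids <- names(diseases)

  base <- rep(dis_ids, spec$min_admissions_per_diagnosis)
  if (length(base) > n)
    stop("min_admissions_per_diagnosis infeasible for ", n, " admissions")
  w_dis <- seq_along(dis_ids)^(-1)   # Zipf-1 prevalence
  rest <- sample(dis_ids, n - length(base), replace = TRUE, prob = w_dis)
  diagnoses <- sample(c(base, rest))

  # Noise pool: reserved common terms first, then terms unused by any
  # disease profile; Zipf weights by pool rank.
  pool <- c(common_noise_terms(spec),
            setdiff(g$terms, c(g$terms[g$root], common_noise_terms(spec),
                               unique(unlist(diseases)))))
  w_pool <- seq_along(pool)^(-spec$noise_skew)

  sizes <- rtpois(n, spec$mean_terms_per_admission)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    dprof <- diseases[[diagnoses[i]]]
    n_noise <- round(spec$noise_fraction * sizes[i])
    n_signal <- sizes[i] - n_noise
    if (n_signal > length(dprof)) {
      deficit <- n_signal - length(dprof)
      n_signal <- length(dprof)
      if (spec$noise_fraction > 0) n_noise <- n_noise + deficit
    }
    n_noise <- min(n_noise, length(pool))
    signal <- if (n_signal > 0) sample(dprof, n_signal) else character()
    noise <- if (n_noise > 0) sample(pool, n_noise, prob = w_pool) else character()
    profiles[[i]] <- sort(c(signal, noise))
  }
  ids <- sprintf("ADM:%05d", seq_len(n))
  adm <- labeled_admissions(ids, profiles, diagnoses)
  list(admissions = adm, corpus = annotation_corpus(adm$profiles))
}

#' Generate a complete synthetic benchmark dataset
#'
#' Convenience wrapper running [generate_ontology()],
#' [generate_disease_profiles()] and [generate_admissions()] from one
#' spec.
#'
#' @param spec a [synthetic_spec()].
#' @param disjoint_diseases force pairwise-disjoint disease profiles.
#' @return List with `ontology`, `diseases`, `admissions`, `corpus`.
#' @export
generate_benchmark_data <- function(spec, disjoint_diseases = FALSE) {
  g <- generate_ontology(spec)
  dis <- generate_disease_profiles(g, spec, disjoint = disjoint_diseases)
  ac <- generate_admissions(g, dis, spec)
  list(ontology = g, diseases = dis,
       admissions = ac$admissions, corpus = ac$corpus)
}
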