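---
title: "Benchmarking ontology-based similarity on phenotype profiles: methods"
author: "phenosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking ontology-based similarity on phenotype profiles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosim)
```

This vignette documents the models, conventions and design choices behind
`phenosim`, in the spirit of the methods sections of mature analysis
packages. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The taxonomy and its contract

All measures operate on a rooted, acyclic `is_a` hierarchy. `read_obo()`
loads only the asserted subsumptive skeleton of an OBO file: `[Term]`
stanzas with `id:`, `is_a:` and `is_obsolete:`. Other relationship types
(e.g. `part_of`) are deliberately ignored — the measures implemented here
are defined on subsumption alone, and mixing relation semantics would
silently change what "ancestor" means. Obsolete terms are dropped; a term
whose parents are all obsolete is re-rooted under its nearest live
ancestor reachable through obsolete `is_a` chains, or attached directly
to the root if no such ancestor exists, so no term is orphaned by
curation history. Classification by an OWL reasoner is out of scope: on a
well-curated ontology the asserted hierarchy is the standard operating
substrate for these measures, but users should be aware that inferred
subsumptions could in principle alter ancestor sets.

Two structural conventions matter downstream:

- **Depths are edge counts with the root at depth 0.** Minimum and
  maximum depth are computed per term over all root paths.
- **Path distance is undirected**: the Rada measure's
  `dist(x, y)` is the shortest path over `is_a` edges traversed in either
  direction. This is the common reading of path-based similarity, and it
  is checkable against a plain breadth-first search, which the test suite
  does on random DAGs.

Multiple parentless terms are an error by default; `virtual_root = TRUE`
inserts a synthetic root above them, which is useful for ad-hoc subsets
of an ontology but intentionally opt-in, since a forgotten root usually
indicates a malformed input rather than a multi-rooted design.

## Information content

All ICs are in nats. The natural log is a free choice — every benchmark
metric here is rank-based, hence invariant to the base — but fixing it
keeps tables comparable.

**Corpus IC** follows the annotation-frequency definition:
`p(x) = |I(x)|/|I|` and `IC(x) = -ln p(x)`, where `|I(x)|` counts the
annotation *pairs* falling on `x` or its descendants. Counting pairs
(rather than distinct entities) matches the plain reading of an
annotation set; a `count = "entities"` flag provides the alternative for
sensitivity analysis, since reference implementations differ silently on
this point. Terms whose closure is never annotated receive
`-ln(1/(|I|+1))`: finite, and strictly above the largest observed IC, so
"never seen" remains the most informative state. A consequence worth
noting: this pseudocount depends on corpus size, so IC values of *unseen*
terms are not invariant under duplicating the corpus, while all observed
terms are (`p` is scale-free); the tests assert exactly this split.

**Structural ICs** use the standard formulations, with `N` the term
count, `hypo(x)` exclusive descendants, `D` the ontology's maximum
depth, `leaves(x)` leaf descendants (a leaf counts itself), `subs(x)`
inclusive ancestors and `L` total leaves:

| id | formula | range |
|----|---------|-------|
| `seco` | `1 - ln(hypo(x)+1)/ln N` | [0, 1] |
| `zhou` | `k·seco(x) + (1-k)·ln(maxdepth(x)+1)/ln(D+1)`, `k = 0.5` | [0, 1] |
| `sanchez` | `-ln((leaves(x)/subs(x) + 1)/(L + 1))` | ≥ 0 |
| `depth_max` | `ln(maxdepth(x)+1)/ln(D+1)` | [0, 1] |
| `depth_min` | `ln(mindepth(x)+1)/ln(D+1)` | [0, 1] |

The depth-normalised pair `depth_max`/`depth_min` is our reading of the
"Max"/"Min" IC labels used in semantic-measures tooling; the registry is
extensible if another normalisation is preferred. One subtlety: on a
multi-parent DAG, `depth_min` is not monotone along every edge (a child
can have a shorter root path than one of its parents), so only
`seco`, `zhou` and `depth_max` carry an edge-wise monotonicity guarantee;
`depth_min` is monotone on trees and along shortest root paths.

## Similarity measures

Pairwise: Rada (`1/(dist+1)`), ancestor-set Jaccard (`jaccard_pw`) and
Dice (`node_sim`) over inclusive ancestor closures, and Resnik
(`IC(MICA)`). MICA ties — several common ancestors at the maximal IC —
are broken by the lexicographically smallest term id, purely for
determinism; the returned IC is unaffected.

Groupwise-direct: set Jaccard on the *raw* annotated term sets (the
annotation-level reading of a set Jaccard; `ui` provides the
ancestor-closure variant separately, so both readings are registered and
comparable), and GIC, the ratio of summed IC over the intersection versus
the union of the two profiles' closures. GIC is sometimes glossed as "the
average IC of the intersection"; the implemented quantity is the
ratio-of-sums, which is the form that is bounded in [0, 1] and reaches 1
exactly on identical closures.

Groupwise-indirect aggregators over the m×n pairwise matrix `S`: MAX,
MIN, AVG (grand mean), BMA `½(mean rowmax + mean colmax)` and BMM
`max(mean rowmax, mean colmax)` — the symmetric best-match conventions.
These satisfy `MIN ≤ AVG ≤ MAX` and `MIN ≤ BMA ≤ BMM ≤ MAX` entry-wise,
which the tests assert across every registered configuration.

Degenerate inputs: comparing against an empty profile returns 0 with a
logged message (text mining does produce empty profiles, and silently
erroring mid-sweep would be worse); two empty profiles are an error. A
GIC union carrying zero total IC (e.g. profiles consisting only of the
root) falls back to closure identity — 1 for identical closures, else 0
— so the "identical inputs score 1" axiom survives the degenerate case.

## The benchmark pipeline

For each configuration: all-pairs similarity matrix (computed once per
unordered pair and mirrored, so symmetry is exact), pair records over the
upper triangle with a shared-primary-diagnosis flag, then:

- **AUC** via the Mann–Whitney rank formulation, ties weighted ½. The
  95% CI uses the Hanley–McNeil parametric standard error
  (`Q1 = A/(2-A)`, `Q2 = 2A²/(1+A)`), clipped to [0, 1]. This is the
  standard parametric choice for a rank-sum AUC; a bootstrap would be
  slower and is unnecessary at these pair counts.
- **MRR-0 / MRR-NA and A@k** by ranking each admission's neighbours by
  descending similarity. Ties are broken by ascending admission id by
  default — fully deterministic — with `mid`, `optimistic` and
  `pessimistic` policies available because MRR and A@k are genuinely
  tie-sensitive (the tie-policy test pins down how much they can move).
  A@k uses `min(k, n-1)` and a Wald CI with denominator n.
- **A@10/AUC/MRR correlations** across configurations via Pearson's
  method with the usual t-transform p-value.

The identity `MRR-0 = MRR-NA × n_matchable / n` holds by construction
(unmatchable admissions contribute exactly 0) and is asserted to 1e-12
on random benchmarks.

`enumerate_configs()` expands a roster deterministically, ordered
lexicographically by (groupwise, pairwise, IC): direct measures crossed
with ICs when they need one; indirect measures crossed with non-IC
pairwise measures; indirect × IC-using pairwise × IC. The default
registry (4 pairwise, 3 direct, 5 indirect, 6 ICs) yields 53
configurations. The registry is a plain data frame, so additional
measures can be swept without touching the engine.

`run_benchmark()` isolates per-configuration failures (recorded in the
`status` column), appends each result row to `results.tsv` as it
completes so partial sweeps survive interruption, and writes mean-metric
summaries grouped by groupwise measure and by IC measure.

## The synthetic generator

The generator emulates the statistical shape of uncurated text-derived
admission profiles; it does not simulate text or concept-recognition
errors at the string level.

- **Ontology**: term *i* attaches to one earlier term (preferring
  parents with spare capacity under `max_children`) plus a second parent
  with probability `multi_parent_prob` (default 0.1) — single-rooted and
  acyclic by construction.
- **Diseases**: `n_diseases` profiles of `disease_profile_size` terms
  sampled uniformly from non-root, non-noise terms, optionally pairwise
  disjoint for perfect-signal controls.
- **Admissions**: diagnosis prevalence is Zipf-skewed (exponent 1) over
  diseases with a guaranteed floor of `min_admissions_per_diagnosis`, so
  small cohorts naturally contain diagnoses occurring once — the
  unmatchable admissions that drive the MRR-0 vs MRR-NA gap. Profile
  sizes follow a Poisson truncated at ≥ 1 with mean
  `mean_terms_per_admission = 44`, the annotation density reported for
  text-mined critical-care admissions. A `noise_fraction` of each
  profile is drawn, without replacement, from a noise pool whose
  sampling weights decay as `rank^(-noise_skew)` (default 1.5) — a
  Zipf head of `n_common_noise_terms` reserved terms that appear in most
  admissions, emulating ubiquitous uninformative concepts such as
  "pain" or "allergies". Noise terms never occur in disease profiles,
  so `noise_fraction = 1` produces profiles with no diagnosis signal.
- **Corpus**: the admission set itself is the annotation corpus, so
  corpus IC is self-referential, as in a single-cohort study design:
  ubiquitous noise terms acquire low IC and are automatically
  down-weighted by IC-aware measures.

Everything is a deterministic function of `seed` (the three generation
stages use `seed`, `seed + 1`, `seed + 2`, so regenerating any stage
reproduces byte-identical TSV/OBO output).

What passing on synthetic data does *not* show: real disease profiles
are ontologically coherent (their terms cluster in related subtrees),
real noise is correlated with note type and length, and real diagnosis
labels are themselves imperfect. Synthetic results therefore validate
the machinery and the qualitative behaviour of measure families — e.g.
that extreme-value aggregators collapse to chance under shared
high-frequency noise while averaging and closure-based measures do not —
rather than any absolute performance level.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every code path with comfortable margins: toy fixtures of ≤ 7
terms for formula fidelity, random DAGs of 20–50 terms for oracle
comparisons, and cohorts of 60–100 admissions over 300–500-term
ontologies (20 diseases × 30-term profiles, 50% noise, noise pool 40)
for the end-to-end sweeps. The full default cohort
(`synthetic_spec()` defaults: 1000 admissions, 500 terms, 40 diseases)
runs in minutes and is used where the test concerns distributional
properties (mean profile size, noise skew).

## Known limitations

- Only `is_a` is honoured; ontologies whose semantics lean on other
  relations (or on reasoning) need preprocessing.
- The direct-groupwise roster (set Jaccard, closure Jaccard, GIC) is a
  representative core, not the full zoo of published direct measures;
  the registry is the extension point.
- The Schlicker pairwise measure is excluded by design: it requires a
  tuned hyperparameter, and this benchmark deliberately contains no
  tuning stage.
- Wall-clock performance of measures is not benchmarked.
- Wald and Hanley–McNeil intervals are approximations; at very small
  cohort sizes or metrics near 0/1 they clip at the boundaries.
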