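# phenosim

Benchmarking ontology-based semantic similarity on patient phenotype
profiles.

## The problem

Clinical text mining turns the narrative of a hospital admission into a
*phenotype profile*: the set of ontology terms (typically from the Human
Phenotype Ontology, HPO) recognised in its notes. Profiles from two
admissions can then be compared with a semantic similarity measure, and a
good measure should score two admissions with the same underlying disease
higher than two unrelated ones — the basis of similarity-driven
differential diagnosis, patient stratification and variant prioritisation.

There are, however, dozens of ways to assemble such a measure, and their
relative merits on noisy, uncurated text-derived profiles are far from
obvious. `phenosim` is a benchmarking platform for exactly this question.
It factorises a similarity *configuration* into three interchangeable
components and sweeps every combination:

- **Information content (IC)** — a per-term specificity weight. Corpus
  IC follows Resnik: `IC(x) = -ln p(x)` with
  `p(x) = |I(x)| / |I|`, where `I` is the full annotation set and `I(x)`
  the annotations falling on `x` or its descendants. Structural
  alternatives (Seco, Zhou, Sánchez, and max/min depth normalisations)
  need only the taxonomy.
- **Pairwise term similarity** — e.g. Rada's path measure
  `sim(x, y) = 1 / (dist(x, y) + 1)`, ancestor-set Jaccard/Dice overlap,
  or Resnik's `sim(x, y) = IC(MICA(x, y))`, the IC of the most
  informative common ancestor.
- **Groupwise profile similarity** — *direct* measures defined on the
  term sets themselves (set Jaccard; closure Jaccard; GIC, the ratio of
  summed IC over the intersection vs the union of the two profiles'
  ancestor closures) or *indirect* aggregation of the pairwise matrix
  (MAX, MIN, AVG, best-match average BMA, best-match maximum BMM).

Each configuration yields an all-pairs similarity matrix over a cohort of
admissions labelled with their primary coded diagnosis. The benchmark
scores how well similarity predicts a *shared* primary diagnosis:

- **AUC** — Mann–Whitney probability that a same-diagnosis pair outscores
  a different-diagnosis pair, with Hanley–McNeil 95% CIs;
- **MRR-0 / MRR-NA** — mean reciprocal rank of the first same-diagnosis
  neighbour, counting admissions with no possible match as 0 (MRR-0) or
  excluding them (MRR-NA); the two are linked by
  `MRR-0 = MRR-NA × n_matchable / n`;
- **A@10** — fraction of admissions with a same-diagnosis neighbour among
  their ten nearest, with a Wald 95% CI;

plus Pearson correlations between the metrics across configurations.

Because real admission-level data are access-restricted, the package
ships a synthetic generator that emulates their statistical shape:
admissions average 44 annotated terms, a tunable fraction of which is
drawn from a Zipf-skewed pool of uninformative high-frequency noise terms
(the synthetic analogue of ubiquitous clinical-text concepts like
"pain"), and rare diagnoses may occur only once, creating unmatchable
admissions.

## Worked example

```r
library(phenosim)

spec <- synthetic_spec(seed = 42, n_terms = 300, n_diseases = 20,
                       disease_profile_size = 30, n_admissions = 100,
                       noise_fraction = 0.5, n_common_noise_terms = 40,
                       min_admissions_per_diagnosis = 2)
dat <- generate_benchmark_data(spec)
dat$ontology
#> ontology: 300 terms, 327 is_a edges, root ST:0000001
dat$admissions
#> labeled_admissions: 100 admissions, 20 distinct diagnoses, mean profile size 43.3

cfgs <- enumerate_configs()          # 53 configurations from the full registry
res <- run_benchmark(dat$ontology, dat$corpus, dat$admissions,
                     cfgs[cfgs$config_id %in%
                            c("avg+resnik+resnik", "bma+resnik+resnik",
                              "gic+resnik", "jaccard", "max+rada", "min+rada"), ])
res[, c("config_id", "auc", "auc_lo", "auc_hi", "mrr0", "mrrna", "a10", "n_matchable")]
#>           config_id   auc auc_lo auc_hi  mrr0 mrrna  a10 n_matchable
#> 1 avg+resnik+resnik 0.771  0.745  0.797 0.661 0.661 0.85         100
#> 2 bma+resnik+resnik 0.949  0.935  0.964 1.000 1.000 1.00         100
#> 3        gic+resnik 0.992  0.986  0.998 0.990 0.990 1.00         100
#> 4           jaccard 1.000  1.000  1.000 1.000 1.000 1.00         100
#> 5          max+rada 0.500  0.472  0.528 0.274 0.274 0.51         100
#> 6          min+rada 0.515  0.487  0.544 0.219 0.219 0.54         100
```

Reading the table: with half of every profile replaced by skewed noise,
configurations that pool evidence across the whole profile (GIC, BMA,
AVG, set Jaccard) still separate same-diagnosis pairs well, while the
single-best-pair MAX and single-worst-pair MIN aggregators collapse to
chance (AUC ≈ 0.5) because every admission pair shares some
high-frequency noise term. `n_matchable` is the number of admissions
with at least one same-diagnosis partner; here all 100, so MRR-0 and
MRR-NA coincide.

```r
correlate_metrics(res, "auc", "a10")$r
#> [1] 0.99
```

A command-line wrapper over the same pipeline lives at
`inst/cli/phenosim.R`:

```sh
Rscript inst/cli/phenosim.R enumerate                      # list configurations
Rscript inst/cli/phenosim.R run --obo hp.obo \
    --profiles profiles.tsv --diagnoses diagnoses.tsv \
    --configs roster.txt --out results/
```

`run` writes `results.tsv` incrementally (one row per configuration, so
interrupted sweeps keep their partial results) plus per-groupwise and
per-IC summary tables.

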